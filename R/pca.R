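# PCA of the pair-difference table: PC1/PC2 covariates plus the variable
# diagnostics (contributions, cos2) usually drawn on a PCA variable plot.

#' PCA of pairwise property differences
#'
#' Principal component analysis of the 190 x P table of absolute property
#' differences, standardized by default (centered, unit variance, i.e. an
#' eigendecomposition of the correlation matrix). Because PCA signs are
#' arbitrary, each component's sign is fixed deterministically: if the
#' component has a named anchor variable its loading is made positive,
#' otherwise the variable with the largest absolute loading gets a positive
#' loading.
#'
#' @param differences A pair-difference table from [pairwise_differences()]
#'   (columns `aa1`, `aa2` plus numeric property columns).
#' @param standardize Center and scale columns to unit variance (default
#'   `TRUE`). Constant columns are an error when standardizing.
#' @param anchors Optional named character vector mapping component labels
#'   (`"PC1"`, `"PC2"`, ...) to anchor variable names, e.g.
#'   `c(PC1 = "hydropathy", PC2 = "mol_weight")`.
#' @return An object of class `"pair_pca"` with elements `loadings` (P x K,
#'   orthonormal columns), `scores` (190 x K, rows keyed by `pairs`),
#'   `explained_fraction` (length K, sums to 1), `contributions` (P x K,
#'   each column sums to 100), `cos2` (P x K squared quality of
#'   representation), `sdev`, `pairs` (the `aa1`/`aa2` key), `standardized`,
#'   and `anchors`.
#' @export
#' @examples
#' pca <- pair_pca(pairwise_differences(builtin_properties()),
#'                 anchors = c(PC1 = "hydropathy", PC2 = "mol_weight"))
#' pca$explained_fraction[1:2]
pair_pca <- function(differences, standardize = TRUE, anchors = NULL) {
  keys <- differences[, c("aa1", "aa2")]
  x <- as.matrix(differences[, setdiff(names(differences), c("aa1", "aa2")),
                             drop = FALSE])
  if (ncol(x) < 2) stop("need at least 2 property columns", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (standardize && any(sds == 0))
    stop("constant column(s) under standardization: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = standardize)
  ev <- pc$sdev^2
  k <- length(ev)

  # deterministic sign convention
  for (comp in seq_len(k)) {
    lab <- paste0("PC", comp)
    anchor <- if (!is.null(anchors) && lab %in% names(anchors)) {
      a <- anchors[[lab]]
      if (!a %in% colnames(x))
        stop("anchor variable not found: ", a, call. = FALSE)
      a
    } else colnames(x)[which.max(abs(pc$rotation[, comp]))]
    if (pc$rotation[anchor, comp] < 0) {
      pc$rotation[, comp] <- -pc$rotation[, comp]
      pc$x[, comp] <- -pc$x[, comp]
    }
  }

  # variable coordinates: loading * sdev = correlation with the component
  # (under standardization); cos2 = coord^2, contributions = 100 * loading^2
  coord <- sweep(pc$rotation, 2, pc$sdev, `*`)
  cos2 <- coord^2
  if (!standardize) cos2 <- sweep(cos2, 1, rowSums(cos2), `/`)
  contrib <- 100 * pc$rotation^2

  structure(list(
    loadings = pc$rotation,
    scores = pc$x,
    explained_fraction = ev / sum(ev),
    contributions = contrib,
    cos2 = cos2,
    sdev = pc$sdev,
    center = pc$center,
    scale = pc$scale,
    pairs = keys,
    standardized = standardize,
    anchors = anchors
  ), class = "pair_pca")
}

#' @export
print.pair_pca <- function(x, ...) {
  cat("PCA of amino-acid pair property differences\n")
  cat("  ", nrow(x$loadings), "properties,", nrow(x$scores), "pairs\n")
  ef <- round(100 * x$explained_fraction[seq_len(min(4, length(x$explained_fraction)))], 1)
  cat("  explained variance (%):", paste(ef, collapse = ", "),
      if (length(x$explained_fraction) > 4) "..." else "", "\n")
  invisible(x)
}

#' Per-pair scores for one component
#'
#' Extracts the score column of component `k`, optionally replicated onto a
#' directed pair key (the score of a pair is direction-free, so the A->R and
#' R->A rows share one value).
#'
#' @param pca A [pair_pca()] result.
#' @param k Component index.
#' @param aa1,aa2 Optional equal-length amino-acid vectors (directed or
#'   unordered keys) onto which scores are joined; defaults to the PCA's own
#'   190 unordered pairs.
#' @return Numeric vector of scores.
#' @export
pc_scores <- function(pca, k, aa1 = NULL, aa2 = NULL) {
  if (k > ncol(pca$scores) || k < 1) stop("component index out of range", call. = FALSE)
  s <- pca$scores[, k]
  if (is.null(aa1)) return(s)
  key <- .pair_key(pca$pairs$aa1, pca$pairs$aa2)
  m <- match(.pair_key(aa1, aa2), key)
  if (anyNA(m)) stop("unknown pair(s) requested", call. = FALSE)
  unname(s[m])
}

#' Plot a pair PCA
#'
#' Basic base-graphics rendering: pair scores on the first two components,
#' with variable loadings overlaid as arrows scaled to the plot.
#'
#' @param x A `pair_pca` object.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.pair_pca <- function(x, ...) {
  s <- x$scores[, 1:2, drop = FALSE]
  plot(s, pch = 16, col = "grey50",
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_fraction[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_fraction[2]), ...)
  sc <- max(abs(s)) / max(abs(x$loadings[, 1:2]))
  arrows(0, 0, sc * x$loadings[, 1] * 0.8, sc * x$loadings[, 2] * 0.8,
         length = 0.08, col = "firebrick")
  text(sc * x$loadings[, 1] * 0.9, sc * x$loadings[, 2] * 0.9,
       rownames(x$loadings), cex = 0.7, col = "firebrick")
  invisible(x)
}
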