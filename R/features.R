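# Assembly of the pair-level feature table that enters the mixed models.

#' Build the pair feature table
#'
#' Joins per-pair log substitution rates with the PC1/PC2 property-difference
#' scores and the genetic-code mutational covariates, producing the data
#' frame the mixed models are fitted to.
#'
#' @param model An `exchange_model` or `nonreversible_model`, or a
#'   ready-made table from [pair_rates()].
#' @param pca A [pair_pca()] result (scores are joined by unordered pair, so
#'   both directions of a pair share one score).
#' @param metrics Genetic-code metric table; defaults to
#'   [pair_metric_table()].
#' @param mode `"directed"` (380 rows; `aa1` = donor, `aa2` = acceptor) or
#'   `"undirected"` (190 rows). Ignored when `model` is already a rate table.
#' @param normalize,log_base Passed to [pair_rates()] when `model` is a model
#'   object.
#' @return A data frame with columns `aa1`, `aa2`, `rate`, `log_rate`,
#'   `PC1`, `PC2`, `min_steps`, `gc_diff`, `pyr_diff`; attributes carry the
#'   mode and model name.
#' @export
#' @examples
#' pca <- pair_pca(pairwise_differences(builtin_properties()),
#'                 anchors = c(PC1 = "hydropathy", PC2 = "mol_weight"))
#' m <- exchange_model(matrix(1, 20, 20), rep(0.05, 20))
#' head(feature_table(m, pca))
feature_table <- function(model, pca, metrics = pair_metric_table(),
                          mode = c("directed", "undirected"),
                          normalize = FALSE, log_base = exp(1)) {
  mode <- match.arg(mode)
  rates <- if (is.data.frame(model)) model
           else pair_rates(model, mode = mode, normalize = normalize,
                           log_base = log_base)
  mode <- attr(rates, "mode")

  out <- rates
  out$PC1 <- pc_scores(pca, 1, rates$aa1, rates$aa2)
  out$PC2 <- pc_scores(pca, 2, rates$aa1, rates$aa2)

  mk <- .pair_key(metrics$aa1, metrics$aa2)
  m <- match(.pair_key(rates$aa1, rates$aa2), mk)
  if (anyNA(m)) stop("metric table does not cover all pairs", call. = FALSE)
  out$min_steps <- metrics$min_steps[m]
  out$gc_diff <- metrics$gc_diff[m]
  out$pyr_diff <- metrics$pyr_diff[m]
  structure(out, mode = mode, model = attr(rates, "model"),
            log_base = attr(rates, "log_base"))
}
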