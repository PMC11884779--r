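# Reading/writing empirical amino-acid model files (PAML/IQ-TREE dialects)
# and converting exchangeabilities to per-pair substitution rates.

#' Construct a reversible exchangeability model
#'
#' A time-reversible empirical amino-acid model: a symmetric, nonnegative
#' 20x20 exchangeability matrix `s` with zero diagonal, and equilibrium
#' frequencies `pi` summing to one. The instantaneous substitution rate from
#' amino acid i to j is `s[i, j] * pi[j]`.
#'
#' @param s 20x20 symmetric numeric matrix of exchangeabilities (diagonal
#'   ignored, forced to zero).
#' @param pi Numeric vector of 20 equilibrium frequencies; renormalized if the
#'   sum deviates from 1 by at most `1e-4`, otherwise an error.
#' @param name Model label.
#' @return An object of class `"exchange_model"`.
#' @export
exchange_model <- function(s, pi, name = "model") {
  s <- as.matrix(s)
  if (!all(dim(s) == c(20L, 20L)))
    stop("exchangeability matrix must be 20x20", call. = FALSE)
  if (any(s < 0)) stop("negative exchangeability values", call. = FALSE)
  diag(s) <- 0
  if (max(abs(s - t(s))) > 1e-8)
    stop("exchangeability matrix must be symmetric", call. = FALSE)
  pi <- as.numeric(pi)
  if (length(pi) != 20L) stop("need 20 equilibrium frequencies", call. = FALSE)
  if (any(pi <= 0)) stop("equilibrium frequencies must be positive", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-4)
    stop(sprintf("equilibrium frequencies sum to %.6f (must be 1 within 1e-4)",
                 sum(pi)), call. = FALSE)
  pi <- pi / sum(pi)
  dimnames(s) <- list(.AA_ORDER, .AA_ORDER)
  structure(list(s = s, pi = setNames(pi, .AA_ORDER), name = name,
                 reversible = TRUE),
            class = "exchange_model")
}

#' Construct a non-reversible rate model
#'
#' A time non-reversible amino-acid model: a full 20x20 matrix of directed
#' instantaneous rates with nonnegative off-diagonal entries. The diagonal is
#' ignored on input (it is the usual negative row sum and never enters pair
#' tables).
#'
#' @param q 20x20 numeric matrix of directed rates.
#' @param pi Optional numeric vector of 20 frequencies (metadata only).
#' @param name Model label.
#' @return An object of class `"nonreversible_model"`.
#' @export
nonreversible_model <- function(q, pi = NULL, name = "model") {
  q <- as.matrix(q)
  if (!all(dim(q) == c(20L, 20L)))
    stop("rate matrix must be 20x20", call. = FALSE)
  off <- q; diag(off) <- 0
  if (any(off < 0)) stop("negative off-diagonal rate values", call. = FALSE)
  diag(q) <- 0
  dimnames(q) <- list(.AA_ORDER, .AA_ORDER)
  if (!is.null(pi)) {
    pi <- as.numeric(pi)
    if (length(pi) != 20L) stop("need 20 frequencies", call. = FALSE)
    if (abs(sum(pi) - 1) > 1e-4)
      stop("frequencies must sum to 1 within 1e-4", call. = FALSE)
    pi <- setNames(pi / sum(pi), .AA_ORDER)
  }
  structure(list(q = q, pi = pi, name = name, reversible = FALSE),
            class = "nonreversible_model")
}

#' @export
print.exchange_model <- function(x, ...) {
  cat("Reversible amino-acid exchangeability model:", x$name, "\n")
  cat("  mean exchangeability:", format(mean(x$s[lower.tri(x$s)]), digits = 4),
      "\n  frequency range: [", format(min(x$pi), digits = 3), ",",
      format(max(x$pi), digits = 3), "]\n")
  invisible(x)
}

#' @export
print.nonreversible_model <- function(x, ...) {
  off <- x$q[row(x$q) != col(x$q)]
  cat("Non-reversible amino-acid rate model:", x$name, "\n")
  cat("  mean directed rate:", format(mean(off), digits = 4),
      if (is.null(x$pi)) "\n  (no frequencies)\n" else "\n")
  invisible(x)
}

# numeric tokens from a model file, '#'-comments and blank lines stripped
.numeric_tokens <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(trimws(lines), "[ \t]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals))
    stop("non-numeric token(s) in model file '", path, "': ",
         paste(utils::head(toks[is.na(vals)], 3), collapse = ", "), call. = FALSE)
  vals
}

#' Read a reversible model file (PAML dialect)
#'
#' Parses a PAML-style amino-acid model file: the 190 lower-triangular
#' exchangeabilities (rows 2..20, whitespace separated; blank lines and `#`
#' comments tolerated) followed by the 20 equilibrium frequencies.
#'
#' @param path File path.
#' @param name Model label; defaults to the file name.
#' @return An [exchange_model()].
#' @export
read_exchange_model <- function(path, name = NULL) {
  vals <- .numeric_tokens(path)
  if (length(vals) != 210L)
    stop(sprintf("expected 210 values (190 exchangeabilities + 20 frequencies) in '%s', found %d",
                 path, length(vals)), call. = FALSE)
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- .lower_by_row(vals[1:190])
  s <- s + t(s)
  exchange_model(s, vals[191:210],
                 name = if (is.null(name)) basename(path) else name)
}

# PAML files store the lower triangle row by row; R's lower.tri indexing is
# column-major, so reorder.
.lower_by_row <- function(vals) {
  m <- matrix(NA_real_, 20, 20)
  k <- 0L
  for (i in 2:20) for (j in 1:(i - 1)) {
    k <- k + 1L
    m[i, j] <- vals[k]
  }
  m[lower.tri(m)]
}

.lower_to_row_order <- function(s) {
  out <- numeric(190)
  k <- 0L
  for (i in 2:20) for (j in 1:(i - 1)) {
    k <- k + 1L
    out[k] <- s[i, j]
  }
  out
}

#' Read a non-reversible model file (full-matrix dialect)
#'
#' Parses a full 20x20 directed-rate matrix (400 whitespace-separated values,
#' row by row), optionally followed by 20 frequencies.
#'
#' @inheritParams read_exchange_model
#' @return A [nonreversible_model()].
#' @export
read_nonreversible_model <- function(path, name = NULL) {
  vals <- .numeric_tokens(path)
  if (!(length(vals) %in% c(400L, 420L)))
    stop(sprintf("expected 400 values (20x20 matrix), optionally + 20 frequencies, in '%s', found %d",
                 path, length(vals)), call. = FALSE)
  q <- matrix(vals[1:400], 20, 20, byrow = TRUE)
  pi <- if (length(vals) == 420L) vals[401:420] else NULL
  nonreversible_model(q, pi, name = if (is.null(name)) basename(path) else name)
}

#' Write a model file
#'
#' Writes a model in the dialect its class implies: lower-triangle + 20
#' frequencies for reversible models, full 20x20 matrix (+ frequencies if
#' present) for non-reversible models. Values round-trip through
#' [read_exchange_model()] / [read_nonreversible_model()].
#'
#' @param model An `exchange_model` or `nonreversible_model`.
#' @param path Output file path.
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, digits = 10) {
  fmt <- function(x) paste(format(x, digits = digits, scientific = FALSE,
                                  trim = TRUE), collapse = " ")
  if (inherits(model, "exchange_model")) {
    tri <- .lower_to_row_order(model$s)
    lines <- character(19)
    k <- 0L
    for (i in 2:20) {
      lines[i - 1L] <- fmt(tri[(k + 1):(k + i - 1L)])
      k <- k + i - 1L
    }
    lines <- c(lines, "", fmt(model$pi))
  } else if (inherits(model, "nonreversible_model")) {
    lines <- apply(model$q, 1, fmt)
    if (!is.null(model$pi)) lines <- c(lines, "", fmt(model$pi))
  } else stop("unsupported model class", call. = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Empirical model shipped with phangorn
#'
#' Convenience accessor for the empirical amino-acid models embedded in the
#' phangorn package (LG, WAG, JTT, Dayhoff, ...), returned as an
#' [exchange_model()]. LG was estimated from the Pfam alignment database and
#' is the default.
#'
#' @param name Model name as listed by phangorn (case sensitive), e.g. `"LG"`.
#' @return An [exchange_model()].
#' @export
empirical_model <- function(name = "LG") {
  if (!requireNamespace("phangorn", quietly = TRUE))
    stop("the phangorn package is required for empirical_model()", call. = FALSE)
  ns <- asNamespace("phangorn")
  key <- paste0(".", name)
  if (!exists(key, envir = ns))
    stop("unknown phangorn model: ", name, call. = FALSE)
  obj <- get(key, envir = ns)
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- obj$Q  # phangorn stores column-major lower triangle
  s <- s + t(s)
  exchange_model(s, obj$bf / sum(obj$bf), name = name)
}

#' Per-pair substitution rates from a model
#'
#' Converts a model to a long table of substitution rates. For a reversible
#' model the directed rate from i to j is the exchangeability times the
#' frequency of the target amino acid, `s[i, j] * pi[j]`; for a
#' non-reversible model it is the matrix entry `q[i, j]`. In `"undirected"`
#' mode the rate of a pair is the arithmetic mean of its two directed rates.
#'
#' @param model An `exchange_model` or `nonreversible_model`.
#' @param mode `"directed"` (380 rows) or `"undirected"` (190 rows).
#' @param normalize If `TRUE`, divide all rates by their mean before taking
#'   logs (only relative rates matter to regression slopes).
#' @param log_base Base of the logarithm; natural log by default.
#' @return A data frame with columns `aa1`, `aa2` (donor and acceptor in
#'   directed mode; `aa1` before `aa2` in PAML order otherwise), `rate`, and
#'   `log_rate`, with attributes `mode`, `model`, `log_base` and `normalized`.
#' @export
#' @examples
#' m <- exchange_model(matrix(1, 20, 20), rep(0.05, 20))
#' head(pair_rates(m))
pair_rates <- function(model, mode = c("directed", "undirected"),
                       normalize = FALSE, log_base = exp(1)) {
  mode <- match.arg(mode)
  rate_of <- if (inherits(model, "exchange_model")) {
    function(i, j) model$s[i, j] * model$pi[j]
  } else if (inherits(model, "nonreversible_model")) {
    function(i, j) model$q[i, j]
  } else stop("unsupported model class", call. = FALSE)

  idx <- combn(20L, 2L)
  i <- idx[1, ]; j <- idx[2, ]
  fwd <- mapply(rate_of, i, j)
  rev <- mapply(rate_of, j, i)
  if (mode == "directed") {
    out <- data.frame(
      aa1 = c(.AA_ORDER[i], .AA_ORDER[j]),
      aa2 = c(.AA_ORDER[j], .AA_ORDER[i]),
      rate = c(fwd, rev), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(aa1 = .AA_ORDER[i], aa2 = .AA_ORDER[j],
                      rate = (fwd + rev) / 2, stringsAsFactors = FALSE)
  }
  if (normalize) out$rate <- out$rate / mean(out$rate)
  bad <- out$rate <= 0
  if (any(bad))
    stop("degenerate (zero or negative) rate for pair(s): ",
         paste(paste0(out$aa1[bad], ":", out$aa2[bad]), collapse = ", "),
         call. = FALSE)
  out$log_rate <- log(out$rate, base = log_base)
  structure(out, mode = mode, model = model$name, log_base = log_base,
            normalized = normalize)
}

#' Similarity of two rate tables
#'
#' Pearson correlation of log rates across matched pairs of two
#' [pair_rates()] tables computed in the same mode.
#'
#' @param a,b Pair-rate tables from [pair_rates()].
#' @return Pearson correlation coefficient.
#' @export
matrix_similarity <- function(a, b) {
  if (!identical(attr(a, "mode"), attr(b, "mode")))
    stop("rate tables have different modes (directed vs undirected)", call. = FALSE)
  ka <- paste(a$aa1, a$aa2); kb <- paste(b$aa1, b$aa2)
  m <- match(ka, kb)
  if (anyNA(m)) stop("rate tables do not cover the same pairs", call. = FALSE)
  cor(a$log_rate, b$log_rate[m])
}
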