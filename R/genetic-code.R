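# Genetic-code derived covariates: per-amino-acid codon GC content and
# pyrimidine proportion, and the minimum number of nucleotide changes
# separating the codon sets of two amino acids.

.NUC <- c("T", "C", "A", "G")

# Build the standard genetic code (NCBI translation table 1) once, via
# seqinr's translation, and cache codon <-> amino-acid maps.
.genetic_code <- function() {
  if (!is.null(.aasubst_cache$code)) return(.aasubst_cache$code)
  codons <- as.vector(outer(as.vector(outer(.NUC, .NUC, paste0)), .NUC, paste0))
  aa <- vapply(codons, function(cd) seqinr::translate(strsplit(cd, "")[[1]], numcode = 1),
               character(1))
  sense <- codons[aa != "*"]
  aa_sense <- aa[aa != "*"]
  stopifnot(length(sense) == 61L, all(aa_sense %in% .AA_ORDER))
  code <- list(
    codon_to_aa = setNames(aa, codons),
    aa_to_codons = split(sense, factor(aa_sense, levels = .AA_ORDER))
  )
  .aasubst_cache$code <- code
  code
}

.normalize_codon <- function(codon) {
  codon <- toupper(gsub("U", "T", toupper(as.character(codon))))
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad))
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         call. = FALSE)
  codon
}

#' Translate codons under the standard genetic code
#'
#' Maps nucleotide triplets to one-letter amino-acid codes (or `"*"` for stop
#' codons) under NCBI translation table 1. RNA input (`U`) is accepted and
#' normalized to DNA (`T`).
#'
#' @param codon Character vector of nucleotide triplets.
#' @return Character vector of one-letter amino-acid codes, `"*"` for stops.
#' @export
#' @examples
#' codon_to_aa(c("ATG", "UGG", "TAA"))
codon_to_aa <- function(codon) {
  codon <- .normalize_codon(codon)
  unname(.genetic_code()$codon_to_aa[codon])
}

#' Sense codons of an amino acid
#'
#' @param aa One-letter amino-acid code.
#' @return Character vector of the codons encoding `aa` in the standard
#'   genetic code.
#' @export
#' @examples
#' codons_for("W")
#' codons_for("L")
codons_for <- function(aa) {
  aa <- .check_aa(aa)
  if (length(aa) != 1L) stop("codons_for() takes a single amino acid", call. = FALSE)
  .genetic_code()$aa_to_codons[[aa]]
}

.codon_base_fraction <- function(codon, bases) {
  vapply(strsplit(codon, ""), function(b) sum(b %in% bases) / 3, numeric(1))
}

#' Mean codon GC content of amino acids
#'
#' For each amino acid, the fraction of G or C bases averaged uniformly over
#' all its sense codons.
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Numeric vector in `[0, 1]`, named by `aa`.
#' @export
#' @examples
#' gc_content("W")  # TGG: 2/3
#' gc_content(aa_order())
gc_content <- function(aa = aa_order()) {
  aa <- .check_aa(aa)
  code <- .genetic_code()
  setNames(vapply(aa, function(a)
    mean(.codon_base_fraction(code$aa_to_codons[[a]], c("G", "C"))), numeric(1)), aa)
}

#' Mean codon pyrimidine proportion of amino acids
#'
#' For each amino acid, the fraction of pyrimidine bases (C or T) averaged
#' uniformly over all its sense codons. The absolute difference of this
#' quantity between two amino acids is used as a transition:transversion
#' proxy: pairs whose codon sets differ more in pyrimidine content require,
#' on average, more transversion mutations to interconvert.
#'
#' @inheritParams gc_content
#' @return Numeric vector in `[0, 1]`, named by `aa`.
#' @export
#' @examples
#' pyrimidine_proportion("F")  # TTT/TTC: all pyrimidine
#' pyrimidine_proportion("K")  # AAA/AAG: none
pyrimidine_proportion <- function(aa = aa_order()) {
  aa <- .check_aa(aa)
  code <- .genetic_code()
  setNames(vapply(aa, function(a)
    mean(.codon_base_fraction(code$aa_to_codons[[a]], c("C", "T"))), numeric(1)), aa)
}

#' Minimum mutational steps between two amino acids
#'
#' The smallest Hamming distance between any codon of `aa1` and any codon of
#' `aa2` in the standard genetic code: 0 for identical amino acids, otherwise
#' 1, 2 or 3. Intermediate codons are not required to be sense codons.
#'
#' @param aa1,aa2 One-letter amino-acid codes (vectorized, recycled).
#' @return Integer vector of minimum nucleotide differences.
#' @export
#' @examples
#' min_mutational_steps("F", "L")  # 1
#' min_mutational_steps("M", "Y")  # 3
min_mutational_steps <- function(aa1, aa2) {
  aa1 <- .check_aa(aa1); aa2 <- .check_aa(aa2)
  n <- max(length(aa1), length(aa2))
  aa1 <- rep_len(aa1, n); aa2 <- rep_len(aa2, n)
  code <- .genetic_code()
  split3 <- function(x) do.call(rbind, strsplit(x, ""))
  vapply(seq_len(n), function(k) {
    if (aa1[k] == aa2[k]) return(0L)
    c1 <- split3(code$aa_to_codons[[aa1[k]]])
    c2 <- split3(code$aa_to_codons[[aa2[k]]])
    best <- 3L
    for (i in seq_len(nrow(c1))) {
      d <- rowSums(c2 != matrix(c1[i, ], nrow(c2), 3, byrow = TRUE))
      best <- min(best, min(d))
    }
    as.integer(best)
  }, integer(1))
}

#' Genetic-code metrics for all unordered amino-acid pairs
#'
#' Builds the 190-row table of mutational covariates: minimum mutational
#' steps, absolute difference in mean codon GC content, and absolute
#' difference in mean codon pyrimidine proportion, for every unordered pair
#' of distinct amino acids.
#'
#' @return A data frame with columns `aa1`, `aa2` (with `aa1` before `aa2` in
#'   PAML order), `min_steps` (integer in 1..3), `gc_diff` and `pyr_diff`
#'   (both in `[0, 1]`).
#' @export
#' @examples
#' head(pair_metric_table())
pair_metric_table <- function() {
  idx <- combn(20L, 2L)
  aa1 <- .AA_ORDER[idx[1, ]]
  aa2 <- .AA_ORDER[idx[2, ]]
  gc <- gc_content()
  pyr <- pyrimidine_proportion()
  data.frame(
    aa1 = aa1, aa2 = aa2,
    min_steps = min_mutational_steps(aa1, aa2),
    gc_diff = abs(unname(gc[aa1] - gc[aa2])),
    pyr_diff = abs(unname(pyr[aa1] - pyr[aa2])),
    stringsAsFactors = FALSE
  )
}
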