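# Amino-acid physicochemical property tables: AAindex parsing, the builtin
# scale set, pairwise absolute differences, and property correlations.

# three-letter names in PAML order, for mapping seqinr's aaindex vectors
.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
          "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")

# builtin scales: name -> AAindex accession. The set covers the charge /
# hydrophobicity family (hydropathy, hydrophobicity, contact energy,
# flexibility, polarity, net charge, isoelectric point) and the size family
# (molecular weight, volume, maximum accessible surface area), so that the
# pair-difference PCA separates into a charge/hydrophobicity component and a
# size component.
.BUILTIN_ACCESSIONS <- c(
  hydropathy      = "KYTJ820101",  # Kyte-Doolittle hydropathy
  hydrophobicity  = "FASG890101",  # Fasman hydrophobicity
  contact_energy  = "MIYS990101",  # Miyazawa-Jernigan partition energies
  flexibility     = "BHAR880101",  # Bhaskaran-Ponnuswamy average flexibility
  polarity        = "GRAR740102",  # Grantham polarity
  net_charge      = "KLEP840101",  # Klein net charge
  iso_point       = "ZIMJ680104",  # Zimmerman isoelectric point
  mol_weight      = "FASG760101",  # Fasman molecular weight
  volume          = "GRAR740103",  # Grantham volume
  max_asa         = "CHOC760101"   # Chothia accessible surface area (tripeptide)
)

.property_table <- function(values, provenance) {
  stopifnot(is.matrix(values), nrow(values) == 20L)
  rownames(values) <- .AA_ORDER
  structure(values, provenance = provenance, class = c("property_table", "matrix"))
}

#' @export
print.property_table <- function(x, ...) {
  cat("Amino-acid property table: 20 x", ncol(x), "scales\n")
  cat("  ", paste(colnames(x), collapse = ", "), "\n")
  prov <- attr(x, "provenance")
  if (!is.null(prov)) cat("  provenance:", paste(prov, collapse = ", "), "\n")
  invisible(x)
}

#' Builtin physicochemical property scales
#'
#' Returns the package's default set of ten AAindex scales, loaded from the
#' AAindex distribution shipped with seqinr, mapped to the 20 amino acids in
#' PAML order. The set spans a charge/hydrophobicity family (Kyte-Doolittle
#' hydropathy, Fasman hydrophobicity, Miyazawa-Jernigan contact energy,
#' flexibility, Grantham polarity, net charge, isoelectric point) and a size
#' family (molecular weight, Grantham volume, maximum accessible surface
#' area). AAindex accessions are recorded in the `provenance` attribute.
#'
#' @return A 20 x 10 `property_table` matrix (rows in PAML order) with a
#'   `provenance` attribute of AAindex accessions.
#' @export
#' @examples
#' p <- builtin_properties()
#' attr(p, "provenance")
builtin_properties <- function() {
  if (!is.null(.aasubst_cache$builtin)) return(.aasubst_cache$builtin)
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  vals <- vapply(.BUILTIN_ACCESSIONS, function(acc) {
    rec <- aaindex[[acc]]
    if (is.null(rec)) stop("accession not found in seqinr's aaindex: ", acc,
                           call. = FALSE)
    v <- rec$I[match(.AA3, names(rec$I))]
    if (anyNA(v)) stop("missing values in builtin scale ", acc, call. = FALSE)
    unname(v)
  }, numeric(20))
  out <- .property_table(vals, provenance = .BUILTIN_ACCESSIONS)
  .aasubst_cache$builtin <- out
  out
}

#' Parse an AAindex1 flat file
#'
#' Reads amino-acid property records from the AAindex1 format: records are
#' separated by `//`; each has an `H` line (accession), a `D` line
#' (description), and an `I` block whose header lists the amino acids as
#' `A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V` followed by two lines of ten
#' values each (first line = A R N D C Q E G H I, second = L K M F P S T W Y
#' V). `NA` values are handled per `na_action`.
#'
#' @param path Path to an AAindex1 flat file.
#' @param na_action `"drop"` (default) drops any property containing missing
#'   values with a warning; `"error"` fails.
#' @return A `property_table` (20 x P, PAML row order) with accessions in the
#'   `provenance` attribute and descriptions in the `description` attribute.
#' @export
parse_aaindex <- function(path, na_action = c("drop", "error")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("AAindex file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, head(lines == "//", -1))))
  acc <- character(0); desc <- character(0); cols <- list()
  for (rec in recs) {
    h <- grep("^H ", rec, value = TRUE)
    if (length(h) == 0) next  # trailing blank record
    a <- trimws(sub("^H ", "", h[1]))
    if (a %in% acc) stop("duplicate accession in AAindex file: ", a, call. = FALSE)
    d <- trimws(sub("^D ", "", grep("^D ", rec, value = TRUE)[1]))
    ihdr <- grep("^I ", rec)
    if (length(ihdr) != 1)
      stop("malformed record (no I block): ", a, call. = FALSE)
    if (length(rec) < ihdr + 2)
      stop("malformed I block (truncated) in record ", a, call. = FALSE)
    toks <- unlist(strsplit(trimws(rec[(ihdr + 1):(ihdr + 2)]), "[ \t]+"))
    toks <- toks[nzchar(toks)]
    if (length(toks) != 20)
      stop(sprintf("malformed I block in record %s: expected 20 values, found %d",
                   a, length(toks)), call. = FALSE)
    v <- suppressWarnings(as.numeric(toks))
    v[toks %in% c("NA", "-")] <- NA
    if (any(is.na(v) & !(toks %in% c("NA", "-"))))
      stop("non-numeric value in I block of record ", a, call. = FALSE)
    # I-block order: A R N D C Q E G H I / L K M F P S T W Y V == PAML order
    if (anyNA(v)) {
      if (na_action == "error")
        stop("missing values in record ", a, call. = FALSE)
      warning("dropping property ", a, " (missing values)", call. = FALSE)
      next
    }
    acc <- c(acc, a); desc <- c(desc, d); cols <- c(cols, list(v))
  }
  if (length(cols) == 0) stop("no complete records in '", path, "'", call. = FALSE)
  vals <- do.call(cbind, cols)
  colnames(vals) <- acc
  out <- .property_table(vals, provenance = setNames(acc, acc))
  attr(out, "description") <- setNames(desc, acc)
  out
}

#' Read a property table from CSV
#'
#' Expects one row per amino acid with an `aa` column of one-letter codes
#' (any order; all 20 required) and one numeric column per property.
#'
#' @param path CSV path.
#' @return A `property_table`.
#' @export
read_property_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"aa" %in% names(d)) stop("CSV must have an 'aa' column", call. = FALSE)
  m <- match(.AA_ORDER, toupper(d$aa))
  if (anyNA(m)) stop("CSV must contain all 20 amino acids", call. = FALSE)
  vals <- as.matrix(d[m, setdiff(names(d), "aa"), drop = FALSE])
  if (anyNA(vals)) stop("missing values in property CSV", call. = FALSE)
  .property_table(vals, provenance = setNames(colnames(vals), colnames(vals)))
}

#' Pairwise absolute property differences
#'
#' For every unordered pair of distinct amino acids, the absolute difference
#' `|x_i - x_j|` in each property, on raw scale units (standardization, if
#' any, happens in the PCA step).
#'
#' @param properties A `property_table` (or plain 20 x P matrix in PAML row
#'   order).
#' @return A data frame of 190 rows: `aa1`, `aa2` (aa1 before aa2 in PAML
#'   order) followed by one nonnegative column per property.
#' @export
pairwise_differences <- function(properties) {
  p <- unclass(properties)
  stopifnot(nrow(p) == 20L)
  idx <- combn(20L, 2L)
  d <- abs(p[idx[1, ], , drop = FALSE] - p[idx[2, ], , drop = FALSE])
  out <- data.frame(aa1 = .AA_ORDER[idx[1, ]], aa2 = .AA_ORDER[idx[2, ]],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(d))
}

#' Correlations among property scales
#'
#' Pearson correlation matrix of the property scales across the 20 amino
#' acids.
#'
#' @param properties A `property_table`.
#' @return Symmetric P x P correlation matrix.
#' @export
#' @examples
#' r <- property_correlations(builtin_properties())
#' r["mol_weight", "volume"]
property_correlations <- function(properties) {
  p <- unclass(properties)
  sds <- apply(p, 2, sd)
  if (any(sds == 0))
    stop("constant property column(s): ",
         paste(colnames(p)[sds == 0], collapse = ", "), call. = FALSE)
  cor(p)
}
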