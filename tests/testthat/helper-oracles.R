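# Independent oracles and fixture builders shared across the test files.

# Brute-force genetic-code oracle built on Biostrings' standard code table,
# independent of the package's own implementation.
oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  list(codon_aa = gc, sense = sense, aa = unname(gc[sense]))
})

oracle_codons_for <- function(a) oracle_code$sense[oracle_code$aa == a]

oracle_base_frac <- function(codons, bases) {
  mean(vapply(strsplit(codons, ""), function(b) sum(b %in% bases) / 3, numeric(1)))
}

oracle_min_steps <- function(a, b) {
  c1 <- oracle_codons_for(a); c2 <- oracle_codons_for(b)
  best <- 3L
  for (x in c1) for (y in c2) {
    d <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (d < best) best <- d
  }
  best
}

# a reversible model file with uniform exchangeabilities and frequencies
write_uniform_model <- function(path, s = 1, pi = rep(0.05, 20)) {
  lines <- vapply(2:20, function(i) paste(rep(format(s), i - 1), collapse = " "),
                  character(1))
  writeLines(c("# uniform synthetic fixture", lines, "",
               paste(format(pi), collapse = " ")), path)
  path
}

# a random valid reversible model (positive exchangeabilities, dirichlet-ish pi)
random_exchange_model <- function(seed = 1) {
  set.seed(seed)
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- exp(rnorm(190, 0, 1))
  s <- s + t(s)
  pi <- rgamma(20, 5, 1); pi <- pi / sum(pi)
  exchange_model(s, pi, name = "random")
}

# an AAindex1-format record block
aaindex_record <- function(acc, desc, values) {
  stopifnot(length(values) == 20)
  fmt <- function(v) paste(sprintf("%8s", ifelse(is.na(v), "NA", format(v))),
                           collapse = "")
  c(paste("H", acc), paste("D", desc),
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    fmt(values[1:10]), fmt(values[11:20]), "//")
}
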