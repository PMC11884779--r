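# Model-file IO and exchangeability-to-rate conversion.

test_that("uniform reversible fixture parses to the expected model", {
  f <- withr::local_tempfile(fileext = ".dat")
  write_uniform_model(f)
  m <- read_exchange_model(f)
  expect_s3_class(m, "exchange_model")
  off <- m$s[row(m$s) != col(m$s)]
  expect_true(all(off == 1))
  expect_equal(unname(m$pi), rep(0.05, 20))
  rt <- pair_rates(m, mode = "directed")
  expect_equal(nrow(rt), 380L)
  expect_true(all(abs(rt$rate - 0.05) < 1e-12))
})

test_that("reversible parser rejects malformed files", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(paste(rep("1", 189 + 20), collapse = " "), f)
  expect_error(read_exchange_model(f), "expected 210 values.*found 209")
  writeLines(c(paste(rep("1", 189), collapse = " "), "-1",
               paste(rep("0.05", 20), collapse = " ")), f)
  expect_error(read_exchange_model(f), "negative")
  writeLines(c(paste(rep("1", 190), collapse = " "),
               paste(rep("0.2", 20), collapse = " ")), f)
  expect_error(read_exchange_model(f), "sum")
  writeLines(c(paste(rep("1", 190), collapse = " "), "x",
               paste(rep("0.05", 19), collapse = " ")), f)
  expect_error(read_exchange_model(f), "non-numeric")
})

test_that("write/read round-trips reversible models", {
  m <- random_exchange_model(seed = 42)
  f <- withr::local_tempfile(fileext = ".dat")
  write_model(m, f)
  m2 <- read_exchange_model(f)
  expect_equal(m2$s, m$s, tolerance = 1e-8)
  expect_equal(m2$pi, m$pi, tolerance = 1e-8)
})

test_that("non-reversible parser preserves asymmetry and validates input", {
  set.seed(7)
  q <- matrix(exp(rnorm(400)), 20, 20)
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(apply(q, 1, function(r) paste(format(r, digits = 12), collapse = " ")), f)
  m <- read_nonreversible_model(f)
  expect_s3_class(m, "nonreversible_model")
  off <- row(q) != col(q)
  expect_equal(unname(m$q[off]), unname(q[off]), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(m$q["A", "R"], m$q["R", "A"])))

  # symmetric input -> equal directed rates both ways
  qs <- (q + t(q)) / 2
  writeLines(apply(qs, 1, function(r) paste(format(r, digits = 12), collapse = " ")), f)
  rt <- pair_rates(read_nonreversible_model(f), mode = "directed")
  key <- paste(rt$aa1, rt$aa2)
  rev_rate <- rt$rate[match(paste(rt$aa2, rt$aa1), key)]
  expect_equal(rt$rate, rev_rate, tolerance = 1e-9)

  q2 <- q; q2[1, 2] <- -0.5
  writeLines(apply(q2, 1, function(r) paste(format(r, digits = 12), collapse = " ")), f)
  expect_error(read_nonreversible_model(f), "negative")
})

test_that("round-trip preserves non-reversible models including frequencies", {
  set.seed(11)
  q <- matrix(exp(rnorm(400)), 20, 20)
  pi <- rgamma(20, 4); pi <- pi / sum(pi)
  m <- nonreversible_model(q, pi)
  f <- withr::local_tempfile(fileext = ".dat")
  write_model(m, f)
  m2 <- read_nonreversible_model(f)
  expect_equal(m2$q, m$q, tolerance = 1e-8)
  expect_equal(m2$pi, m$pi, tolerance = 1e-8)
})

test_that("constructed Q obeys detailed balance for reversible models", {
  m <- random_exchange_model(seed = 3)
  rt <- pair_rates(m, mode = "directed")
  key <- paste(rt$aa1, rt$aa2)
  rev_rate <- rt$rate[match(paste(rt$aa2, rt$aa1), key)]
  ratio <- rt$rate / rev_rate
  expected <- m$pi[rt$aa2] / m$pi[rt$aa1]
  expect_equal(unname(ratio), unname(expected), tolerance = 1e-10)
})

test_that("undirected rates are the mean of the two directions", {
  m <- random_exchange_model(seed = 5)
  d <- pair_rates(m, mode = "directed")
  u <- pair_rates(m, mode = "undirected")
  expect_equal(nrow(u), 190L)
  key <- paste(d$aa1, d$aa2)
  fwd <- d$rate[match(paste(u$aa1, u$aa2), key)]
  rev <- d$rate[match(paste(u$aa2, u$aa1), key)]
  expect_equal(u$rate, (fwd + rev) / 2)
  # algebraic identity: mean rate = s_ij (pi_i + pi_j) / 2
  i <- match(u$aa1, aa_order()); j <- match(u$aa2, aa_order())
  expect_equal(u$rate, m$s[cbind(i, j)] * (m$pi[i] + m$pi[j]) / 2,
               ignore_attr = TRUE)
})

test_that("zero rates are a named degenerate-rate error", {
  s <- matrix(1, 20, 20); s[1, 2] <- s[2, 1] <- 0
  m <- exchange_model(s, rep(0.05, 20))
  expect_error(pair_rates(m), "degenerate.*A:R|degenerate.*R:A")
})

test_that("rate normalization rescales to mean 1 without changing structure", {
  m <- random_exchange_model(seed = 9)
  rt <- pair_rates(m, normalize = TRUE)
  expect_equal(mean(rt$rate), 1)
  rt0 <- pair_rates(m)
  expect_equal(cor(rt$log_rate, rt0$log_rate), 1)
})

test_that("matrix similarity behaves as a correlation", {
  m <- random_exchange_model(seed = 1)
  a <- pair_rates(m)
  expect_equal(matrix_similarity(a, a), 1)
  b <- a
  b$log_rate <- -a$log_rate
  expect_equal(matrix_similarity(a, b), -1)
  u <- pair_rates(m, mode = "undirected")
  expect_error(matrix_similarity(a, u), "mode")
})

test_that("the embedded LG model satisfies the reversible invariants", {
  skip_if_not_installed("phangorn")
  m <- empirical_model("LG")
  expect_equal(sum(m$pi), 1, tolerance = 1e-8)
  expect_true(all(m$s[lower.tri(m$s)] > 0))
  expect_equal(m$s, t(m$s))
})
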