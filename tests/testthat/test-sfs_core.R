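# Spectrum construction, projection, folding, rescaling, residuals.

test_that("build_spectrum tallies simple configurations correctly", {
  # one SNP heterozygous in exactly one population-1 individual
  calls <- matrix(0L, 10, 1)
  calls[1, 1] <- 1L
  g <- genotype_matrix(calls, rep(c("bornean", "sumatran"), each = 5))
  s <- build_spectrum(g, min_quality = 0)
  expect_equal(s$sample_sizes, c(10L, 10L))
  expect_equal(s$counts[2, 1], 1)
  expect_equal(segregating_total(s), 1)

  # monomorphic site lands in the masked (0,0) corner
  g0 <- genotype_matrix(matrix(0L, 10, 1), rep(c("b", "s"), each = 5))
  s0 <- build_spectrum(g0, min_quality = 0)
  expect_equal(s0$counts[1, 1], 1)
  expect_true(s0$mask[1, 1])
  expect_equal(segregating_total(s0), 0)
})

test_that("build_spectrum matches a brute-force per-site tally oracle", {
  g <- toy_genotypes(seed = 42, n_ind = 5, n_sites = 200)
  s <- build_spectrum(g, min_quality = 0)
  oracle <- matrix(0, 11, 11)
  for (k in seq_len(200)) {
    d1 <- sum(g$calls[1:5, k]); d2 <- sum(g$calls[6:10, k])
    oracle[d1 + 1, d2 + 1] <- oracle[d1 + 1, d2 + 1] + 1
  }
  expect_equal(unname(s$counts), oracle)
})

test_that("build_spectrum applies the quality filter and missing-site modes", {
  calls <- matrix(1L, 4, 3)
  qual <- matrix(1, 4, 3)
  qual[1, 1] <- 0.95       # at threshold -> excluded
  g <- genotype_matrix(calls, c("a", "a", "b", "b"), quality = qual)
  s_drop <- build_spectrum(g, min_quality = 0.95, missing = "drop")
  expect_equal(segregating_total(s_drop), 2)   # site 1 dropped
  s_proj <- build_spectrum(g, min_quality = 0.95, missing = "project")
  # site 1 projected from 2 to 2 pop-1 chromosomes... smallest fully-called
  expect_equal(s_proj$sample_sizes, c(2L, 4L))
  expect_equal(segregating_total(s_proj), 3)
  expect_error(build_spectrum(g, min_quality = 2), "min_quality")
})

test_that("build_spectrum rejects invalid inputs", {
  expect_error(genotype_matrix(matrix(0L, 3, 2), c("a", "a", "a")),
               "exactly two")
  expect_error(genotype_matrix(matrix(3L, 4, 2), c("a", "a", "b", "b")),
               "mixed ploidy")
  expect_error(build_spectrum(42), "genotype_matrix")
})

test_that("project handles identity, the singleton case, and errors", {
  s <- random_spectrum_1d(10, 1)
  expect_identical(project(s, 10L), s)
  one <- spectrum(c(0, 1, 0, 0, 0), 4)
  p <- project(one, 2)
  expect_equal(p$counts, c(1 / 2, 1 / 2, 0))
  expect_true(p$mask[1])
  expect_error(project(one, 6), "project up")
  expect_error(project(one, 1), ">= 2")
})

test_that("projection matches a Monte-Carlo subsampling oracle within 3 SE", {
  s <- random_spectrum_1d(10, 7)
  p <- project(s, 6)
  ndraw <- 1e5
  set.seed(99)
  mc <- matrix(0, 9, 7)  # source bins 1..9 x target bins 0..6
  for (i in 1:9) {
    draws <- stats::rhyper(ndraw, i, 10 - i, 6)
    mc[i, ] <- tabulate(draws + 1L, 7) / ndraw
  }
  expected <- as.numeric(s$counts[2:10] %*% mc)
  se <- sqrt(as.numeric(s$counts[2:10]^2 %*% (mc * (1 - mc) / ndraw)))
  i <- 2:6  # unmasked target bins
  expect_true(all(abs(p$counts[i] - expected[i]) <= 3 * se[i] + 1e-12))
})

test_that("projection is linear and never increases the segregating total", {
  A <- random_spectrum_1d(10, 2); B <- random_spectrum_1d(10, 3)
  AB <- spectrum(2 * A$counts + 3 * B$counts, 10)
  lhs <- project(AB, 6)$counts
  rhs <- 2 * project(A, 6)$counts + 3 * project(B, 6)$counts
  expect_equal(lhs, rhs, tolerance = 1e-12)
  for (seed in 1:5) {
    s <- random_spectrum_2d(8, 8, seed)
    expect_lte(segregating_total(project(s, c(4, 6))),
               segregating_total(s) + 1e-9)
  }
})

test_that("fold mirrors, preserves totals, and rejects double folding", {
  s <- spectrum(c(0, 3, 2, 1, 0), 4)
  f <- fold(s)
  expect_equal(f$counts[2:3], c(4, 2))
  expect_true(all(f$mask[4:5]))
  expect_error(fold(f), "already folded")
  for (seed in 1:5) {
    s2 <- random_spectrum_2d(8, 8, seed)
    expect_equal(segregating_total(fold(s2)), segregating_total(s2))
  }
})

test_that("fold and project commute on 1D spectra", {
  for (seed in 1:5) {
    s <- random_spectrum_1d(12, seed)
    a <- fold(project(s, 8))
    b <- project(fold(s), 8)
    expect_equal(a$counts[!a$mask], b$counts[!b$mask], tolerance = 1e-12)
  }
})

test_that("rescale_to_segregating scales unmasked entries exactly", {
  s <- random_spectrum_1d(10, 5)
  tot <- segregating_total(s)
  h <- rescale_to_segregating(s, tot / 2)
  expect_equal(h$counts[!h$mask], s$counts[!s$mask] / 2)
  expect_equal(rescale_to_segregating(s, tot)$counts, s$counts)
  empty <- spectrum(rep(0, 5), 4)
  expect_error(rescale_to_segregating(empty, 10), "zero segregating")
})

test_that("residual_spectrum has the stated closed form and antisymmetry", {
  a <- spectrum(c(0, 8, 0, 0), 3); b <- spectrum(c(0, 2, 0, 0), 3)
  r <- residual_spectrum(a, b)
  expect_equal(r[2], (8 - 2) / sqrt(5), tolerance = 1e-12)
  expect_equal(residual_spectrum(a, a)[!a$mask], rep(0, sum(!a$mask)))
  for (seed in 1:3) {
    x <- random_spectrum_2d(6, 6, seed); y <- random_spectrum_2d(6, 6, seed + 50)
    expect_equal(residual_spectrum(x, y), -residual_spectrum(y, x))
  }
  expect_error(residual_spectrum(a, random_spectrum_1d(10, 1)), "shapes")
})

test_that("spectrum text serialization round-trips bit-exactly", {
  for (s in list(random_spectrum_1d(10, 11), fold(random_spectrum_2d(8, 8, 12)))) {
    path <- tempfile(fileext = ".sfs")
    write_spectrum(s, path)
    r <- read_spectrum(path)
    expect_identical(r$counts, s$counts)
    expect_identical(r$mask, s$mask)
    expect_identical(r$folded, s$folded)
    expect_identical(r$sample_sizes, s$sample_sizes)
  }
})
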