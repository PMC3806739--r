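# Synthetic-data generators: determinism, distributional correctness,
# and round trips through the inference stages.

test_that("simulate_sfs is seeded-Poisson around the expected spectrum", {
  cache <- test_cache()
  sc <- simulation_config(gamma = -1, seed = 13)
  s1 <- simulate_sfs(sc, cache = cache)
  s2 <- simulate_sfs(sc, cache = cache)
  expect_identical(s1$counts, s2$counts)       # bit-reproducible
  # theta -> 0 gives an empty spectrum
  sc0 <- simulation_config(gamma = -1, theta_syn = 1e-12, seed = 13)
  expect_equal(segregating_total(simulate_sfs(sc0, cache = cache)), 0)
  # mean of 200 seeded draws within 3 standard errors per entry
  mu <- popgensel:::config_expected_sfs(sc, cache = cache)
  acc <- mu$counts * 0
  for (r in 1:200) {
    scr <- simulation_config(gamma = -1, seed = 1000 + r)
    acc <- acc + simulate_sfs(scr, cache = cache)$counts
  }
  m <- acc / 200
  se <- sqrt(mu$counts / 200)
  i <- !mu$mask & mu$counts > 0
  expect_true(all(abs(m[i] - mu$counts[i]) <= 3 * se[i] + 1e-9))
})

test_that("neutral simulated spectra follow the 1/i law marginally", {
  # a stationary configuration (constant sizes, no migration), where the
  # marginal expectation is the equilibrium 1/i law
  m0 <- demographic_model(T_split = 0.05, nu1_0 = 1, nu1 = 1, nu2_0 = 1,
                          nu2 = 1, m12 = 0, m21 = 0)
  sc <- simulation_config(model = m0, gamma = 0, theta_syn = 2000, seed = 17)
  s <- simulate_sfs(sc, category = "syn", control = dev_ctl())
  mg <- marginal_1d(s, 1)
  counts <- mg$counts[2:8]
  expected <- sum(counts) * (1 / (1:7)) / sum(1 / (1:7))
  # chi-square-scale agreement (7 cells) for a Poisson draw of this size
  expect_lt(sum((counts - expected)^2 / expected), 40)
})

test_that("simulate_genotypes round-trips through build_spectrum", {
  sc <- simulation_config(gamma = 0, seed = 19)
  g <- simulate_genotypes(sc, n_sites = 800, cache = test_cache())
  expect_identical(
    g$calls,
    simulate_genotypes(sc, n_sites = 800, cache = test_cache())$calls)
  s <- build_spectrum(g, min_quality = 0)
  expect_equal(segregating_total(s) + s$counts[1, 1] + s$counts[9, 9], 800)
  # the recovered frequency histogram matches the generating distribution:
  # a frequency bin i feeds sampled counts Binomial(8, i/8), so the expected
  # marginal is the bin distribution convolved with that resampling kernel
  mu <- popgensel:::config_expected_sfs(sc, cache = test_cache())
  pr <- mu$counts; pr[mu$mask] <- 0; pr <- pr / sum(pr)
  pr1 <- rowSums(pr)
  kernel <- t(vapply(0:8, function(i) stats::dbinom(0:8, 8, i / 8),
                     numeric(9)))
  exp_marg <- 800 * as.numeric(pr1 %*% kernel)
  obs <- rowSums(s$counts)
  keep <- exp_marg > 5
  expect_lt(sum((obs[keep] - exp_marg[keep])^2 / exp_marg[keep]),
            3 * sum(keep))
})

test_that("full missingness empties the spectrum in strict mode", {
  sc <- simulation_config(gamma = 0, missingness = 1, seed = 23)
  g <- simulate_genotypes(sc, n_sites = 50, cache = test_cache())
  s <- build_spectrum(g, missing = "drop")
  expect_equal(segregating_total(s), 0)
})

test_that("quality injection exercises the genotype filter", {
  sc <- simulation_config(gamma = 0, low_quality_rate = 0.3, seed = 29)
  g <- simulate_genotypes(sc, n_sites = 400, cache = test_cache())
  s_all <- build_spectrum(g, min_quality = 0)
  s_filt <- build_spectrum(g, min_quality = 0.95, missing = "drop")
  expect_lt(segregating_total(s_filt), segregating_total(s_all))
})

test_that("null MK tables have matching genome-wide ratios", {
  # all effects zero, including the genome-wide interaction
  sc <- simulation_config(seed = 37, n_genes = 2000, sigma_u = 0, sigma_v = 0,
                          mean_L_n = 3000, mean_L_s = 1000,
                          mk_beta = c(b0 = log(0.0031), bR = log(0.08 / 0.31),
                                      bF = log(2.90 / 0.31), bRF = 0))
  mk <- simulate_mk_tables(sc)
  t <- mk$tables
  ratio_poly <- (sum(t$P_n) / sum(t$L_n)) / (sum(t$P_s) / sum(t$L_s))
  ratio_div <- (sum(t$D_n) / sum(t$L_n)) / (sum(t$D_s) / sum(t$L_s))
  expect_equal(ratio_poly, ratio_div, tolerance = 0.1)
})

test_that("a strong negative effect suppresses a gene's D_n", {
  # expectation check across 100 seeded replicates
  tot_dn <- 0; tot_null <- 0
  for (r in 1:100) {
    sc <- simulation_config(seed = 4000 + r, n_genes = 2)
    mk <- simulate_mk_tables(sc, v_effects = c(-3, 0))
    tot_dn <- tot_dn + mk$tables$D_n[1]
    tot_null <- tot_null + mk$tables$D_n[2]
  }
  expect_lt(tot_dn, 0.15 * tot_null)
})

test_that("simulate_mtdna matches the target density and artifact model", {
  mt <- simulate_mtdna(10, 13648, density = 1 / 12.5, het_rate = 0.01,
                       seed = 41)
  n_snps <- length(mt$site_ids)
  expect_lt(abs(n_snps - 1090), 3 * sqrt(1090))
  frac_het <- attr(drop_heteroplasmic_sites(mt), "fraction_removed")
  expect_lt(frac_het, 5)
  # het_rate 0: the filter is the identity on sites
  mt0 <- simulate_mtdna(10, 2000, density = 0.05, het_rate = 0, seed = 43)
  expect_length(drop_heteroplasmic_sites(mt0)$site_ids,
                length(mt0$site_ids))
  # determinism
  mtb <- simulate_mtdna(10, 13648, density = 1 / 12.5, het_rate = 0.01,
                        seed = 41)
  expect_identical(mt$calls, mtb$calls)
})
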