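# DFE mixtures: grid weights, expected spectra, Poisson likelihood, fits.

test_that("dfe_weights places point masses and normalises mixtures", {
  grid <- reduced_selection_grid()
  g5 <- grid$gamma_values[5]
  w <- dfe_weights(dfe_model("point_lethal", p_point = 0.36,
                             gamma_point = g5), grid)
  expect_equal(w$weights[5], 0.36)
  expect_equal(w$lethal, 0.64)
  for (dfe in list(dfe_model("gamma", shape = 0.2, scale = 1000),
                   dfe_model("expon_lethal", mean = 10, p_lethal = 0.3),
                   dfe_model("norm_lethal", mean = -5, sd = 10,
                             p_lethal = 0.2))) {
    w <- dfe_weights(dfe, grid)
    expect_equal(sum(w$weights) + w$lethal, 1, tolerance = 1e-9)
    expect_true(all(w$weights >= 0))
  }
})

test_that("dfe_weights matches a fine-grid quadrature oracle", {
  grid <- reduced_selection_grid()
  dfe <- dfe_model("expon_lethal", mean = 25, p_lethal = 0.4)
  w <- dfe_weights(dfe, grid)
  # 1e6-point midpoint rule over |gamma| in [1e-6, 2000], log-spaced
  lg <- seq(log(1e-6), log(2000), length.out = 1e6 + 1)
  mid <- exp((lg[-1] + lg[-length(lg)]) / 2)
  dg <- diff(exp(lg))
  mass <- 0.6 * stats::dexp(mid, rate = 1 / 25) * dg
  edges <- popgensel:::grid_cell_edges(grid)
  bins <- findInterval(-mid, edges)
  oracle <- numeric(length(grid$gamma_values))
  ok <- bins >= 1 & bins <= length(oracle)
  oracle_tab <- tapply(mass[ok], bins[ok], sum)
  oracle[as.integer(names(oracle_tab))] <- oracle_tab
  expect_lt(max(abs(w$weights - oracle)), 1e-4)
})

test_that("expected_sfs_under_dfe delegates, vanishes at lethality, and is linear", {
  cache <- test_cache()
  gv <- cache$grid$gamma_values
  neutral <- dfe_model("point_lethal", p_point = 1 - 1e-12, gamma_point = -1e-6)
  s <- expected_sfs_under_dfe(cache, neutral, theta_non = 2)
  expect_equal(s$counts, 2 * cache_spectrum_at(cache, -1e-6)$counts,
               tolerance = 1e-9)
  dead <- dfe_model("point_lethal", p_point = 0, gamma_point = -1)
  expect_equal(segregating_total(expected_sfs_under_dfe(cache, dead, 5)), 0)
  # two point masses combined by hand
  k1 <- which(gv == gv[10]); k2 <- which(gv == gv[20])
  hand <- 0.3 * cache$spectra[[k1]]$counts + 0.2 * cache$spectra[[k2]]$counts
  mix1 <- expected_sfs_under_dfe(cache,
    dfe_model("point_lethal", p_point = 0.3, gamma_point = gv[10]), 1)
  mix2 <- expected_sfs_under_dfe(cache,
    dfe_model("point_lethal", p_point = 0.2, gamma_point = gv[20]), 1)
  expect_equal(mix1$counts + mix2$counts, hand, tolerance = 1e-12)
})

test_that("poisson_loglik matches closed forms and a summation oracle", {
  m <- spectrum(c(0, 1, 0), 2); d <- spectrum(c(0, 2, 0), 2)
  expect_equal(poisson_loglik(m, d), -1 + 2 * log(1) - log(2),
               tolerance = 1e-12)
  # Poisson MLE property: the data is its own best uniform scaling
  dd <- random_spectrum_2d(6, 6, 3)
  ll_at <- function(c) poisson_loglik(
    spectrum(pmax(dd$counts * c, 1e-300), c(6, 6)), dd)
  expect_gt(ll_at(1), ll_at(0.9))
  expect_gt(ll_at(1), ll_at(1.1))
  # literal per-entry summation oracle
  mm <- random_spectrum_2d(6, 6, 4)
  ref <- 0
  for (i in 1:7) for (j in 1:7) {
    if (mm$mask[i, j]) next
    ref <- ref - mm$counts[i, j] + dd$counts[i, j] * log(mm$counts[i, j]) -
      lgamma(dd$counts[i, j] + 1)
  }
  expect_equal(poisson_loglik(mm, dd), ref, tolerance = 1e-10)
  expect_true(is.infinite(poisson_loglik(spectrum(c(0, 0, 0), 2), d)))
})

test_that("class_masses reproduces the point-mass table and CDF oracle", {
  pt <- dfe_model("point_lethal", p_point = 0.36, gamma_point = -0.85)
  expect_equal(unname(class_masses(pt, 17900)), c(64, 0, 0, 36))
  all_lethal <- dfe_model("point_lethal", p_point = 0, gamma_point = -1)
  expect_equal(unname(class_masses(all_lethal, 17900)), c(100, 0, 0, 0))
  gam <- dfe_model("gamma", shape = 0.25, scale = 500)
  cm <- class_masses(gam, 10000)
  edges_g <- 2 * 10000 * c(-Inf, -1e-2, -1e-3, -1e-4, Inf)
  oracle <- 100 * diff(stats::pgamma(-edges_g, 0.25, scale = 500,
                                     lower.tail = FALSE))
  expect_equal(unname(cm), oracle, tolerance = 1e-6)
  expect_equal(sum(cm), 100, tolerance = 1e-9)
})

test_that("fitted likelihood is at least the value at the true parameters", {
  cache <- test_cache()
  truth <- dfe_model("expon_lethal", mean = 3, p_lethal = 0.5)
  mu <- expected_sfs_under_dfe(fold_cache_for_tests(cache), truth, 800)
  fit <- fit_dfe(mu, cache, "expon_lethal", theta_non = 800,
                 n_restarts = 3, seed = 5)
  ll_truth <- poisson_loglik(
    expected_sfs_under_dfe(fold_cache_for_tests(cache), truth, 800), mu)
  expect_gte(fit$loglik, ll_truth - 1e-6)
  # free-theta fits match the data total exactly (profiled theta)
  fit_free <- fit_dfe(mu, cache, "expon_lethal", n_restarts = 3, seed = 6)
  mu_fit <- expected_sfs_under_dfe(fold_cache_for_tests(cache), fit_free$dfe,
                                   fit_free$theta_non)
  expect_equal(segregating_total(mu_fit), segregating_total(mu),
               tolerance = 1e-6)
})

test_that("bootstrap intervals behave degenerately and shrink with data", {
  cache <- test_cache()
  # single unmasked nonzero entry: all resamples identical, zero width
  d <- cache$spectra[[1]]
  d <- fold(d)
  d$counts[] <- 0
  idx <- which(!d$mask)[3]
  d$counts[idx] <- 50
  ci <- bootstrap_ci(d, cache, "point_lethal", n_boot = 5, seed = 3,
                     theta_non = 100, n_restarts = 2)
  # identical resamples; width is optimizer noise only
  expect_equal(ci$intervals["gamma_point", "lower"],
               ci$intervals["gamma_point", "upper"], tolerance = 1e-3)
  # width shrinks when the data grow 100-fold
  truth <- dfe_model("point_lethal", p_point = 0.36, gamma_point = -0.85)
  fc <- fold_cache_for_tests(cache)
  mu_small <- expected_sfs_under_dfe(fc, truth, 60)
  mu_big <- expected_sfs_under_dfe(fc, truth, 6000)
  w <- sapply(list(mu_small, mu_big), function(mu) {
    ci <- bootstrap_ci(mu, cache, "point_lethal", n_boot = 12, seed = 4,
                       theta_non = segregating_total(mu) /
                         segregating_total(expected_sfs_under_dfe(fc, truth, 1)),
                       n_restarts = 2)
    diff(ci$intervals["p_point", ])
  })
  expect_lt(w[2], w[1])
})

test_that("reduced and denser gamma grids agree on recovered p_point", {
  # grid-density insensitivity at desk scale: 60- vs 120-point grids at a
  # coarse solver resolution (both caches share it, so only the gamma grid
  # differs)
  ctl <- sfs_solver_control(pts = 80, dt = 0.01, crwd = 6)
  cache60 <- build_cache(demographic_model(), reduced_selection_grid(),
                         c(8, 8), control = ctl)
  grid120 <- selection_grid(n_negative = 88, n_positive = 31)
  cache120 <- build_cache(demographic_model(), grid120, c(8, 8),
                          control = ctl)
  truth <- expected_sfs(demographic_model(), -0.85, c(8, 8), control = ctl)
  th <- 4911 / segregating_total(truth) / 0.36
  data <- fold(truth)
  data$counts <- 0.36 * th * data$counts
  p60 <- fit_dfe(data, cache60, "point_lethal", theta_non = th,
                 seed = 2)$params$p_point
  p120 <- fit_dfe(data, cache120, "point_lethal", theta_non = th,
                  seed = 2)$params$p_point
  expect_lt(abs(p60 - p120), 0.02)
})
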