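# Expected spectra under selection: closed-form equilibrium, Wright-Fisher
# matrix oracle, and the two-population diffusion solver.

test_that("equilibrium spectrum reduces to the neutral 1/i law", {
  s <- equilibrium_selected_sfs(0, 10, theta = 1)
  expect_equal(s$counts[2:10], 1 / (1:9), tolerance = 1e-6)
  expect_error(equilibrium_selected_sfs(0, 1), ">= 2")
})

test_that("strong negative selection skews mass toward singletons", {
  s <- equilibrium_selected_sfs(-50, 10)
  frac <- s$counts[2] / segregating_total(s)
  expect_gt(frac, 1 / sum(1 / (1:9)))  # neutral singleton fraction 0.3535
  # cross-check against a fine midpoint-rule Riemann oracle
  q <- (seq_len(2e5) - 0.5) / 2e5
  dens <- exp(-2 * (-50) * 0 + 0)  # placeholder to keep lints quiet
  gt <- 2 * (-50)
  a <- -gt
  dens <- exp(-a * q) * (-expm1(-a * (1 - q))) / (-expm1(-a)) / (q * (1 - q))
  for (i in c(1, 3, 9)) {
    riemann <- mean(choose(10, i) * q^i * (1 - q)^(10 - i) * dens)
    expect_equal(s$counts[i + 1], riemann, tolerance = 1e-4)
  }
})

test_that("heterozygosity is lower under negative than positive selection", {
  neg <- equilibrium_selected_sfs(-1, 2)
  pos <- equilibrium_selected_sfs(1, 2)
  expect_lt(segregating_total(neg), segregating_total(pos))
})

test_that("Wright-Fisher oracle is neutral-correct and captures lethality", {
  w <- wf_oracle_sfs(100, 0, 10)
  expect_equal(w$counts[2:10] * (1:9), rep(1, 9), tolerance = 0.01)
  lethal <- wf_oracle_sfs(100, -2000, 10)
  expect_lt(segregating_total(lethal), 1e-3 * segregating_total(w))
  expect_error(wf_oracle_sfs(1000, 0, 10), "too large")
})

test_that("diffusion equilibrium matches the closed form after projection", {
  # single-population reduction: no migration, constant sizes; the marginal
  # of the joint spectrum must sit at the selected equilibrium
  m0 <- demographic_model(T_split = 0.2, nu1_0 = 1, nu1 = 1, nu2_0 = 1,
                          nu2 = 1, m12 = 0, m21 = 0)
  for (g in c(0, -1)) {
    mg <- marginal_1d(expected_sfs(m0, g, c(8, 8), control = dev_ctl()), 1)
    e <- equilibrium_selected_sfs(g, 8)
    expect_equal(mg$counts[2:8], e$counts[2:8], tolerance = 0.01)
  }
})

test_that("joint spectrum is symmetric for an exchangeable model", {
  msym <- demographic_model(T_split = 0.05, nu1_0 = 1, nu1 = 2, nu2_0 = 1,
                            nu2 = 2, m12 = 1, m21 = 1)
  s <- expected_sfs(msym, -1, c(8, 8), control = dev_ctl())
  expect_lt(max(abs(s$counts - t(s$counts))) / max(s$counts), 1e-3)
})

test_that("diffusion agrees with the Wright-Fisher oracle out of equilibrium", {
  N <- 150; Td <- 0.2
  m2 <- demographic_model(N_anc = N, T_split = Td, nu1_0 = 2, nu1 = 2,
                          nu2_0 = 2, nu2 = 2, variant = "no_migration")
  mg <- marginal_1d(expected_sfs(m2, -2, c(8, 8), control = dev_ctl()), 1)
  wf <- wf_oracle_sfs(N, -2, 8,
                      epochs = data.frame(N = 2 * N, t_gens = round(Td * 2 * N)))
  expect_equal(mg$counts[2:8], wf$counts[2:8], tolerance = 0.05)
})

test_that("expected spectra are theta-linear and positive", {
  m <- demographic_model(T_split = 0.1)
  s1 <- expected_sfs(m, -1, c(4, 4), theta = 1, control = dev_ctl())
  s3 <- expected_sfs(m, -1, c(4, 4), theta = 3, control = dev_ctl())
  expect_equal(s3$counts, 3 * s1$counts, tolerance = 1e-10)
  expect_true(all(s1$counts[!s1$mask] > 0))
})

test_that("selection grid has the published structure", {
  g <- selection_grid()
  expect_length(g$gamma_values, 2501)
  expect_equal(range(g$gamma_values), c(-2000, 100))
  expect_true(any(g$gamma_values == 0))
  expect_false(is.unsorted(g$gamma_values, strictly = TRUE))
  expect_length(reduced_selection_grid()$gamma_values, 60)
})

test_that("cache is keyed by the grid, monotone in gamma, and reloadable", {
  cache <- test_cache()
  gv <- cache$grid$gamma_values
  expect_length(cache$spectra, 60)
  k0 <- which(gv == 0)
  direct <- expected_sfs(cache$model, 0, c(8, 8), control = dev_ctl())
  expect_equal(cache$spectra[[k0]]$counts, direct$counts, tolerance = 1e-12)
  tots <- vapply(cache$spectra, segregating_total, numeric(1))
  expect_true(all(diff(tots[gv < 0]) >= -1e-9))
  # interpolation: exact at nodes, between neighbours elsewhere
  expect_equal(cache_spectrum_at(cache, gv[5])$counts,
               cache$spectra[[5]]$counts)
  mid <- cache_spectrum_at(cache, -0.85)
  lo <- max(gv[gv < -0.85]); hi <- min(gv[gv > -0.85])
  tot_mid <- segregating_total(mid)
  expect_true(tot_mid >= segregating_total(cache_spectrum_at(cache, lo)) &&
              tot_mid <= segregating_total(cache_spectrum_at(cache, hi)))
  expect_equal(segregating_total(cache_spectrum_at(cache, -3000)), 0)
  # persistence round trip
  dir <- tempfile()
  write_cache(cache, dir)
  r <- read_cache(dir)
  expect_equal(r$spectra[[10]]$counts, cache$spectra[[10]]$counts)
  expect_equal(r$grid$gamma_values, gv)
})
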