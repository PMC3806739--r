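# Shared fixtures. Module tests use a documented desk-scale solver
# resolution (pts = 100) wherever the asserted tolerance leaves headroom;
# the acceptance suite runs at package defaults.

dev_ctl <- function() sfs_solver_control(pts = 100, dt = 0.005, crwd = 6.5)

.fixture_env <- new.env(parent = emptyenv())

# memoised reduced-grid spectra cache at desk-scale resolution
test_cache <- function() {
  if (is.null(.fixture_env$cache)) {
    .fixture_env$cache <- build_cache(demographic_model(),
                                      reduced_selection_grid(), c(8, 8),
                                      control = dev_ctl())
  }
  .fixture_env$cache
}

random_spectrum_1d <- function(n, seed) {
  set.seed(seed)
  spectrum(c(0, stats::rpois(n - 1, 20), 0), n)
}

random_spectrum_2d <- function(n1, n2, seed) {
  set.seed(seed)
  cnt <- matrix(stats::rpois((n1 + 1) * (n2 + 1), 10), n1 + 1, n2 + 1)
  spectrum(cnt, c(n1, n2))
}

toy_genotypes <- function(seed = 1, n_ind = 5, n_sites = 200) {
  set.seed(seed)
  calls <- matrix(stats::rbinom(2 * n_ind * n_sites, 2, 0.25),
                  2 * n_ind, n_sites)
  genotype_matrix(calls, rep(c("bornean", "sumatran"), each = n_ind))
}

fold_cache_for_tests <- function(cache) popgensel:::fold_cache(cache)
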