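#' Isolation-with-migration demographic model
#'
#' Two populations split from an ancestral population of diploid effective
#' size `N_anc` at time `T_split` (in units of `2 N_anc` generations before
#' present) and change size exponentially from `nu*_0` (relative size at the
#' split) to `nu*` (relative size now), exchanging migrants at scaled rates
#' `m12` (into population 1) and `m21` (into population 2), both in units of
#' `2 N_anc` times the per-generation migrant fraction.
#'
#' The shipped defaults are an *illustrative* two-island configuration (a
#' modest decline in population 1, a six-fold expansion in population 2, a
#' split on the order of half a coalescent time unit, symmetric moderate
#' migration). They are not fitted values; every inference function takes the
#' model as explicit input and holds it fixed.
#'
#' @param N_anc ancestral diploid effective size (individuals).
#' @param T_split divergence time in `2 N_anc` generations.
#' @param nu1_0,nu1 population-1 relative size at the split and at present.
#' @param nu2_0,nu2 population-2 relative size at the split and at present.
#' @param m12,m21 scaled migration rates (`>= 0`).
#' @param variant `"full"`, `"no_migration"` (forces `m12 = m21 = 0`) or
#'   `"no_growth"` (forces constant sizes `nu*_0 = nu*`).
#' @return an object of class `"demographic_model"`.
#' @export
demographic_model <- function(N_anc = 17900, T_split = 0.56,
                              nu1_0 = 1, nu1 = 0.6,
                              nu2_0 = 1, nu2 = 6,
                              m12 = 0.5, m21 = 0.5,
                              variant = c("full", "no_migration", "no_growth")) {
  variant <- match.arg(variant)
  if (variant == "no_migration") m12 <- m21 <- 0
  if (variant == "no_growth") { nu1_0 <- nu1; nu2_0 <- nu2 }
  if (N_anc <= 0 || T_split <= 0) stop("N_anc and T_split must be positive")
  if (any(c(nu1_0, nu1, nu2_0, nu2) <= 0)) stop("relative sizes must be positive")
  if (m12 < 0 || m21 < 0) stop("migration rates must be non-negative")
  structure(list(N_anc = N_anc, T_split = T_split,
                 nu1_0 = nu1_0, nu1 = nu1, nu2_0 = nu2_0, nu2 = nu2,
                 m12 = m12, m21 = m21, variant = variant),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf(paste0("isolation-with-migration model (%s): N_anc = %g, ",
                     "T = %g, nu1 %g->%g, nu2 %g->%g, m12 = %g, m21 = %g\n"),
              x$variant, x$N_anc, x$T_split, x$nu1_0, x$nu1,
              x$nu2_0, x$nu2, x$m12, x$m21))
  invisible(x)
}

#' Logarithmic grid of scaled selection coefficients
#'
#' By default: 2000 values of gamma = 2*N*s uniform on a log scale from
#' -2000 to -1e-6, gamma = 0, and 500 values uniform on a log scale from
#' 1e-6 to 100 (2501 values in all, strictly increasing). A reduced grid
#' (see `n_negative`, `n_positive`) covering the same bounds is used for
#' desk-scale work, with interpolation between cached points.
#'
#' @param n_negative,n_positive number of log-uniform points on the negative
#'   and positive branches.
#' @param negative_bounds,positive_bounds `|gamma|` ranges of the branches.
#' @param include_zero include gamma = 0?
#' @return an object of class `"selection_grid"` with element `gamma_values`.
#' @export
selection_grid <- function(n_negative = 2000, n_positive = 500,
                           negative_bounds = c(-2000, -1e-6),
                           positive_bounds = c(1e-6, 100),
                           include_zero = TRUE) {
  neg <- -10^seq(log10(-negative_bounds[1]), log10(-negative_bounds[2]),
                 length.out = n_negative)
  pos <- 10^seq(log10(positive_bounds[1]), log10(positive_bounds[2]),
                length.out = n_positive)
  g <- c(neg, if (include_zero) 0, pos)
  stopifnot(!is.unsorted(g, strictly = TRUE))
  structure(list(gamma_values = g,
                 n_negative = n_negative, n_positive = n_positive,
                 negative_bounds = negative_bounds,
                 positive_bounds = positive_bounds,
                 include_zero = include_zero),
            class = "selection_grid")
}

#' Reduced selection grid for desk-scale fitting
#'
#' Same bounds as the full grid but 60 points by default (44 negative, zero,
#' 15 positive).
#' @param n_negative,n_positive branch sizes.
#' @export
reduced_selection_grid <- function(n_negative = 44, n_positive = 15) {
  selection_grid(n_negative = n_negative, n_positive = n_positive)
}

# stable PRF sojourn density (1 - exp(-gt*(1-q))) / ((1 - exp(-gt)) q (1-q)),
# gt = 2*gamma; neutral limit 1/q
prf_density <- function(q, gamma) {
  gt <- 2 * gamma
  if (abs(gt) < 1e-8) return(1 / q)
  if (gt < 0) {
    a <- -gt
    # = exp(-a q) (1 - exp(-a (1-q))) / (1 - exp(-a)) / (q (1-q))
    num <- exp(-a * q) * (-expm1(-a * (1 - q)))
    den <- -expm1(-a)
  } else {
    num <- -expm1(-gt * (1 - q))
    den <- -expm1(-gt)
  }
  num / den / (q * (1 - q))
}

#' Single-population equilibrium spectrum under selection
#'
#' Expected SFS of a stationary population under the Poisson random field
#' model with genic selection: `E[eta_i] = theta * integral over q of
#' C(n,i) q^i (1-q)^(n-i) * (1 - exp(-2 gamma (1-q))) /
#' ((1 - exp(-2 gamma)) q (1-q)) dq`, with gamma = 2*N*s. At gamma = 0 this
#' reduces to the neutral law `theta / i`.
#'
#' @param gamma scaled selection coefficient (gamma = 2 N s).
#' @param n sample size in chromosomes, `>= 2`.
#' @param theta population-scaled mutation influx; `E[eta_1] = theta` when
#'   neutral.
#' @param rel_tol quadrature relative tolerance.
#' @return a 1D `"sfs"` with entries `i = 0..n` (corners masked, zero).
#' @export
equilibrium_selected_sfs <- function(gamma, n, theta = 1, rel_tol = 1e-10) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (theta <= 0) stop("theta must be positive")
  eta <- numeric(n + 1L)
  for (i in 1:(n - 1L)) {
    f <- function(q) {
      exp(lchoose(n, i) + i * log(q) + (n - i) * log1p(-q)) *
        prf_density(q, gamma)
    }
    eta[i + 1L] <- theta *
      stats::integrate(f, 0, 1, rel.tol = rel_tol, subdivisions = 500L)$value
  }
  spectrum(eta, n, folded = FALSE)
}

#' Exact Wright-Fisher transition-matrix oracle for the expected SFS
#'
#' Iterates (or solves at stationarity) the binomial Wright-Fisher model with
#' genic selection and constant mutational influx, then samples down to `n`
#' chromosomes hypergeometrically. Selection uses multiplicative allele
#' fitness `exp(s)` with `s = gamma / (2 N)`, which matches the additive
#' diffusion for small `s` and stays well defined for arbitrarily strong
#' selection. Used only for validation: `N <= 500`.
#'
#' @param N diploid population size of the initial (stationary) epoch.
#' @param gamma scaled selection coefficient `2 N s` (fixed `s` throughout;
#'   the scaled coefficient refers to the initial `N`).
#' @param n sample size in chromosomes, `<= 2 N`.
#' @param epochs optional `data.frame(N, t_gens)` of later epochs applied
#'   after the stationary start, in order.
#' @param theta scaled mutation influx `4 N mu` for the initial epoch; the
#'   per-generation influx `theta/2` mutations is scaled by `N_t / N` in later
#'   epochs (constant per-base mutation rate).
#' @return a 1D `"sfs"` of expected counts at sample size `n`.
#' @export
wf_oracle_sfs <- function(N, gamma, n, epochs = NULL, theta = 1) {
  N <- as.integer(N)
  if (N > 500L) stop("N too large for the dense transition-matrix oracle")
  n <- as.integer(n)
  if (n > 2L * N) stop("n exceeds 2N")
  s <- gamma / (2 * N)

  trans <- function(Npop, s) {
    M <- 2L * Npop
    x <- (1:(M - 1L)) / M
    xs <- x * exp(s) / (x * exp(s) + (1 - x))
    # rows: current count 1..M-1; cols: next count 1..M-1 (0 and M absorb)
    t(vapply(xs, function(p) stats::dbinom(1:(M - 1L), M, p), numeric(M - 1L)))
  }

  Q <- trans(N, s)
  M <- 2L * N
  influx <- numeric(M - 1L)
  influx[1L] <- theta / 2
  # stationary expected counts: eta (I - Q) = influx
  eta <- solve(t(diag(M - 1L) - Q), influx)
  influx_now <- influx[1L]

  if (!is.null(epochs)) {
    for (e in seq_len(nrow(epochs))) {
      Ne <- as.integer(epochs$N[e])
      Me <- 2L * Ne
      if (Me != M) {
        # binomial resampling across the size change
        map <- t(vapply((1:(M - 1L)) / M,
                        function(p) stats::dbinom(1:(Me - 1L), Me, p),
                        numeric(Me - 1L)))
        eta <- as.numeric(eta %*% map)
        M <- Me
      }
      Qe <- trans(Ne, s)
      influx_e <- numeric(M - 1L)
      influx_e[1L] <- (theta / 2) * (Ne / N)
      for (g in seq_len(epochs$t_gens[e])) {
        eta <- as.numeric(eta %*% Qe) + influx_e
      }
      influx_now <- influx_e[1L]
    }
  }

  # census in adults, after viability selection: the age-0 cohort (this
  # generation's fresh mutants, influx_now sites at count 1) contributes its
  # expected post-selection copy number, i.e. is weighted by exp(s). Without
  # this the discrete chain reports a spurious age-0 singleton mass that the
  # diffusion (with influx at frequency 0+) does not have, which matters in
  # the strong-selection (lethal) limit.
  eta[1L] <- eta[1L] - influx_now * (1 - exp(s))
  P <- projection_matrix(M, n)[2:M, , drop = FALSE]
  spectrum(as.numeric(eta %*% P), n, folded = FALSE)
}
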