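#' Parametric distribution of fitness effects (DFE)
#'
#' Mixture models over the scaled selection coefficient gamma = 2*N*s of new
#' non-synonymous mutations:
#' \describe{
#'   \item{`point_lethal`}{proportion `p_point` at a single `gamma_point`
#'     (< 0), remaining `1 - p_point` lethal.}
#'   \item{`expon_lethal`}{`|gamma|` exponential with mean `mean` on the
#'     negative axis, plus `p_lethal` at lethality.}
#'   \item{`norm_lethal`}{gamma normal with `mean` and `sd`, plus `p_lethal`
#'     at lethality.}
#'   \item{`gamma`}{`|gamma|` gamma-distributed with `shape` and `scale` on
#'     the negative axis (no lethal atom).}
#' }
#' "Lethal" mutations (and any continuous mass beyond the selection grid's
#' most negative value) contribute zero polymorphism.
#'
#' @param family one of `"point_lethal"`, `"expon_lethal"`, `"norm_lethal"`,
#'   `"gamma"`.
#' @param ... family-specific parameters (see above).
#' @return an object of class `"dfe_model"`.
#' @export
dfe_model <- function(family = c("point_lethal", "expon_lethal",
                                 "norm_lethal", "gamma"), ...) {
  family <- match.arg(family)
  p <- list(...)
  need <- switch(family,
                 point_lethal = c("p_point", "gamma_point"),
                 expon_lethal = c("mean", "p_lethal"),
                 norm_lethal = c("mean", "sd", "p_lethal"),
                 gamma = c("shape", "scale"))
  if (!all(need %in% names(p)))
    stop(sprintf("family %s needs parameters: %s", family,
                 paste(need, collapse = ", ")))
  p <- p[need]
  prop <- intersect(names(p), c("p_point", "p_lethal"))
  if (length(prop) && (p[[prop]] < 0 || p[[prop]] > 1))
    stop("proportions must lie in [0, 1]")
  if (family == "point_lethal" && p$gamma_point >= 0)
    stop("gamma_point must be negative")
  for (nm in intersect(names(p), c("sd", "scale", "shape", "mean")))
    if (nm != "mean" && p[[nm]] <= 0) stop(sprintf("%s must be positive", nm))
  if (family == "expon_lethal" && p$mean <= 0)
    stop("mean of |gamma| must be positive")
  structure(list(family = family, params = p), class = "dfe_model")
}

#' @export
print.dfe_model <- function(x, ...) {
  cat(sprintf("DFE model '%s': %s\n", x$family,
              paste(sprintf("%s = %.4g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

# Voronoi cell boundaries of the selection grid on the signed gamma axis:
# geometric means of |gamma| between same-sign neighbours, arithmetic
# midpoints across zero; outermost negative boundary is the grid minimum
# (mass beyond it counts as lethal), outermost positive boundary +Inf
# (lumped into the top grid point).
grid_cell_edges <- function(grid) {
  gv <- grid$gamma_values
  K <- length(gv)
  inner <- numeric(K - 1L)
  for (k in seq_len(K - 1L)) {
    a <- gv[k]; b <- gv[k + 1L]
    inner[k] <- if (a < 0 && b < 0) -sqrt(a * b)
    else if (a > 0 && b > 0) sqrt(a * b)
    else (a + b) / 2
  }
  c(gv[1], inner, Inf)
}

#' Mixture weights of a DFE over a selection grid
#'
#' Integrates the DFE density over the Voronoi cell of each grid point (in
#' log |gamma| within a sign branch). Continuous mass more negative than the
#' grid minimum, and any explicit lethal atom, is returned as the `lethal`
#' mass; weights plus `lethal` sum to 1.
#'
#' @param dfe a [dfe_model()].
#' @param grid a [selection_grid()].
#' @return list with `weights` (one per grid value) and `lethal`.
#' @export
dfe_weights <- function(dfe, grid) {
  gv <- grid$gamma_values
  edges <- grid_cell_edges(grid)
  w <- numeric(length(gv))
  lethal <- 0
  p <- dfe$params
  cdf <- switch(dfe$family,
    # P(gamma <= x) for the continuous component
    point_lethal = NULL,
    expon_lethal = function(x) stats::pexp(-x, rate = 1 / p$mean,
                                           lower.tail = FALSE),
    norm_lethal = function(x) stats::pnorm(x, p$mean, p$sd),
    gamma = function(x) stats::pgamma(-x, shape = p$shape, scale = p$scale,
                                      lower.tail = FALSE))
  if (dfe$family == "point_lethal") {
    k <- which(gv == p$gamma_point)
    if (!length(k)) {
      if (p$gamma_point < edges[1]) {
        lethal <- lethal + p$p_point
      } else {
        k <- findInterval(p$gamma_point, edges)
        w[k] <- p$p_point
      }
    } else {
      w[k] <- p$p_point
    }
    lethal <- lethal + 1 - p$p_point
  } else {
    p_cont <- if (is.null(p$p_lethal)) 1 else 1 - p$p_lethal
    cm <- cdf(edges)
    w <- p_cont * diff(cm)
    lethal <- (if (is.null(p$p_lethal)) 0 else p$p_lethal) + p_cont * cm[1]
  }
  list(weights = w, lethal = lethal)
}

#' Expected spectrum under a DFE
#'
#' Mixes the cached unit-theta expected spectra over the DFE's grid weights
#' and scales by the non-synonymous mutation influx `theta_non`; the lethal
#' mass contributes zero polymorphism. For the `point_lethal` family the
#' spectrum at `gamma_point` is interpolated from the cache, so the expected
#' spectrum is smooth in `gamma_point` even on a reduced grid.
#'
#' @param cache an `"sfs_cache"`.
#' @param dfe a [dfe_model()].
#' @param theta_non non-synonymous mutation influx.
#' @return a 2D `"sfs"`.
#' @export
expected_sfs_under_dfe <- function(cache, dfe, theta_non) {
  if (!inherits(cache, "sfs_cache")) stop("cache must be an sfs_cache")
  if (dfe$family == "point_lethal") {
    s <- cache_spectrum_at(cache, dfe$params$gamma_point)
    s$counts <- theta_non * dfe$params$p_point * s$counts
    return(s)
  }
  wts <- dfe_weights(dfe, cache$grid)
  out <- cache$spectra[[1]]
  acc <- out$counts * 0
  nz <- which(wts$weights > 0)
  for (k in nz) acc <- acc + wts$weights[k] * cache$spectra[[k]]$counts
  out$counts <- theta_non * acc
  out
}

#' Poisson random-field log-likelihood of a data spectrum
#'
#' `sum over unmasked entries of (-m_i + d_i log m_i - log d_i!)`; `-Inf`
#' when a model entry is zero but the data entry is not.
#'
#' @param model expected `"sfs"` (the Poisson means).
#' @param data observed `"sfs"`, same shape, folding and mask.
#' @export
poisson_loglik <- function(model, data) {
  stopifnot_spectrum(model); stopifnot_spectrum(data)
  if (!identical(dim2(model$counts), dim2(data$counts)))
    stop("model and data spectra have different shapes")
  if (!identical(model$folded, data$folded))
    stop("model and data spectra have different folding")
  if (!identical(model$mask, data$mask))
    stop("model and data spectra have different masks")
  m <- model$counts[!model$mask]
  d <- data$counts[!data$mask]
  if (any(m == 0 & d > 0)) return(-Inf)
  ok <- m > 0
  sum(-m[ok] + d[ok] * log(m[ok]) - lgamma(d[ok] + 1))
}

# natural-scale parameters <-> unconstrained optimizer scale, per family
dfe_par_info <- function(family) {
  switch(family,
    point_lethal = list(
      names = c("p_point", "gamma_point"),
      to_opt = function(p) c(stats::qlogis(p$p_point), log(-p$gamma_point)),
      from_opt = function(x) list(p_point = stats::plogis(x[1]),
                                  gamma_point = -exp(x[2])),
      lower = c(-12, log(1e-6)), upper = c(12, log(2000)),
      start = function() c(stats::rnorm(1, 0, 2),
                           stats::runif(1, log(0.05), log(50)))),
    expon_lethal = list(
      names = c("mean", "p_lethal"),
      to_opt = function(p) c(log(p$mean), stats::qlogis(p$p_lethal)),
      from_opt = function(x) list(mean = exp(x[1]),
                                  p_lethal = stats::plogis(x[2])),
      lower = c(log(1e-4), -12), upper = c(log(1e5), 12),
      start = function() c(stats::runif(1, log(0.1), log(100)),
                           stats::rnorm(1, 0, 2))),
    norm_lethal = list(
      names = c("mean", "sd", "p_lethal"),
      to_opt = function(p) c(p$mean, log(p$sd), stats::qlogis(p$p_lethal)),
      from_opt = function(x) list(mean = x[1], sd = exp(x[2]),
                                  p_lethal = stats::plogis(x[3])),
      lower = c(-2000, log(1e-3), -12), upper = c(100, log(1e4), 12),
      start = function() c(stats::rnorm(1, -5, 5),
                           stats::runif(1, log(0.5), log(50)),
                           stats::rnorm(1, 0, 2))),
    gamma = list(
      names = c("shape", "scale"),
      to_opt = function(p) c(log(p$shape), log(p$scale)),
      from_opt = function(x) list(shape = exp(x[1]), scale = exp(x[2])),
      lower = c(log(1e-3), log(1e-3)), upper = c(log(100), log(1e6)),
      start = function() c(stats::rnorm(1, log(0.3), 1),
                           stats::runif(1, log(1), log(5000)))))
}

#' Fit a DFE family to a folded spectrum by Poisson likelihood
#'
#' Maximizes the Poisson random-field likelihood of the observed folded
#' spectrum over the family's parameters by bounded quasi-Newton (L-BFGS-B)
#' from `n_restarts` seeded random starts. With `theta_non = NULL` the influx
#' is profiled out analytically (its conditional MLE is the ratio of data to
#' unit-theta model totals); otherwise it is held fixed (the 2.5 x
#' theta_syn constraint).
#'
#' @param data folded 2D `"sfs"` of observed counts.
#' @param cache an `"sfs_cache"` over the selection grid (unfolded spectra;
#'   folded internally to match the data).
#' @param family DFE family name, see [dfe_model()].
#' @param theta_non fixed non-synonymous influx, or `NULL` to profile.
#' @param n_restarts number of random optimizer starts.
#' @param seed integer seed (mandatory: restarts are random).
#' @return an object of class `"dfe_fit"`: fitted [dfe_model()], `theta_non`,
#'   `loglik`, convergence info.
#' @export
fit_dfe <- function(data, cache, family, theta_non = NULL, n_restarts = 5,
                    seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!data$folded) stop("fit_dfe expects a folded data spectrum")
  info <- dfe_par_info(family)
  folded_cache <- fold_cache(cache)

  model_unit <- function(p) {
    dfe <- do.call(dfe_model, c(list(family = family), p))
    expected_sfs_under_dfe(folded_cache, dfe, theta_non = 1)
  }
  negll <- function(x) {
    p <- info$from_opt(x)
    mu <- model_unit(p)
    mtot <- segregating_total(mu)
    if (!is.finite(mtot) || mtot <= 0) return(1e10)
    th <- if (is.null(theta_non)) segregating_total(data) / mtot else theta_non
    mu$counts <- th * mu$counts
    ll <- poisson_loglik(mu, data)
    if (!is.finite(ll)) 1e10 else -ll
  }

  set.seed(seed)
  starts <- replicate(n_restarts, info$start(), simplify = FALSE)
  fits <- lapply(starts, function(s0) {
    tryCatch(stats::optim(s0, negll, method = "L-BFGS-B",
                          lower = info$lower, upper = info$upper,
                          control = list(maxit = 300)),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all optimizer restarts failed")
  fits <- fits[ok]
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p <- info$from_opt(best$par)
  dfe <- do.call(dfe_model, c(list(family = family), p))
  mu <- model_unit(p)
  th <- if (is.null(theta_non))
    segregating_total(data) / segregating_total(mu) else theta_non
  structure(list(family = family, dfe = dfe, params = p, theta_non = th,
                 loglik = -best$value, convergence = best$convergence,
                 n_restarts_ok = length(fits)),
            class = "dfe_fit")
}

# fold every cached spectrum once (fits work on folded spectra)
fold_cache <- function(cache) {
  if (isTRUE(attr(cache, "folded"))) return(cache)
  cache$spectra <- lapply(cache$spectra, fold)
  attr(cache, "folded") <- TRUE
  cache
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("DFE fit (%s): logLik = %.3f, theta_non = %.4g\n",
              x$family, x$loglik, x$theta_non))
  print(x$dfe)
  invisible(x)
}

#' DFE mass in the four selective classes of |s|
#'
#' Converts gamma to s = gamma / (2 N_anc) and reports the percent of
#' mutations with `s < -1e-2`, `-1e-2 < s < -1e-3`, `-1e-3 < s < -1e-4` and
#' `s > -1e-4`. Lethal mass counts in the strongest class.
#'
#' @param dfe a [dfe_model()].
#' @param N_anc ancestral diploid effective size.
#' @return named numeric vector of four percentages summing to 100.
#' @export
class_masses <- function(dfe, N_anc) {
  if (N_anc <= 0) stop("N_anc must be positive")
  edges_s <- c(-Inf, -1e-2, -1e-3, -1e-4, Inf)
  edges_g <- 2 * N_anc * edges_s
  p <- dfe$params
  mass <- numeric(4)
  cum <- switch(dfe$family,
    point_lethal = {
      k <- findInterval(p$gamma_point, edges_g, rightmost.closed = TRUE)
      mass[k] <- mass[k] + p$p_point
      mass[1] <- mass[1] + 1 - p$p_point
      NULL
    },
    expon_lethal = {
      cm <- stats::pexp(-edges_g, rate = 1 / p$mean, lower.tail = FALSE)
      mass <- (1 - p$p_lethal) * diff(cm)
      mass[1] <- mass[1] + p$p_lethal
      NULL
    },
    norm_lethal = {
      cm <- stats::pnorm(edges_g, p$mean, p$sd)
      mass <- (1 - p$p_lethal) * diff(cm)
      mass[1] <- mass[1] + p$p_lethal
      NULL
    },
    gamma = {
      cm <- stats::pgamma(-edges_g, shape = p$shape, scale = p$scale,
                          lower.tail = FALSE)
      mass <- diff(cm)
      NULL
    })
  out <- 100 * mass
  names(out) <- c("s<-1e-2", "-1e-2<s<-1e-3", "-1e-3<s<-1e-4", "s>-1e-4")
  out
}

#' Bootstrap confidence intervals for DFE parameters
#'
#' Resamples the observed spectrum at the SNP level (multinomial over the
#' unmasked bins, holding the segregating total fixed -- the
#' linkage-conservative unit), refits the family per replicate, and returns
#' percentile intervals. Failed replicate fits are recorded and excluded
#' (with a warning if more than 10 percent fail).
#'
#' @inheritParams fit_dfe
#' @param n_boot number of bootstrap replicates (`>= 2`).
#' @param level interval level (default 0.95).
#' @return list with the point `fit`, matrix `intervals` (rows = parameters
#'   and theta_non; columns lower/upper), and `n_failed`.
#' @export
bootstrap_ci <- function(data, cache, family, n_boot = 100, seed,
                         theta_non = NULL, n_restarts = 3, level = 0.95) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_boot < 2) stop("n_boot must be >= 2")
  fit0 <- fit_dfe(data, cache, family, theta_non = theta_non,
                  n_restarts = n_restarts, seed = seed)
  tot <- segregating_total(data)
  pr <- data$counts[!data$mask] / tot
  N <- round(tot)
  set.seed(seed + 1L)
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    d <- data
    d$counts[!d$mask] <- as.numeric(stats::rmultinom(1, N, pr))
    reps[[b]] <- tryCatch(
      fit_dfe(d, cache, family, theta_non = theta_non,
              n_restarts = n_restarts, seed = seed + 1L + b),
      error = function(e) NULL)
  }
  failed <- vapply(reps, is.null, logical(1))
  if (mean(failed) > 0.1)
    warning(sprintf("%d of %d bootstrap refits failed", sum(failed), n_boot))
  reps <- reps[!failed]
  parmat <- t(vapply(reps, function(f)
    c(unlist(f$params), theta_non = f$theta_non),
    numeric(length(fit0$params) + 1L)))
  a <- (1 - level) / 2
  ints <- t(apply(parmat, 2, stats::quantile, probs = c(a, 1 - a),
                  na.rm = TRUE))
  colnames(ints) <- c("lower", "upper")
  list(fit = fit0, intervals = ints, n_failed = sum(failed))
}

#' Selective-class table for a set of fitted DFEs
#'
#' One row per fit, columns the four |s| classes in percent (the standard
#' summary layout for DFE comparisons across models).
#'
#' @param fits named list of `"dfe_fit"` objects (or [dfe_model()]s).
#' @param N_anc ancestral size for the gamma -> s conversion.
#' @export
dfe_class_table <- function(fits, N_anc) {
  rows <- lapply(fits, function(f) {
    dfe <- if (inherits(f, "dfe_fit")) f$dfe else f
    as.list(round(class_masses(dfe, N_anc)))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame, check.names = FALSE))
  df <- cbind(model = names(fits), df)
  rownames(df) <- NULL
  df
}

#' Write a DFE fit as a flat text report plus a JSON twin
#' @param fit a `"dfe_fit"`.
#' @param path output path (`.txt`; a `.json` twin is written alongside).
#' @export
write_fit_report <- function(fit, path) {
  kv <- c(family = fit$family,
          vapply(fit$params, function(v) sprintf("%.10g", v), character(1)),
          theta_non = sprintf("%.10g", fit$theta_non),
          loglik = sprintf("%.10g", fit$loglik),
          convergence = fit$convergence)
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  jsonlite::write_json(
    list(family = fit$family, params = fit$params,
         theta_non = fit$theta_non, loglik = fit$loglik,
         convergence = fit$convergence),
    sub("\\.txt$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
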