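# Finite-volume diffusion solver for expected spectra under the
# two-population isolation-with-migration model with genic selection.
#
# The density phi(x1, x2, t) of derived-allele frequencies evolves by
#   dphi/dt = sum_i [ d^2/dxi^2 ( xi(1-xi) phi / (2 nu_i(t)) )
#                     - d/dxi ( (gamma xi(1-xi) + m_ij (xj - xi)) phi ) ]
# with time in units of 2*N_anc generations and gamma = 2*N_anc*s (so the
# stationary sojourn density carries exp(-2*gamma*x) factors; see
# equilibrium_selected_sfs). The scheme is a conservative finite-volume
# discretisation on a boundary-refined grid with Chang-Cooper exponential
# fitting (upwinding in the strong-selection limit), integrated by backward
# Euler with alternating-direction implicit sweeps. Boundaries absorb: mass
# reaching x = 0 or 1 accumulates there (loss / fixation) and can re-enter
# through migration.

#' Solver settings for [expected_sfs()]
#'
#' @param pts number of frequency grid points per axis.
#' @param dt maximum time step (in `2 N_anc` generations).
#' @param crwd grid crowding: larger values concentrate points near the
#'   absorbing boundaries 0 and 1 where the density is steep.
#' @export
sfs_solver_control <- function(pts = 160, dt = 0.002, crwd = 7) {
  list(pts = as.integer(pts), dt = dt, crwd = crwd)
}

# boundary-refined grid on [0,1]
freq_grid <- function(pts, crwd = 5) {
  u <- seq(0, 1, length.out = pts)
  (tanh(crwd * (u - 0.5)) / tanh(crwd * 0.5) + 1) / 2
}

# Chang-Cooper weight: delta in [0,1]; 0.5 for small Peclet w,
# upwind in the advection direction for large |w|
cc_delta <- function(w) {
  d <- ifelse(abs(w) < 1e-10, 0.5, 1 / w - 1 / expm1(w))
  pmin(pmax(d, 0), 1)
}

# Tridiagonal operator A for one axis; coefficients may differ per system
# (columns of the state matrix). The flux is written in advection-diffusion
# form J = Meff phi - D dphi/dx with Meff = M - V'/2 and D = V/2 at cell
# midpoints, and Chang-Cooper exponential fitting, which keeps the implicit
# update exactly positivity-preserving. Boundary nodes (x = 0, 1) are
# absorbing along this axis: mass flows in and never couples back.
# Arguments:
#   xx: grid (length G); nu: relative size; gamma: selection; m: migration
#   rate into this population; yother: other-axis coordinate per system
#   (length S, or NULL for a single 1D system).
# Returns list(lo, di, up): G x S matrices (lo[1,] and up[G,] unused).
axis_operator <- function(xx, nu, gamma, m = 0, yother = NULL) {
  G <- length(xx)
  S <- if (is.null(yother)) 1L else length(yother)
  dx <- diff(xx)                              # G-1
  h <- c(dx[1] / 2, (xx[-(1:2)] - xx[seq_len(G - 2)]) / 2, dx[G - 1] / 2)
  xm <- (xx[-G] + xx[-1]) / 2                  # midpoints, G-1
  D <- xm * (1 - xm) / (2 * nu)                # diffusion coeff at midpoints
  Meff1 <- gamma * xm * (1 - xm) - (1 - 2 * xm) / (2 * nu)
  if (is.null(yother)) {
    Mmid <- matrix(Meff1, G - 1L, 1L)
  } else {
    Mmid <- outer(Meff1 - m * xm, rep(1, S)) + outer(rep(m, G - 1L), yother)
  }
  w <- Mmid * dx / D
  del <- cc_delta(w)
  # flux k (between nodes k, k+1):
  #   J_k = Mmid_k ((1-del)phi_k + del phi_{k+1}) - D_k (phi_{k+1}-phi_k)/dx_k
  fl_lo <- Mmid * (1 - del) + D / dx     # coeff of phi_k in J_k   (>= 0)
  fl_up <- Mmid * del - D / dx           # coeff of phi_{k+1} in J_k (<= 0)
  # absorbing boundaries: the boundary nodes' own density never couples back
  fl_lo[1, ] <- 0
  fl_up[G - 1L, ] <- 0
  lo <- di <- up <- matrix(0, G, S)
  # dphi_i/dt = (J_{i-1} - J_i)/h_i
  di[-G, ] <- di[-G, , drop = FALSE] - fl_lo / h[-G]
  up[-G, ] <- -fl_up / h[-G]
  lo[-1, ] <- fl_lo / h[-1]
  di[-1, ] <- di[-1, , drop = FALSE] + fl_up / h[-1]
  list(lo = lo, di = di, up = up)
}

# Solve (I - dt A) x = rhs for each system (column) with the Thomas
# algorithm, vectorised across systems.
implicit_step <- function(op, rhs, dt) {
  G <- nrow(rhs); S <- ncol(rhs)
  a <- -dt * op$lo                      # sub-diagonal
  b <- 1 - dt * op$di                   # diagonal
  c <- -dt * op$up                      # super-diagonal
  cp <- matrix(0, G, S)
  dp <- matrix(0, G, S)
  cp[1, ] <- c[1, ] / b[1, ]
  dp[1, ] <- rhs[1, ] / b[1, ]
  for (i in 2:G) {
    denom <- b[i, ] - a[i, ] * cp[i - 1L, ]
    cp[i, ] <- c[i, ] / denom
    dp[i, ] <- (rhs[i, ] - a[i, ] * dp[i - 1L, ]) / denom
  }
  x <- dp
  for (i in (G - 1L):1L) {
    x[i, ] <- dp[i, ] - cp[i, ] * x[i + 1L, ]
  }
  x
}

# stationary interior solve of the (decoupled-boundary) tridiagonal operator
# for a given injection rate at the first interior node
stationary_interior <- function(xx, op, rate) {
  G <- length(xx)
  inj <- numeric(G)
  inj[2] <- rate
  idx <- 2:(G - 1L)
  A <- matrix(0, G - 2L, G - 2L)
  diag(A) <- op$di[idx, 1]
  A[cbind(2:(G - 2L), 1:(G - 3L))] <- op$lo[idx[-1], 1]
  A[cbind(1:(G - 3L), 2:(G - 2L))] <- op$up[idx[-length(idx)], 1]
  phi <- numeric(G)
  phi[idx] <- solve(-A, inj[idx])
  phi
}

# Injection rate into the first interior node that realises unit mutation
# influx theta = 1 on this grid: calibrated so the neutral stationary
# density matches the theta/x law in the grid interior (a pure
# discretisation constant, independent of selection).
injection_rate <- function(xx) {
  op0 <- axis_operator(xx, 1, 0)
  phi <- stationary_interior(xx, op0, 1)
  mid <- xx > 0.3 & xx < 0.7
  1 / stats::median(phi[mid] * xx[mid])
}

# discrete stationary 1D density at influx theta, absorbing boundaries
phi_equilibrium_1d <- function(xx, gamma, nu = 1, theta = 1,
                               rate1 = injection_rate(xx)) {
  G <- length(xx)
  op <- axis_operator(xx, nu, gamma)
  phi <- stationary_interior(xx, op, theta * rate1)
  phi[1] <- phi[2]
  gt <- 2 * gamma
  phi[G] <- theta * if (abs(gt) < 1e-8) 1 else gt / (-expm1(-gt))
  phi
}

# binomial sampling matrix: rows = grid nodes, cols = 0..n
sampling_matrix <- function(xx, n) {
  t(vapply(xx, function(x) stats::dbinom(0:n, n, x), numeric(n + 1L)))
}

trapz_weights <- function(xx) {
  G <- length(xx)
  c(diff(xx)[1] / 2, (xx[-(1:2)] - xx[seq_len(G - 2)]) / 2,
    diff(xx)[G - 1L] / 2)
}

#' Expected joint spectrum under the isolation-with-migration model
#'
#' Numerically integrates the two-population Wright-Fisher diffusion (drift,
#' genic selection `gamma`, migration, exponential size change over
#' `T_split`) forward from the single-population equilibrium, then samples
#' binomially to the requested chromosome counts. Deterministic given the
#' solver settings; linear in `theta`.
#'
#' @param model a [demographic_model()].
#' @param gamma scaled selection coefficient `2 N_anc s`.
#' @param sizes chromosome counts per population, each `>= 2`.
#' @param theta scaled mutation influx (per-population branch injection).
#' @param control solver settings from [sfs_solver_control()].
#' @return a 2D `"sfs"` of expected per-bin counts.
#' @export
expected_sfs <- function(model, gamma, sizes, theta = 1,
                         control = sfs_solver_control()) {
  if (!inherits(model, "demographic_model")) stop("model must be a demographic_model")
  sizes <- as.integer(sizes)
  if (length(sizes) != 2L || any(sizes < 2L)) stop("need two sample sizes >= 2")
  if (theta <= 0) stop("theta must be positive")
  xx <- freq_grid(control$pts, control$crwd)
  G <- length(xx)
  w <- trapz_weights(xx)

  rate1 <- injection_rate(xx)
  phi1 <- phi_equilibrium_1d(xx, gamma, nu = 1, theta = theta, rate1 = rate1)
  phi <- matrix(0, G, G)
  diag(phi) <- phi1 / w        # line density on the diagonal -> 2D density

  TT <- model$T_split
  nsteps <- max(1L, ceiling(TT / control$dt))
  dt <- TT / nsteps
  # per-step injection of new mutations arising in each population:
  # 1D rate scaled by the other axis' boundary cell width
  inj1 <- dt * theta * rate1 * 2 / (xx[2] - xx[1])
  for (k in seq_len(nsteps)) {
    tmid <- (k - 0.5) * dt
    nu1 <- model$nu1_0 * (model$nu1 / model$nu1_0)^(tmid / TT)
    nu2 <- model$nu2_0 * (model$nu2 / model$nu2_0)^(tmid / TT)
    op1 <- axis_operator(xx, nu1, gamma, model$m12, yother = xx)
    op2 <- axis_operator(xx, nu2, gamma, model$m21, yother = xx)
    phi[2, 1] <- phi[2, 1] + inj1
    phi[1, 2] <- phi[1, 2] + inj1
    if (k %% 2L == 1L) {
      phi <- implicit_step(op1, phi, dt)
      phi <- t(implicit_step(op2, t(phi), dt))
    } else {
      phi <- t(implicit_step(op2, t(phi), dt))
      phi <- implicit_step(op1, phi, dt)
    }
    minphi <- min(phi)
    if (minphi < -1e-6 * max(abs(phi)))
      stop(sprintf("diffusion solver produced negative density (%.3g) at step %d; refine the grid/time step", minphi, k))
    phi[phi < 0] <- 0
  }

  B1 <- sampling_matrix(xx, sizes[1])
  B2 <- sampling_matrix(xx, sizes[2])
  cnt <- crossprod(B1, (phi * outer(w, w)) %*% B2)
  spectrum(cnt, sizes, folded = FALSE)
}

#' Cache of expected spectra across a selection grid
#'
#' One unit-theta expected spectrum per grid value of gamma, at a fixed
#' demography and sample size. Supports interpolation in log |gamma| between
#' cached points (used with reduced grids) via [cache_spectrum_at()].
#'
#' @param model a [demographic_model()].
#' @param grid a [selection_grid()].
#' @param sizes chromosome counts per population.
#' @param control solver settings.
#' @param progress print progress every 10 grid points?
#' @return an object of class `"sfs_cache"`.
#' @export
build_cache <- function(model, grid, sizes, control = sfs_solver_control(),
                        progress = FALSE) {
  if (!inherits(grid, "selection_grid")) stop("grid must be a selection_grid")
  gv <- grid$gamma_values
  spectra <- vector("list", length(gv))
  for (i in seq_along(gv)) {
    spectra[[i]] <- tryCatch(
      expected_sfs(model, gv[i], sizes, theta = 1, control = control),
      error = function(e)
        stop(sprintf("solver failed at gamma = %g: %s", gv[i], conditionMessage(e))))
    if (progress && i %% 10L == 0L)
      message(sprintf("cached %d / %d spectra", i, length(gv)))
  }
  structure(list(spectra = spectra, grid = grid, model = model,
                 sizes = as.integer(sizes), control = control),
            class = "sfs_cache")
}

#' @export
print.sfs_cache <- function(x, ...) {
  cat(sprintf("spectra cache: %d gamma values, sample sizes %s\n",
              length(x$grid$gamma_values), paste(x$sizes, collapse = " x ")))
  invisible(x)
}

#' Expected unit-theta spectrum at an arbitrary gamma, from a cache
#'
#' Exact cache hits are returned directly; other values are linearly
#' interpolated entrywise in log |gamma| within the same sign branch.
#' Values below the grid minimum (stronger than the most deleterious cached
#' point) return the zero-polymorphism (lethal) spectrum; values above the
#' positive maximum clamp to the endpoint.
#'
#' @param cache an `"sfs_cache"`.
#' @param gamma scaled selection coefficient.
#' @return a 2D `"sfs"` at unit theta.
#' @export
cache_spectrum_at <- function(cache, gamma) {
  gv <- cache$grid$gamma_values
  hit <- which(gv == gamma)
  if (length(hit)) return(cache$spectra[[hit[1]]])
  if (gamma < gv[1]) {
    z <- cache$spectra[[1]]
    z$counts[] <- 0
    return(z)
  }
  if (gamma > gv[length(gv)]) return(cache$spectra[[length(gv)]])
  hi <- findInterval(gamma, gv) + 1L
  lo <- hi - 1L
  glo <- gv[lo]; ghi <- gv[hi]
  # interpolate in log|gamma| when both neighbours share a sign, else linear
  if (glo * ghi > 0) {
    f <- (log(abs(gamma)) - log(abs(glo))) / (log(abs(ghi)) - log(abs(glo)))
  } else {
    f <- (gamma - glo) / (ghi - glo)
  }
  out <- cache$spectra[[lo]]
  out$counts <- (1 - f) * cache$spectra[[lo]]$counts +
    f * cache$spectra[[hi]]$counts
  out
}

#' Persist a spectra cache as a directory of text files plus a manifest
#' @param cache an `"sfs_cache"`.
#' @param dir output directory (created if needed).
#' @export
write_cache <- function(cache, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cache$spectra)) {
    write_spectrum(cache$spectra[[i]], file.path(dir, sprintf("gamma_%05d.sfs", i)))
  }
  manifest <- list(gamma_values = cache$grid$gamma_values,
                   grid = cache$grid[setdiff(names(cache$grid), "gamma_values")],
                   model = unclass(cache$model),
                   sizes = cache$sizes, control = cache$control)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Re-load a spectra cache written by [write_cache()]
#' @param dir cache directory.
#' @export
read_cache <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- manifest$grid
  grid <- selection_grid(n_negative = g$n_negative, n_positive = g$n_positive,
                         negative_bounds = g$negative_bounds,
                         positive_bounds = g$positive_bounds,
                         include_zero = g$include_zero)
  stopifnot(isTRUE(all.equal(grid$gamma_values, manifest$gamma_values)))
  files <- file.path(dir, sprintf("gamma_%05d.sfs", seq_along(grid$gamma_values)))
  spectra <- lapply(files, read_spectrum)
  m <- manifest$model
  model <- demographic_model(m$N_anc, m$T_split, m$nu1_0, m$nu1, m$nu2_0,
                             m$nu2, m$m12, m$m21, m$variant)
  structure(list(spectra = spectra, grid = grid, model = model,
                 sizes = as.integer(manifest$sizes),
                 control = manifest$control),
            class = "sfs_cache")
}
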