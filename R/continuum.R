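# Fokker-Planck continuum description of the boundary dynamics.
#
# In the continuum limit f = n/N the backward equations become
#   -1 = A(f)/N tau'(f) + B(f)/(2 N^2) tau''(f)
#    0 = A(f) P'(f)     + B(f)/(2 N)   P''(f)
# with drift A = r+ - r- and diffusion B = r+ + r-.  For the spatial
# exclusion model
#   A(f) = r N [(w-1) f^2 + 2 f - 1] / (2 [1 + f (w - 1)])
#   B(f) = r N [w f^2 + (1 - f)^2]   / (2 [1 + f (w - 1)])
# and for the Moran model
#   A(f) = r N (w - 1) f (1 - f) / (1 + (w - 1) f)
#   B(f) = r N (w + 1) f (1 - f) / (1 + (w - 1) f).
# The effective potential U(f) = -2N * integral of A/B is unimodal for the
# spatial model with an unstable maximum at f_eq = 1/(1 + sqrt(w)).

#' Continuum drift and diffusion of the boundary position
#'
#' Drift `A(f)` and diffusion `B(f)` of the continuum (Fokker-Planck) limit
#' of the discrete boundary dynamics, in units of 1/time.  `A` is the large-N
#' limit of `N [r+(n) - r-(n)] / N` evaluated at `n = f N`; likewise `B`
#' with the sum of rates.  For the spatial exclusion model `A` vanishes
#' only at the equiprobable takeover abundance [equiprobable_abundance()].
#'
#' @param params A [competition_params()] object.
#' @param f Fractional abundance(s) in `[0, 1]`.
#' @param model `"spatial"` (default) or `"moran"`.
#' @return Numeric vector of the same length as `f`.
#'
#' @examples
#' p <- competition_params(100, w = 4)
#' drift(p, 1/3)  # zero: f_eq = 1/(1 + sqrt(4))
#' @export
drift <- function(params, f, model = c("spatial", "moran")) {
  params <- as_competition_params(params)
  model <- match.arg(model)
  stopifnot(all(f >= 0 & f <= 1))
  N <- params$N; w <- params$w; r <- params$r
  if (model == "spatial")
    r * N * ((w - 1) * f^2 + 2 * f - 1) / (2 * (1 + f * (w - 1)))
  else
    r * N * (w - 1) * f * (1 - f) / (1 + (w - 1) * f)
}

#' @rdname drift
#' @export
diffusion <- function(params, f, model = c("spatial", "moran")) {
  params <- as_competition_params(params)
  model <- match.arg(model)
  stopifnot(all(f >= 0 & f <= 1))
  N <- params$N; w <- params$w; r <- params$r
  if (model == "spatial")
    r * N * (w * f^2 + (1 - f)^2) / (2 * (1 + f * (w - 1)))
  else
    r * N * (w + 1) * f * (1 - f) / (1 + (w - 1) * f)
}

#' Equiprobable takeover abundance
#'
#' The initial fractional abundance at which both species are equally
#' likely to take over the channel: the unique zero of the spatial drift
#' `A(f)` in `(0, 1)`, i.e. the positive root of
#' `(w - 1) f^2 + 2 f - 1 = 0`,
#' \deqn{f_{eq} = \frac{1}{1 + \sqrt{w}}.}
#' Equals 1/2 in the neutral case and decreases monotonically toward 0 as
#' the fitness advantage grows.
#'
#' @param w Relative fitness (positive scalar or vector).
#' @return Numeric vector in `(0, 1)`.
#' @export
equiprobable_abundance <- function(w) {
  stopifnot(all(w > 0))
  1 / (1 + sqrt(w))
}

# Closed-form antiderivative of A(y)/B(y) for the spatial model.
# A/B = [(w-1)y^2 + 2y - 1] / [(w+1)y^2 - 2y + 1]; partial fractions give
#   G(y) = alpha y + c1 log Q(y) + (c2/sqrt(w)) atan(((w+1)y - 1)/sqrt(w))
# with Q(y) = (w+1)y^2 - 2y + 1 > 0 (discriminant -4w < 0),
# alpha = (w-1)/(w+1), c1 = (1+alpha)/(w+1), c2 = (1+alpha)(1-w)/(1+w).
.ab_antiderivative <- function(y, w) {
  alpha <- (w - 1) / (w + 1)
  c1 <- (1 + alpha) / (w + 1)
  c2 <- (1 + alpha) * (1 - w) / (1 + w)
  Q <- (w + 1) * y^2 - 2 * y + 1
  alpha * y + c1 * log(Q) + (c2 / sqrt(w)) * atan(((w + 1) * y - 1) / sqrt(w))
}

#' Fokker-Planck potential of the spatial exclusion model
#'
#' The effective landscape `U(f) = -2N * integral of A(y)/B(y) dy` in which
#' the inter-species boundary moves (dimensionless; the basal rate cancels
#' in the ratio).  Normalised so that `U(f_eq) = 0` at its single interior
#' maximum; the values at the channel ends are of order `-N`, so ratios of
#' `exp(U)` are always formed with the peak value subtracted.
#'
#' Evaluated from the closed-form antiderivative of the rational integrand
#' (a linear + logarithmic + arctangent term), which is exact and cheap
#' enough to sit inside nested quadrature.  In the neutral case it reduces
#' to `U(f) = -N log(2 (2 f^2 - 2 f + 1))`.
#'
#' @param params A [competition_params()] object.
#' @param f Fractional abundance(s) in `[0, 1]`.
#' @return Numeric vector, `<= 0`, zero at `f_eq`.
#' @export
fp_potential <- function(params, f) {
  params <- as_competition_params(params)
  stopifnot(all(f >= 0 & f <= 1))
  w <- params$w
  feq <- equiprobable_abundance(w)
  -2 * params$N * (.ab_antiderivative(f, w) - .ab_antiderivative(feq, w))
}

# U'(f) = -2N A/B, and U''(f_eq) = -4 N sqrt(w) / Q(f_eq) (since A(f_eq)=0
# the quotient-rule derivative collapses to A'(f_eq)/B(f_eq) with
# A'(f_eq) = 2 sqrt(w) * B-denominator cancellation).
.u_prime <- function(params, f) {
  w <- params$w
  -2 * params$N * ((w - 1) * f^2 + 2 * f - 1) / ((w + 1) * f^2 - 2 * f + 1)
}

.u_curvature_at_peak <- function(params) {
  w <- params$w
  feq <- equiprobable_abundance(w)
  Q <- (w + 1) * feq^2 - 2 * feq + 1
  -4 * params$N * sqrt(w) / Q
}

# Internal dense evaluation mesh: uniform base refined around the potential
# peak (the exp(U) mass concentrates in a window of width ~ N^{-1/2}).
.fp_mesh <- function(params, model, n_base = 4001L, n_peak = 2001L) {
  base <- seq(0, 1, length.out = n_base)
  if (model != "spatial") return(base)
  feq <- equiprobable_abundance(params$w)
  delta <- 1 / sqrt(abs(.u_curvature_at_peak(params)))
  lo <- max(0, feq - 30 * delta); hi <- min(1, feq + 30 * delta)
  sort(unique(c(base, seq(lo, hi, length.out = n_peak))))
}

#' Continuum fixation probability
#'
#' Solves the continuum backward equation
#' `0 = A P' + B/(2N) P''` with `P(0) = 0`, `P(1) = 1` via the potential:
#' \deqn{P_1(f) = \int_0^f e^{U(y)}\,dy \Big/ \int_0^1 e^{U(y)}\,dy,}
#' evaluated by cumulative trapezoidal quadrature on a mesh refined around
#' the potential peak, with the peak value of `U` subtracted before
#' exponentiating (all weights `<= 1`, stable up to `N ~ 1e4`).
#'
#' For the neutral Moran model (`A == 0`) this reduces to `P_1(f) = f`.
#'
#' @param params A [competition_params()] object.
#' @param grid Ordered fractional abundances in `[0, 1]` at which to return
#'   the probability.
#' @param model `"spatial"` or `"moran"`.
#' @return Numeric vector of probabilities on `grid`.
#' @export
fp_fixation_probability <- function(params, grid = seq(0, 1, length.out = 2001),
                                    model = c("spatial", "moran")) {
  params <- as_competition_params(params)
  model <- match.arg(model)
  stopifnot(all(grid >= 0 & grid <= 1), !is.unsorted(grid))
  mesh <- .fp_mesh(params, model)
  U <- if (model == "spatial") fp_potential(params, mesh)
       else -2 * params$N * (params$w - 1) / (params$w + 1) * mesh
  U <- U - max(U)
  cum <- pracma::cumtrapz(mesh, exp(U))[, 1]
  p <- stats::approx(mesh, cum / cum[length(cum)], xout = grid,
                     yleft = 0, yright = 1)$y
  pmin(pmax(p, 0), 1)
}

#' Continuum mean first-passage time
#'
#' Solves the continuum backward boundary-value problem
#' `-1 = A(f)/N tau' + B(f)/(2 N^2) tau''` with `tau(0) = tau(1) = 0` by a
#' direct sparse finite-difference solve on a uniform mesh whose spacing
#' scales as `1/(20 N)` (capped at 40001 nodes), keeping the cell Peclet
#' number well below 1 so central differencing is stable.  The result is
#' interpolated onto `grid`.
#'
#' @inheritParams fp_fixation_probability
#' @param mesh_n Optional mesh size override (odd integer recommended).
#' @return Numeric vector of times (units `1/r`) on `grid`.
#' @export
fp_mfpt <- function(params, grid = seq(0, 1, length.out = 2001),
                    model = c("spatial", "moran"), mesh_n = NULL) {
  params <- as_competition_params(params)
  model <- match.arg(model)
  stopifnot(all(grid >= 0 & grid <= 1), !is.unsorted(grid))
  N <- params$N
  if (is.null(mesh_n)) mesh_n <- max(2001L, min(20L * N + 1L, 40001L))
  mesh <- seq(0, 1, length.out = mesh_n)
  h <- mesh[2] - mesh[1]
  fi <- mesh[2:(mesh_n - 1L)]
  a <- drift(params, fi, model) / N
  d <- diffusion(params, fi, model) / (2 * N^2)
  lower <- (d / h^2 - a / (2 * h))[-1]
  diagm <- -2 * d / h^2
  upper <- (d / h^2 + a / (2 * h))[-(mesh_n - 2L)]
  L <- Matrix::bandSparse(mesh_n - 2L, k = -1:1,
                          diagonals = list(lower, diagm, upper))
  tau <- c(0, as.numeric(Matrix::solve(L, rep(-1, mesh_n - 2L))), 0)
  stats::approx(mesh, tau, xout = grid, yleft = 0, yright = 0)$y
}

#' Deterministic fixation time
#'
#' Outside the diffusive region around `f_eq` the abundance follows the
#' quasi-deterministic flow `df/dt = A(f)/N`, whose exact time to reach the
#' nearer absorbing end from `f` is
#' \deqn{\tau_{det}(f) = -\frac{1}{r}\Big(\log\big|(w-1)f^2 + 2f - 1\big|
#'   - \Theta(f - f_{eq})\,\log w\Big),}
#' with the Heaviside step ensuring `tau_det(0) = tau_det(1) = 0` and
#' continuity with the neutral case.  Diverges logarithmically at `f_eq`,
#' where the deterministic picture breaks down; evaluation exactly at
#' `f_eq` is an error.
#'
#' @param params A [competition_params()] object.
#' @param f Fractional abundance(s) in `[0, 1]`, none equal to `f_eq`.
#' @return Numeric vector of times (units `1/r`).
#'
#' @examples
#' tau_det(competition_params(100, w = 1), 0.75)  # log(2)
#' @export
tau_det <- function(params, f) {
  params <- as_competition_params(params)
  stopifnot(all(f >= 0 & f <= 1))
  w <- params$w
  feq <- equiprobable_abundance(w)
  if (any(f == feq))
    stop("tau_det diverges at the equiprobable abundance f_eq = ",
         signif(feq, 6))
  -(1 / params$r) * (log(abs((w - 1) * f^2 + 2 * f - 1)) -
                       (f > feq) * log(w))
}

#' Boundaries of the stochastic (tug-of-war) region
#'
#' The interval around `f_eq` where diffusion dominates the dynamics.  Its
#' boundaries solve `|U'(f_t)| = sqrt(|U''(f_eq)| / pi)`: the potential
#' slope at the edge of the region matches the curvature scale of the peak.
#' Since `U'' ~ N` the width shrinks as `N^{-1/2}`; in the neutral case
#' `f_t = 1/2 +/- sqrt(1/(8 pi N))`.  Solved by bracketed root-finding on
#' each side of `f_eq` to `1e-10` in `f`.
#'
#' @param params A [competition_params()] object.
#' @return Named numeric vector `c(f_t_minus, f_t_plus)`.
#' @export
stochastic_region <- function(params) {
  params <- as_competition_params(params)
  target <- sqrt(abs(.u_curvature_at_peak(params)) / pi)
  feq <- equiprobable_abundance(params$w)
  g <- function(f) abs(.u_prime(params, f)) - target
  if (g(1e-9) < 0 || g(1 - 1e-9) < 0)
    stop("stochastic-region boundary not bracketed in (0, 1); N too small")
  lo <- stats::uniroot(g, c(1e-9, feq), tol = 1e-12)$root
  hi <- stats::uniroot(g, c(feq, 1 - 1e-9), tol = 1e-12)$root
  c(f_t_minus = lo, f_t_plus = hi)
}

#' Estimate the diffusive residual of the maximal fixation time
#'
#' The maximal mean fixation time of the spatial model grows as
#' `(1/2) log(pi N)` plus an N-independent diffusive residual `tau_dif`.
#' This estimates the residual by computing the exact discrete MFPT at the
#' state nearest `N * f_eq` for each size in `N_list` (via the tridiagonal
#' solver), subtracting `(1/2) log(pi N)` and averaging.  The per-size
#' residuals are returned as well so flatness in `N` can be checked.
#'
#' Note the additive convention: with `2 pi N` inside the logarithm the
#' residual shifts by `(1/2) log 2 ~ 0.35`; this package follows the
#' `pi N` form throughout.
#'
#' @param params A [competition_params()] object (its `N` is ignored).
#' @param N_list Increasing integer vector of at least three system sizes.
#' @return A list with `tau_dif` (mean residual) and `residuals`
#'   (named per-size vector).
#' @export
estimate_tau_dif <- function(params, N_list = c(500L, 1000L, 2000L, 4000L)) {
  params <- as_competition_params(params)
  if (length(N_list) < 3) stop("'N_list' needs at least 3 sizes")
  if (is.unsorted(N_list)) stop("'N_list' must be increasing")
  feq <- equiprobable_abundance(params$w)
  res <- vapply(N_list, function(N) {
    pN <- competition_params(N, w = params$w, r = params$r)
    tau <- mfpt_unconditional(spatial_rates(pN))
    tau[round(N * feq) + 1L] - 0.5 * log(pi * N)
  }, numeric(1))
  names(res) <- N_list
  list(tau_dif = mean(res), residuals = res)
}

#' Asymptotic decomposition of the maximal fixation time
#'
#' Approximates the maximal mean fixation time (attained near `f_eq`) as an
#' escape from the stochastic region followed by a deterministic descent:
#' `tau_a = tau_det(f_t+/-) + tau_dif`, which grows as
#' `(1/2) log(pi N) + tau_dif` for large `N`.  The deterministic part is
#' the average of the two boundary values (they coincide at `w = 1` by
#' mirror symmetry, reflecting the equal probability of escaping either
#' side of the peak).
#'
#' @param params A [competition_params()] object.
#' @param tau_dif The diffusive residual; `NULL` (default) estimates it via
#'   [estimate_tau_dif()] on `tau_dif_N_list`.
#' @param tau_dif_N_list Sizes used for the residual estimate.
#' @return An object of class `asymptotic_decomposition`: a list with
#'   `N`, `w`, `f_eq`, `f_t_minus`, `f_t_plus`, `tau_det_at_boundary`,
#'   `tau_dif`, `tau_a`.
#' @export
tau_max_approx <- function(params, tau_dif = NULL,
                           tau_dif_N_list = c(500L, 1000L, 2000L)) {
  params <- as_competition_params(params)
  ft <- stochastic_region(params)
  td <- mean(tau_det(params, ft))
  if (is.null(tau_dif))
    tau_dif <- estimate_tau_dif(params, tau_dif_N_list)$tau_dif
  structure(list(N = params$N, w = params$w,
                 f_eq = equiprobable_abundance(params$w),
                 f_t_minus = unname(ft[1]), f_t_plus = unname(ft[2]),
                 tau_det_at_boundary = td, tau_dif = tau_dif,
                 tau_a = td + tau_dif),
            class = "asymptotic_decomposition")
}

#' @export
print.asymptotic_decomposition <- function(x, ...) {
  cat("Asymptotic maximal-MFPT decomposition\n")
  cat(sprintf("  N = %d, w = %g, f_eq = %.6f\n", x$N, x$w, x$f_eq))
  cat(sprintf("  stochastic region [%.6f, %.6f] (width %.3g)\n",
              x$f_t_minus, x$f_t_plus, x$f_t_plus - x$f_t_minus))
  cat(sprintf("  tau_det(f_t) = %.4f, tau_dif = %.4f  =>  tau_a = %.4f\n",
              x$tau_det_at_boundary, x$tau_dif, x$tau_a))
  invisible(x)
}

#' Export the continuum fields to CSV
#'
#' Writes columns `f, A, B, U, P1_fp, mfpt_fp` on a uniform grid.
#'
#' @param params A [competition_params()] object.
#' @param path Output CSV path.
#' @param grid Evaluation grid in `[0, 1]`.
#' @export
write_continuum_csv <- function(params, path,
                                grid = seq(0, 1, length.out = 2001)) {
  params <- as_competition_params(params)
  out <- data.frame(
    f = grid,
    A = drift(params, grid),
    B = diffusion(params, grid),
    U = fp_potential(params, grid),
    P1_fp = fp_fixation_probability(params, grid),
    mfpt_fp = fp_mfpt(params, grid)
  )
  .write_num_csv(out, path)
  invisible(path)
}
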