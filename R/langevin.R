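#' Parameters of the coarse-grained Langevin dynamics
#'
#' The agent's long-time motion is approximated by
#' \deqn{dx = \chi \nabla \log R(x)\, dt + \sqrt{2D}\, dW}
#' (a single-agent Keller-Segel/Langevin description). Its stationary law is
#' \eqn{P(x) \propto R(x)^\beta} with \eqn{\beta = \chi / D}.
#'
#' @param D Diffusion coefficient, cm^2/s, positive.
#' @param chi Advection (chemotactic drift) coefficient, cm^2/s.
#' @param m Spatial dimension.
#' @return A `langevin_params` object with derived `beta`.
#' @export
langevin_params <- function(D, chi, m = 1) {
  if (!is.numeric(D) || D <= 0) stop("`D` must be positive")
  if (!is.numeric(chi) || !is.finite(chi)) stop("`chi` must be finite")
  if (!m %in% 1:3) stop("`m` must be 1, 2 or 3")
  structure(list(D = D, chi = chi, m = as.integer(m), beta = chi / D),
            class = "langevin_params")
}

#' @export
print.langevin_params <- function(x, ...) {
  cat(sprintf("Langevin coefficients: D = %g cm^2/s, chi = %g cm^2/s, beta = chi/D = %g (m = %d)\n",
              x$D, x$chi, x$beta, x$m))
  invisible(x)
}

#' Euler-Maruyama simulation of the coarse-grained dynamics
#'
#' Integrates \eqn{dx = \chi \nabla \log R\, dt + \sqrt{2D}\, dW} with
#' fixed-step Euler-Maruyama, reflecting boundaries, and seed-deterministic
#' Gaussian increments. `drift_mode = "gradR"` replaces the logarithmic
#' gradient by the plain gradient \eqn{\chi \nabla R} -- the
#' non-logarithmic control, which does not produce power-law matching.
#'
#' @param params A [langevin_params()] object.
#' @param field A parametric [reward_field()].
#' @param T Duration, s.
#' @param dt Step, s.
#' @param seed Integer seed.
#' @param x_init Initial position (defaults to the origin).
#' @param box As in [simulate_taxis()].
#' @param record_dt Spacing of recorded samples, s.
#' @param centers,window Optional residence-time windows accumulated at
#'   full resolution.
#' @param burn_in Fraction of the path excluded from the occupancy
#'   accumulators (default 0).
#' @param drift_mode `"loggrad"` (default) or `"gradR"`.
#' @return A `langevin_trajectory` list with `times`, `positions`,
#'   `occupancy` and the parameters used.
#' @examples
#' lp <- langevin_params(D = 10, chi = 8)
#' fld <- make_gaussian_field(4, 1)
#' tr <- simulate_langevin(lp, fld, T = 100, dt = 0.01, seed = 1)
#' @export
simulate_langevin <- function(params, field, T, dt = 0.01, seed = NULL,
                              x_init = NULL, box = NULL, record_dt = 0.5,
                              centers = NULL, window = 2.5, burn_in = 0,
                              drift_mode = c("loggrad", "gradR")) {
  stopifnot(inherits(params, "langevin_params"),
            inherits(field, "reward_field"))
  drift_mode <- match.arg(drift_mode)
  if (params$m != field$m) stop("params and field dimensions differ")
  desc <- field_descriptor(field)
  m <- field$m
  if (is.null(x_init)) x_init <- rep(0, m)
  stopifnot(length(x_init) == m)

  if (identical(box, "none")) box <- NULL
  else if (is.null(box)) box <- default_box(field)
  box_lo <- if (is.null(box)) numeric(0) else as.numeric(box$lo)
  box_hi <- if (is.null(box)) numeric(0) else as.numeric(box$hi)

  cmat <- if (is.null(centers)) matrix(numeric(0), 0, m) else
    as_points(centers, m)
  if (!is.null(seed)) set.seed(seed)
  rec_every <- max(1L, as.integer(round(record_dt / dt)))

  raw <- .run_langevin_cpp(desc, params$D, params$chi, as.numeric(x_init),
                           T, dt, box_lo, box_hi, rec_every, cmat, window,
                           if (drift_mode == "loggrad") 0L else 1L, burn_in)
  structure(c(raw, list(params = params, field = field, dt = dt, T = T,
                        centers = cmat, window = window,
                        drift_mode = drift_mode)),
            class = "langevin_trajectory")
}

#' @export
print.langevin_trajectory <- function(x, ...) {
  cat(sprintf("Langevin trajectory: T = %g s (dt = %g s), %d recorded samples, beta = %g\n",
              x$T, x$dt, length(x$times), x$params$beta))
  invisible(x)
}

#' Closed-form stationary law of the Langevin dynamics
#'
#' On a stated domain the stationary density is
#' \eqn{P(x) = R(x)^\beta / Z} with \eqn{Z = \int R(x)^\beta dx} computed
#' by quadrature (1D). \eqn{\beta = 0} gives the uniform law; \eqn{\beta=1}
#' is perfect matching (occupancy ratios equal reward ratios).
#'
#' @param params A [langevin_params()] object, or a bare numeric `beta`.
#' @param field A [reward_field()] (1D for the normalised density).
#' @param domain Length-2 numeric, integration domain.
#' @return A `stationary_law` list with `beta`, `density` (a function of
#'   x), `Z`, and `domain`.
#' @export
stationary_density <- function(params, field, domain) {
  beta <- if (inherits(params, "langevin_params")) params$beta else
    as.numeric(params)
  stopifnot(inherits(field, "reward_field"), length(domain) == 2L,
            domain[1] < domain[2])
  if (field$m != 1L)
    stop("the normalised stationary density is provided in 1D")
  un <- function(x) eval_field(field, x)^beta
  Z <- integrate(un, domain[1], domain[2], rel.tol = 1e-10,
                 subdivisions = 2000L)$value
  if (!is.finite(Z) || Z <= 0) stop("R(x)^beta is not integrable on domain")
  structure(list(beta = beta, Z = Z, domain = domain,
                 density = function(x) un(x) / Z, field = field),
            class = "stationary_law")
}

#' @export
print.stationary_law <- function(x, ...) {
  cat(sprintf("stationary law P(x) = R(x)^%g / Z on [%g, %g], Z = %g\n",
              x$beta, x$domain[1], x$domain[2], x$Z))
  invisible(x)
}

#' Stationary occupancy ratio between two locations
#'
#' \eqn{P(x_1)/P(x_2) = (R(x_1)/R(x_2))^\beta}: the generalized matching
#' law in its two-point form (with bias \eqn{k = 1}).
#'
#' @param law A `stationary_law` from [stationary_density()], or a numeric
#'   `beta` (then `field` must be given).
#' @param x1,x2 Locations.
#' @param field Field, required when `law` is a bare exponent.
#' @return The ratio \eqn{(R(x_1)/R(x_2))^\beta}.
#' @export
stationary_ratio <- function(law, x1, x2, field = NULL) {
  if (inherits(law, "stationary_law")) {
    beta <- law$beta; field <- law$field
  } else {
    beta <- as.numeric(law)
    if (is.null(field)) stop("`field` required with a bare exponent")
  }
  (eval_field(field, x1) / eval_field(field, x2))^beta
}

#' Empirical occupancy histogram of a trajectory
#'
#' Normalised histogram of the recorded positions (1D), for comparison with
#' [stationary_density()] via [l1_distance()].
#'
#' @param traj A trajectory with recorded `positions`.
#' @param breaks Bin edges.
#' @param burn_in Fraction of each path to discard before counting
#'   (default 0.2).
#' @return List with `mids`, `density` (per-unit-length), `breaks`.
#' @export
occupancy_histogram <- function(traj, breaks, burn_in = 0.2) {
  pos <- traj$positions
  pos <- if (is.matrix(pos)) pos[, 1L] else pos
  n <- length(pos)
  keep <- pos[seq.int(floor(burn_in * n) + 1L, n)]
  h <- graphics::hist(keep[keep >= min(breaks) & keep <= max(breaks)],
                      breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density, breaks = breaks,
       counts = h$counts)
}

#' L1 distance between an empirical histogram and a stationary law
#'
#' \eqn{\int |\hat p(x) - p(x)| dx} approximated on the histogram bins,
#' with the reference density averaged over each bin.
#'
#' @param hist_obj Result of [occupancy_histogram()] (or pooled
#'   counts/density on the same breaks).
#' @param law A `stationary_law`.
#' @return The L1 distance (0 = identical, 2 = disjoint).
#' @export
l1_distance <- function(hist_obj, law) {
  widths <- diff(hist_obj$breaks)
  p_ref <- vapply(seq_along(hist_obj$mids), function(i) {
    integrate(law$density, hist_obj$breaks[i], hist_obj$breaks[i + 1L],
              rel.tol = 1e-8)$value
  }, numeric(1))
  p_emp <- hist_obj$density * widths
  sum(abs(p_emp - p_ref / sum(p_ref)))
}
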