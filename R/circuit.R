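#' Circuit parameters for the dopamine FCD model
#'
#' Bundles the constants of the minimal dopamine/GABA circuit
#' \deqn{\dot d = \omega_d (C + \mu \log R - \alpha g - d)}
#' \deqn{\dot g = \omega (d/d_0 - 1)}
#' where \eqn{d} is dopaminergic and \eqn{g} GABAergic population activity
#' (spikes/s) and \eqn{R(t) > 0} is the expected-reward input. The feedback
#' loop gives exact adaptation (the only steady state is \eqn{d = d_0}) and,
#' because the input enters through its logarithm, fold-change detection.
#'
#' Two named parameter sets are provided, estimated from mouse and primate
#' recordings respectively; see [circuit_preset()].
#'
#' @param omega_d Dopamine relaxation rate, 1/s. Must be positive.
#' @param omega Adaptation (integral feedback) rate, 1/s. Must be positive.
#' @param C Baseline drive when \eqn{\log R = g = 0}, spikes/s.
#' @param mu Gain of the logarithmic activation, spikes/s. Non-negative.
#' @param alpha GABAergic inhibition strength, dimensionless, positive.
#' @param d0 Adapted dopamine level, spikes/s, positive.
#' @param variant One of `"feedback"` (integral feedback, the default),
#'   `"feedforward"` (incoherent feed-forward loop with the same FCD
#'   property), `"quasi_static"` (the fast-dopamine limit where \eqn{d}
#'   is eliminated algebraically), or `"rectified"` (a non-negative variant
#'   with drive \eqn{\max(0, C + \mu\log R - \alpha g - k_d)}).
#' @param k_d Rectification constant, spikes/s; used only by the rectified
#'   variant. For \eqn{k_d \ll d_0} the rectified model converges to the
#'   feedback model.
#'
#' @return An object of class `circuit_params`.
#' @examples
#' p <- circuit_params() # Table-of-constants mouse set
#' steady_state(p, R0 = 1)
#' @export
circuit_params <- function(omega_d = 50, omega = 15, C = 15, mu = 6,
                           alpha = 0.7, d0 = 5,
                           variant = c("feedback", "feedforward",
                                       "quasi_static", "rectified"),
                           k_d = 1) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(omega_d), length(omega_d) == 1L,
            is.numeric(omega), is.numeric(C), is.numeric(mu),
            is.numeric(alpha), is.numeric(d0), is.numeric(k_d))
  if (omega_d <= 0) stop("`omega_d` must be positive")
  if (omega <= 0) stop("`omega` must be positive")
  if (mu < 0) stop("`mu` must be non-negative")
  if (alpha <= 0) stop("`alpha` must be positive")
  if (d0 <= 0) stop("`d0` must be positive")
  if (k_d < 0) stop("`k_d` must be non-negative")
  if (omega_d < 2 * omega)
    warning("intended regime is omega_d >> omega; got omega_d = ", omega_d,
            ", omega = ", omega)
  structure(list(omega_d = omega_d, omega = omega, C = C, mu = mu,
                 alpha = alpha, d0 = d0, variant = variant, k_d = k_d),
            class = "circuit_params")
}

#' Named circuit parameter presets
#'
#' Constants estimated from mouse VTA recordings (`"mouse"`:
#' \eqn{\omega_d = 50}, \eqn{\omega = 15}/s) and from primate recordings
#' (`"primate"`: \eqn{\omega_d = 100}, \eqn{\omega = 30}/s); both share
#' \eqn{C = 15}, \eqn{\mu = 6}, \eqn{\alpha = 0.7}, \eqn{d_0 = 5}.
#'
#' @param name `"mouse"` or `"primate"`.
#' @param ... Overrides passed on to [circuit_params()].
#' @return A `circuit_params` object.
#' @export
circuit_preset <- function(name = c("mouse", "primate"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    mouse   = list(omega_d = 50, omega = 15),
    primate = list(omega_d = 100, omega = 30))
  args <- modifyList(c(base, list(C = 15, mu = 6, alpha = 0.7, d0 = 5)),
                     list(...))
  do.call(circuit_params, args)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Dopamine FCD circuit parameters (variant: ", x$variant, ")\n",
      sep = "")
  cat(sprintf("  omega_d = %g /s, omega = %g /s\n", x$omega_d, x$omega))
  cat(sprintf("  C = %g, mu = %g, d0 = %g spikes/s, alpha = %g\n",
              x$C, x$mu, x$d0, x$alpha))
  if (x$variant == "rectified") cat(sprintf("  k_d = %g spikes/s\n", x$k_d))
  invisible(x)
}

#' Steady state of the circuit under a constant input
#'
#' For a constant expected reward \eqn{R_0}, the feedback circuit settles at
#' \eqn{d_{st} = d_0} and \eqn{g_{st} = \alpha^{-1}(C - d_0 + \mu\log R_0)}
#' -- exact adaptation: the dopamine steady state does not depend on the
#' input. The feed-forward variant also has \eqn{d_{st} = d_0}, with
#' \eqn{g_{st} = (C + \mu\log R_0)/\alpha}; the rectified variant has
#' \eqn{g_{st} = \alpha^{-1}(C - d_0 - k_d + \mu\log R_0)}.
#'
#' @param params A [circuit_params()] object.
#' @param R0 Constant expected reward, positive scalar.
#' @return A `circuit_state` list with elements `d`, `g` (spikes/s) and `t`.
#' @examples
#' steady_state(circuit_preset("mouse"), R0 = exp(1))
#' @export
steady_state <- function(params, R0) {
  stopifnot(inherits(params, "circuit_params"))
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 <= 0)
    stop("`R0` must be a positive finite scalar")
  g <- with(params, switch(variant,
    feedback     = (C - d0 + mu * log(R0)) / alpha,
    quasi_static = (C - d0 + mu * log(R0)) / alpha,
    feedforward  = (C + mu * log(R0)) / alpha,
    rectified    = (C - d0 - k_d + mu * log(R0)) / alpha))
  structure(list(d = params$d0, g = g, t = 0), class = "circuit_state")
}

#' Quasi-static dopamine output
#'
#' The fast-dopamine limit eliminates \eqn{d} algebraically:
#' \eqn{d = C + \mu\log R - \alpha g}. The rectified variant returns
#' \eqn{\max(0, C + \mu\log R - \alpha g - k_d)}.
#'
#' @param params A [circuit_params()] object.
#' @param R Expected reward, positive scalar (vectorised).
#' @param g GABAergic activity, spikes/s.
#' @return Dopamine output, spikes/s.
#' @export
quasi_static_output <- function(params, R, g) {
  stopifnot(inherits(params, "circuit_params"))
  if (any(!is.finite(R)) || any(R <= 0))
    stop("`R` must be positive and finite")
  f <- params$C + params$mu * log(R) - params$alpha * g
  if (params$variant == "rectified") pmax(0, f - params$k_d) else f
}

# Drive term of the d-equation for each variant, given log R and g.
circuit_drive <- function(params, logR, g) {
  f <- params$C + params$mu * logR - params$alpha * g
  switch(params$variant,
    feedback     = f,
    quasi_static = f,
    feedforward  = params$d0 + f,
    rectified    = pmax(0, f - params$k_d))
}

#' Simulate the circuit under a time-dependent expected-reward input
#'
#' Integrates the two-ODE system (or the one-ODE quasi-static limit) with
#' `deSolve::lsoda`, restarting the integrator at each discontinuity of the
#' input signal so that step inputs are treated as exact discontinuities
#' rather than smoothed ramps.
#'
#' @param params A [circuit_params()] object.
#' @param R A [reward_signal()] object, or a plain function of time
#'   returning a positive expected reward.
#' @param t_grid Strictly increasing vector of output times, s.
#' @param init Either the string `"adapted"` (start at the steady state for
#'   `R(t_grid[1])`, the default) or a `circuit_state` / numeric vector
#'   `c(d, g)`.
#' @param rtol,atol Integrator tolerances passed to `deSolve::lsoda`.
#' @return A `circuit_trace`: data frame with columns `t`, `R`, `logR`,
#'   `d`, `g`, carrying the parameters as an attribute.
#' @examples
#' tr <- simulate_circuit(circuit_preset("mouse"),
#'                        make_step(R0 = 1, lam = 7, t0 = 1),
#'                        t_grid = seq(0, 3, by = 1e-3))
#' max(tr$d) # transient excursion above d0 = 5
#' @export
simulate_circuit <- function(params, R, t_grid, init = "adapted",
                             rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(params, "circuit_params"))
  sig <- as_reward_signal(R)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("`t_grid` must be strictly increasing with at least two points")
  Rvals <- eval_signal(sig, t_grid)
  if (any(!is.finite(Rvals)) || any(Rvals <= 0))
    stop("expected-reward input must be positive and finite on the grid")

  if (identical(init, "adapted")) {
    st <- steady_state(params, Rvals[1L])
    y0 <- c(d = st$d, g = st$g)
  } else if (inherits(init, "circuit_state")) {
    y0 <- c(d = init$d, g = init$g)
  } else {
    stopifnot(is.numeric(init), length(init) == 2L)
    y0 <- c(d = init[[1L]], g = init[[2L]])
  }

  quasi <- params$variant == "quasi_static"
  deriv <- function(t, y, parms) {
    logR <- log(eval_signal(sig, t))
    if (quasi) {
      d <- circuit_drive(params, logR, y[["g"]])
      list(params$omega * (d / params$d0 - 1))
    } else {
      ddot <- params$omega_d *
        (circuit_drive(params, logR, y[["g"]]) - y[["d"]])
      gdot <- params$omega * (y[["d"]] / params$d0 - 1)
      list(c(ddot, gdot))
    }
  }
  y <- if (quasi) c(g = y0[["g"]]) else y0

  # integrate piecewise between input discontinuities
  brk <- signal_breaks(sig)
  brk <- brk[brk > t_grid[1L] & brk < t_grid[length(t_grid)]]
  edges <- c(t_grid[1L], sort(unique(brk)), t_grid[length(t_grid)])
  out_t <- numeric(0); out_y <- NULL
  for (i in seq_len(length(edges) - 1L)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    # output times inside this smooth piece; evaluate input just above lo
    tt <- t_grid[t_grid >= lo & t_grid <= hi]
    tt <- sort(unique(c(lo, tt, hi)))
    sig_piece <- shift_signal_eval(sig, lo, hi)
    deriv_piece <- function(t, yy, parms) {
      logR <- log(sig_piece(t))
      if (quasi) {
        d <- circuit_drive(params, logR, yy[["g"]])
        list(params$omega * (d / params$d0 - 1))
      } else {
        ddot <- params$omega_d *
          (circuit_drive(params, logR, yy[["g"]]) - yy[["d"]])
        gdot <- params$omega * (yy[["d"]] / params$d0 - 1)
        list(c(ddot, gdot))
      }
    }
    sol <- deSolve::lsoda(y, tt, deriv_piece, rtol = rtol, atol = atol)
    keep <- sol[, 1L] %in% t_grid & !(sol[, 1L] %in% out_t)
    out_t <- c(out_t, sol[keep, 1L])
    out_y <- rbind(out_y, sol[keep, -1L, drop = FALSE])
    y <- sol[nrow(sol), -1L]
    names(y) <- if (quasi) "g" else c("d", "g")
  }
  ord <- order(out_t)
  out_t <- out_t[ord]; out_y <- out_y[ord, , drop = FALSE]
  gg <- if (quasi) out_y[, 1L] else out_y[, 2L]
  dd <- if (quasi) {
    circuit_drive(params, log(Rvals), gg)
  } else out_y[, 1L]
  tr <- data.frame(t = out_t, R = Rvals, logR = log(Rvals), d = dd, g = gg)
  attr(tr, "params") <- params
  class(tr) <- c("circuit_trace", "data.frame")
  tr
}

# Evaluator for one smooth piece (lo, hi]: values at the left edge and at
# interior probe points requested by the adaptive integrator are taken from
# just inside the piece, so the discontinuity at lo is seen as sharp.
shift_signal_eval <- function(sig, lo, hi) {
  eps <- max(1e-12, (hi - lo) * 1e-12)
  function(t) eval_signal(sig, pmin(pmax(t, lo + eps), hi))
}

#' Peak response amplitude of a circuit trace
#'
#' Signed extremum of \eqn{d - d_0} within a time window: the excursion with
#' the larger magnitude, with its sign. This is the "peak firing change"
#' convention used to quantify phasic responses.
#'
#' @param trace A `circuit_trace` from [simulate_circuit()].
#' @param window Length-2 numeric, time interval (inclusive). Defaults to
#'   the whole trace.
#' @param d0 Baseline; defaults to the `d0` of the parameters stored in the
#'   trace.
#' @return Signed amplitude, spikes/s.
#' @export
response_amplitude <- function(trace, window = NULL, d0 = NULL) {
  stopifnot(inherits(trace, "circuit_trace") || is.data.frame(trace))
  if (is.null(d0)) {
    p <- attr(trace, "params")
    if (is.null(p)) stop("no `d0` supplied and trace has no parameters")
    d0 <- p$d0
  }
  if (is.null(window)) window <- range(trace$t)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  sel <- trace$t >= window[1] & trace$t <= window[2]
  if (!any(sel)) stop("window contains no trace points")
  dev <- trace$d[sel] - d0
  dev[which.max(abs(dev))]
}

#' Dopamine response to reward delivery after adaptation to a prediction
#'
#' After the circuit has adapted to a predicted value \eqn{V(s)}, delivery
#' of a reward \eqn{r} with successor value \eqn{V(s')} produces
#' \deqn{\Delta d = \mu\,(\log(r + V(s')) - \log V(s)),}
#' i.e. the gain times the logarithmic prediction error. A fulfilled
#' prediction (\eqn{r + V(s') = V(s)}) gives no response; omission gives a
#' negative response.
#'
#' @param params A [circuit_params()] object (only `mu` is used).
#' @param V_s Predicted value of the current state, positive.
#' @param r Delivered reward (may be 0 for omission).
#' @param V_sprime Value of the successor state.
#' @return Response amplitude \eqn{\Delta d}, spikes/s.
#' @examples
#' # a two-fold positive surprise
#' reward_response_after_adaptation(circuit_preset("mouse"), 0.5, 0, 1)
#' @export
reward_response_after_adaptation <- function(params, V_s, r, V_sprime) {
  stopifnot(inherits(params, "circuit_params"))
  if (!is.numeric(V_s) || any(V_s <= 0))
    stop("`V_s` must be positive")
  if (any(r + V_sprime <= 0))
    stop("`r + V_sprime` must be positive")
  params$mu * (log(r + V_sprime) - log(V_s))
}
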