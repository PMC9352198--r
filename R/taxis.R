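#' Agent parameters for the run-and-tumble simulator
#'
#' The agent moves in straight runs at speed \eqn{v} and reorients
#' ("tumbles") as a Poisson process with mean run duration \eqn{\tau}.
#' Dopamine closes the loop: with `modulation = "speed"` the speed is
#' \eqn{v = v_0 (d/d_0)^{h}} (clipped at zero), with `modulation = "tumble"`
#' the speed is fixed at \eqn{v_0} and the tumble rate is
#' \eqn{\tau^{-1} d_0 / d} (longer runs at high dopamine). Both variants
#' climb gradients of \eqn{\log R} and yield the same matching exponent.
#'
#' @param v0 Baseline speed at \eqn{d = d_0}, cm/s.
#' @param tau Mean run duration, s.
#' @param m Spatial dimension, 1, 2 or 3.
#' @param modulation `"speed"` (default) or `"tumble"`.
#' @param h_speed Speed-gain exponent \eqn{h} in \eqn{v \propto d^h};
#'   default 1 (proportional control).
#' @param turn_corr Correlation of the post-tumble heading with the
#'   previous heading, in `[0, 1)`; 0 (default) is a fresh uniform heading.
#' @return An `agent_params` object.
#' @export
agent_params <- function(v0 = 10, tau = 0.1, m = 1,
                         modulation = c("speed", "tumble"),
                         h_speed = 1, turn_corr = 0) {
  modulation <- match.arg(modulation)
  if (v0 <= 0) stop("`v0` must be positive")
  if (tau <= 0) stop("`tau` must be positive")
  if (!m %in% 1:3) stop("`m` must be 1, 2 or 3")
  if (h_speed <= 0) stop("`h_speed` must be positive")
  if (turn_corr < 0 || turn_corr >= 1) stop("`turn_corr` must be in [0, 1)")
  structure(list(v0 = v0, tau = tau, m = as.integer(m),
                 modulation = modulation, h_speed = h_speed,
                 turn_corr = turn_corr),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("run-and-tumble agent: v0 = %g cm/s, tau = %g s, m = %d, %s-modulated\n",
              x$v0, x$tau, x$m, x$modulation))
  invisible(x)
}

default_box <- function(field) {
  # bounded box with reflecting walls, sized well beyond the field features
  if (identical(field$kind, "gauss2")) {
    m <- field$m
    c1 <- field$pars[5:(4 + m)]; c2 <- field$pars[(5 + m):(4 + 2 * m)]
    b <- max(field$pars[3:4])
    half <- max(abs(c(c1, c2))) + max(1.5 * sqrt(sum((c1 - c2)^2)), 6 * b)
    list(lo = rep(-half, m), hi = rep(half, m))
  } else {
    NULL
  }
}

#' Simulate reward-taxis: run-and-tumble navigation driven by the circuit
#'
#' At every time step the dopamine circuit is driven by \eqn{R(x(t))} at
#' the agent's position (the circuit state is carried continuously, not
#' reset at tumbles) and the current dopamine level sets the speed or the
#' tumble rate. Because dopamine tracks the temporal logarithmic derivative
#' of its input, runs up the gradient of \eqn{\log R} are extended and runs
#' down it are curtailed, producing chemotaxis-like drift toward reward
#' peaks.
#'
#' @param agent An [agent_params()] object.
#' @param circuit A [circuit_params()] object (feedback variant dynamics
#'   are used along the trajectory).
#' @param field A parametric [reward_field()] (uniform, Gaussian mixture,
#'   or exponential decay).
#' @param T Duration, s.
#' @param dt Time step, s; must be much smaller than `tau`.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param x_init Initial position (defaults to the origin).
#' @param box Either `NULL` for the default reflecting box (for Gaussian
#'   fields, a box centred on the peaks and several peak separations wide;
#'   unbounded otherwise), `"none"` for unbounded motion, or a list with
#'   `lo`, `hi` vectors.
#' @param record_dt Spacing of recorded trajectory samples, s (the
#'   dynamics always advance at `dt`; recording is thinned to keep
#'   trajectories light).
#' @param centers Optional matrix (or vector in 1D) of window centers at
#'   which residence time is accumulated at full resolution.
#' @param window Half-width of the residence windows, cm.
#' @param burn_in Fraction of the path excluded from the occupancy
#'   accumulators before statistics are collected (default 0; the matching
#'   harness discards the first 20\% as equilibration).
#' @return A `taxis_trajectory`: list with `times`, `positions`, `d`, `g`,
#'   `speed`, `tumbled`, `occupancy` (seconds per center), `n_tumbles`,
#'   and the parameters used.
#' @examples
#' fld <- make_gaussian_field(4, 1)
#' tr <- simulate_taxis(agent_params(), circuit_params(mu = 4), fld,
#'                      T = 50, dt = 0.005, seed = 1)
#' @export
simulate_taxis <- function(agent, circuit, field, T, dt = 0.005, seed = NULL,
                           x_init = NULL, box = NULL, record_dt = 10 * dt,
                           centers = NULL, window = 2.5, burn_in = 0) {
  stopifnot(inherits(agent, "agent_params"),
            inherits(circuit, "circuit_params"),
            inherits(field, "reward_field"))
  if (agent$m != field$m) stop("agent and field dimensions differ")
  if (dt >= agent$tau) stop("`dt` must be smaller than the run duration `tau`")
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

  if (!circuit$variant %in% c("feedback", "quasi_static"))
    stop("the taxis loop supports the feedback and quasi_static variants")
  raw <- .run_taxis_cpp(desc,
                        c(circuit$omega_d, circuit$omega, circuit$C,
                          circuit$mu, circuit$alpha, circuit$d0,
                          if (circuit$variant == "quasi_static") 1 else 0),
                        c(agent$v0, agent$tau,
                          if (agent$modulation == "speed") 0 else 1,
                          agent$h_speed, agent$turn_corr),
                        as.numeric(x_init), T, dt, box_lo, box_hi,
                        rec_every, cmat, window, burn_in)
  structure(c(raw, list(agent = agent, circuit = circuit, field = field,
                        dt = dt, T = T, centers = cmat, window = window)),
            class = "taxis_trajectory")
}

#' @export
print.taxis_trajectory <- function(x, ...) {
  cat(sprintf("reward-taxis trajectory: T = %g s (dt = %g s), %d recorded samples, %d tumbles\n",
              x$T, x$dt, length(x$times), as.integer(x$n_tumbles)))
  invisible(x)
}

#' Residence time of a trajectory near given centers
#'
#' Total time the trajectory spends within an L-infinity window of each
#' center, estimated from the recorded samples (each sample stands for one
#' recording interval). For full-resolution occupancy, pass `centers` to
#' [simulate_taxis()]/[simulate_langevin()] instead, which accumulate at
#' every dynamics step.
#'
#' @param traj A `taxis_trajectory` or `langevin_trajectory`, or any list
#'   with `times` and `positions`.
#' @param centers Window centers (vector in 1D or matrix).
#' @param window Half-width, cm.
#' @return Numeric vector of occupancy times, s, one per center.
#' @export
residence_times <- function(traj, centers, window = 2.5) {
  if (window <= 0) stop("`window` must be positive")
  pos <- traj$positions
  if (is.null(pos) || NROW(pos) == 0L) stop("empty trajectory")
  pos <- if (is.matrix(pos)) pos else matrix(pos, ncol = 1L)
  m <- ncol(pos)
  cmat <- as_points(centers, m)
  dt_samp <- if (length(traj$times) > 1L) diff(traj$times[1:2]) else 1
  vapply(seq_len(nrow(cmat)), function(i) {
    inside <- rep(TRUE, nrow(pos))
    for (j in seq_len(m))
      inside <- inside & abs(pos[, j] - cmat[i, j]) <= window
    sum(inside) * dt_samp
  }, numeric(1))
}

#' Mechanistic diffusion and drift coefficients
#'
#' Coarse-graining the run-and-tumble agent over many runs gives Brownian
#' motion with \eqn{D \approx m^{-1} v_0^2 \tau} plus a drift
#' \eqn{\chi \nabla \log R} with \eqn{\chi \approx D\, h\, \mu / d_0}
#' (valid for runs short compared with the circuit's adaptation time).
#' The matching exponent is \eqn{\beta = \chi/D = h\mu/d_0}, independent of
#' \eqn{v_0} and \eqn{\tau}.
#'
#' @param agent An [agent_params()] object.
#' @param circuit A [circuit_params()] object.
#' @return A [langevin_params()] object.
#' @examples
#' coefficients_from_mechanism(agent_params(v0 = 10, tau = 0.1),
#'                             circuit_params(mu = 4, d0 = 5))
#' @export
coefficients_from_mechanism <- function(agent, circuit) {
  stopifnot(inherits(agent, "agent_params"),
            inherits(circuit, "circuit_params"))
  D <- agent$v0^2 * agent$tau / agent$m
  chi <- D * agent$h_speed * circuit$mu / circuit$d0
  langevin_params(D = D, chi = chi, m = agent$m)
}
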