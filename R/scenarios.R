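#' Drive the circuit with a prescribed movement trajectory in a field
#'
#' Converts a deterministic position trajectory \eqn{x(t)} through a
#' spatial field into the temporal input \eqn{R(t) = R(x(t))} and simulates
#' the circuit. Used for derivative-readout scenarios: dopamine tracks the
#' temporal logarithmic derivative of the input, so faster approach, a
#' pause, or a teleport toward the target each leave characteristic
#' signatures.
#'
#' @param params A [circuit_params()] object.
#' @param field A [reward_field()] (1D).
#' @param x_of_t Function of time returning position, or a data frame with
#'   columns `t`, `x` (linearly interpolated).
#' @param t_grid Output time grid, s.
#' @param breaks Times at which the trajectory (hence the input) is
#'   discontinuous, e.g. teleports.
#' @param ... Passed to [simulate_circuit()].
#' @return A `circuit_trace` with an extra `x` column.
#' @export
simulate_position_drive <- function(params, field, x_of_t, t_grid,
                                    breaks = numeric(0), ...) {
  stopifnot(inherits(field, "reward_field"), field$m == 1L)
  fx <- if (is.function(x_of_t)) x_of_t else {
    stopifnot(is.data.frame(x_of_t))
    function(t) approx(x_of_t$t, x_of_t$x, xout = t, rule = 2)$y
  }
  sig <- reward_signal(function(t) eval_field(field, fx(t)),
                       breaks = breaks, desc = "R(x(t)) along trajectory")
  tr <- simulate_circuit(params, sig, t_grid, ...)
  tr$x <- fx(t_grid)
  tr
}

#' Movement-perturbation scenarios on an exponential-decay field
#'
#' Canned approach trajectories toward a target at the origin of the field
#' \eqn{R(x) = e^{-\gamma x^h}}: a constant-speed approach
#' (`"baseline"`), a doubled-speed approach (`"fast"`), an approach with a
#' mid-course pause (`"pause"`), and an instantaneous teleport half-way
#' (`"teleport"`). Dopamine output is derivative-like: it scales with
#' approach speed, collapses to baseline during the pause, and spikes at
#' the teleport.
#'
#' @param type Scenario name.
#' @param params A [circuit_params()] object.
#' @param field An exponential-decay [reward_field()]
#'   (default [make_expdecay_field()]).
#' @param x0 Starting distance. Default 1.
#' @param v0 Approach speed. Default 1.
#' @param t_end,dt Time grid.
#' @return A `circuit_trace` with `x` column (see
#'   [simulate_position_drive()]).
#' @export
s1_perturbation_scenario <- function(type = c("baseline", "fast", "pause",
                                              "teleport"),
                                     params = circuit_preset("mouse"),
                                     field = make_expdecay_field(),
                                     x0 = 1, v0 = 1, t_end = NULL,
                                     dt = 1e-3) {
  type <- match.arg(type)
  t_arrive <- x0 / v0
  if (is.null(t_end)) t_end <- 2 * t_arrive
  brk <- numeric(0)
  fx <- switch(type,
    baseline = function(t) pmax(0, x0 - v0 * t),
    fast = function(t) pmax(0, x0 - 2 * v0 * t),
    pause = {
      # pause of one half arrival-time starting half-way in
      t1 <- t_arrive / 2; t2 <- t1 + t_arrive / 2
      function(t) {
        tt <- ifelse(t < t1, t, ifelse(t < t2, t1, t - (t2 - t1)))
        pmax(0, x0 - v0 * tt)
      }
    },
    teleport = {
      t1 <- t_arrive / 4
      brk <- t1
      function(t) pmax(0, x0 - v0 * t - (x0 / 2) * (t >= t1))
    })
  simulate_position_drive(params, field, fx, seq(0, t_end, by = dt),
                          breaks = brk)
}

#' Responses under an alternating X +/- Y schedule
#'
#' Simulates the circuit for each trial of a [make_shifted_pair_schedule()]
#' and reports the delivery-response amplitude per trial. At fixed spread
#' `Y`, raising the common level `X` shrinks the fold change
#' \eqn{(X+Y)/X} and hence the response: a scale-invariance signature that
#' distinguishes fold-change detection from variance normalisation.
#'
#' @param params A [circuit_params()] object.
#' @param X,Y Mean and spread of the two magnitudes.
#' @param n_trials Number of trials simulated.
#' @param t_cue,t_rew,t_end,dt Trial timing, s.
#' @param ... Passed to [make_shifted_pair_schedule()].
#' @return Data frame with `magnitude` and `delivery_response` per trial.
#' @export
shifted_pair_responses <- function(params, X, Y, n_trials = 2,
                                   t_cue = 1, t_rew = 6, t_end = 11,
                                   dt = 1e-3, ...) {
  sch <- make_shifted_pair_schedule(X, Y, n_trials = n_trials,
                                    t_cue = t_cue, t_rew = t_rew, ...)
  grid <- seq(0, t_end, by = dt)
  rows <- lapply(seq_along(sch$signals), function(i) {
    tr <- simulate_circuit(params, sch$signals[[i]], grid)
    data.frame(magnitude = sch$magnitudes[i],
               delivery_response = response_amplitude(tr, c(t_rew, t_end)))
  })
  do.call(rbind, rows)
}
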