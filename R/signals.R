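#' Expected-reward signals R(t)
#'
#' A `reward_signal` wraps a positive-valued evaluator of time together with
#' its list of discontinuity times, so the circuit integrator can restart
#' exactly at steps. Construct with [make_step()], [make_cue_reward()],
#' [reward_signal()] or coerce a plain function with [as_reward_signal()].
#'
#' @param f Function of time returning expected reward (vectorised).
#' @param breaks Numeric vector of discontinuity times (may be empty).
#' @param desc Optional short description.
#' @return A `reward_signal` object.
#' @export
reward_signal <- function(f, breaks = numeric(0), desc = "custom") {
  stopifnot(is.function(f), is.numeric(breaks))
  structure(list(f = f, breaks = sort(unique(breaks)), desc = desc),
            class = "reward_signal")
}

#' @rdname reward_signal
#' @param x Object to coerce.
#' @export
as_reward_signal <- function(x) {
  if (inherits(x, "reward_signal")) return(x)
  if (is.function(x)) return(reward_signal(x))
  stop("cannot coerce to reward_signal")
}

#' Evaluate a reward signal
#' @param sig A `reward_signal`.
#' @param t Times, s.
#' @return Expected reward at `t`.
#' @export
eval_signal <- function(sig, t) {
  sig <- as_reward_signal(sig)
  sig$f(t)
}

signal_breaks <- function(sig) as_reward_signal(sig)$breaks

#' @export
print.reward_signal <- function(x, ...) {
  cat("reward_signal:", x$desc, "\n")
  if (length(x$breaks))
    cat("  discontinuities at t =", paste(signif(x$breaks, 6), collapse = ", "),
        "\n")
  invisible(x)
}

#' Step input in expected reward
#'
#' \eqn{R(t) = R_0 + \lambda\,\theta(t - t_0)} with \eqn{\theta} the unit
#' step. A negative \eqn{\lambda} models reward omission (e.g.
#' \eqn{R_0 = 7}, \eqn{\lambda = -6}).
#'
#' @param R0 Pre-step level, positive.
#' @param lam Step height; `R0 + lam` must stay positive.
#' @param t0 Step time, s.
#' @return A [reward_signal()].
#' @examples
#' s <- make_step(R0 = 1, lam = 7, t0 = 1)
#' eval_signal(s, c(0.5, 1.5)) # 1, 8
#' @export
make_step <- function(R0, lam, t0 = 0) {
  stopifnot(is.numeric(R0), is.numeric(lam), is.numeric(t0))
  if (R0 <= 0) stop("`R0` must be positive")
  if (R0 + lam <= 0) stop("post-step level `R0 + lam` must be positive")
  reward_signal(function(t) R0 + lam * (t >= t0), breaks = t0,
                desc = sprintf("step %g -> %g at t=%g", R0, R0 + lam, t0))
}

#' Cue-then-reward expected-reward schedule
#'
#' The expected reward following a cue that predicts delivery of a reward of
#' magnitude `u` with probability `p` is \eqn{R = p\,(b + \lambda u)}; upon
#' delivery it rises to \eqn{b + \lambda u} (a \eqn{1/p}-fold change,
#' independent of `u` -- the engine of scale-invariant delivery responses).
#' On omission the input drops back to the pre-cue baseline.
#'
#' @param u Reward magnitude (e.g. ml).
#' @param p Delivery probability, in (0, 1].
#' @param b Magnitude-independent component of the reward activation.
#' @param lam Magnitude scaling (e.g. 1/ml).
#' @param R_pre Pre-cue baseline expected reward, positive.
#' @param t_cue,t_rew Cue and scheduled delivery times, s.
#' @param delivered Logical; if `FALSE` the delivery step is an omission
#'   (drop back to `R_pre`).
#' @return A [reward_signal()] with attributes `cue_level` and
#'   `delivery_level`.
#' @examples
#' s <- make_cue_reward(u = 0.05, p = 0.5, b = 2, lam = 10)
#' attr(s, "cue_level")      # 0.5 * 2.5 = 1.25
#' attr(s, "delivery_level") # 2.5
#' @export
make_cue_reward <- function(u, p = 0.5, b = 2, lam = 10, R_pre = 1,
                            t_cue = 1, t_rew = 2, delivered = TRUE) {
  if (!is.numeric(p) || p <= 0 || p > 1) stop("`p` must be in (0, 1]")
  if (R_pre <= 0) stop("`R_pre` must be positive")
  if (t_rew <= t_cue) stop("`t_rew` must follow `t_cue`")
  full <- b + lam * u
  cue <- p * full
  if (cue <= 0 || full <= 0) stop("schedule yields non-positive R(t)")
  post <- if (delivered) full else R_pre
  f <- function(t) {
    ifelse(t < t_cue, R_pre, ifelse(t < t_rew, cue, post))
  }
  out <- reward_signal(f, breaks = c(t_cue, t_rew),
                       desc = sprintf("cue-reward u=%g p=%g (%s)", u, p,
                                      if (delivered) "delivered" else "omitted"))
  attr(out, "cue_level") <- cue
  attr(out, "delivery_level") <- post
  attr(out, "u") <- u
  out
}

#' Expected reward of a delayed probabilistic reward
#'
#' For a reward of magnitude `y` delivered with probability `p` after
#' `dt_steps` discount steps, the cue-time expected reward is
#' \eqn{R(0) \approx p\,\gamma^{\Delta t} y}; the delivery-time to cue-time
#' ratio \eqn{R(\Delta t)/R(0) = 1/(p\,\gamma^{\Delta t})} is independent of
#' the magnitude.
#'
#' @param y Reward magnitude, positive.
#' @param p Delivery probability, in (0, 1].
#' @param gamma_disc Discount factor per step, in (0, 1).
#' @param dt_steps Delay, in discount steps.
#' @return `expected_reward_at_delay()`: \eqn{p\gamma^{\Delta t} y};
#'   `delivery_fold_change()`: the magnitude-independent ratio
#'   \eqn{1/(p\gamma^{\Delta t})}.
#' @export
expected_reward_at_delay <- function(y, p, gamma_disc, dt_steps) {
  stopifnot(y > 0, p > 0, p <= 1, gamma_disc > 0, gamma_disc < 1)
  p * gamma_disc^dt_steps * y
}

#' @rdname expected_reward_at_delay
#' @export
delivery_fold_change <- function(p, gamma_disc = 1 - 1e-12, dt_steps = 1) {
  stopifnot(p > 0, p <= 1, gamma_disc > 0, gamma_disc <= 1)
  1 / (p * gamma_disc^dt_steps)
}

#' Alternating X +/- Y reward schedule
#'
#' A cue predicts that some reward will be delivered; the delivered
#' magnitude alternates (or is drawn at random) between \eqn{r_1 = X + Y}
#' and \eqn{r_2 = X - Y}. Because the circuit detects fold changes, the
#' response to the larger reward shrinks as the common level `X` grows at
#' fixed spread `Y` -- e.g. the response to magnitude 1.5 under
#' \eqn{X = 1} exceeds the response to magnitude 11.5 under \eqn{X = 11}.
#'
#' @param X Mean reward magnitude; must exceed `Y`.
#' @param Y Spread, positive.
#' @param n_trials Number of trials.
#' @param p_alt If `NULL` (default) the magnitudes strictly alternate;
#'   otherwise each trial is \eqn{r_1} independently with this probability.
#' @param R_pre,t_cue,t_rew Passed to [make_cue_reward()]-style timing: the
#'   expected reward steps from `R_pre` to `X` at the cue (the cue predicts
#'   the mean magnitude) and to the drawn magnitude at delivery.
#' @param seed Optional seed for the random order.
#' @return A list with `magnitudes` (numeric vector) and `signals` (list of
#'   [reward_signal()]s, one per trial).
#' @export
make_shifted_pair_schedule <- function(X, Y, n_trials = 10, p_alt = NULL,
                                       R_pre = 1, t_cue = 1, t_rew = 2,
                                       seed = NULL) {
  if (!(X > Y && Y > 0)) stop("need X > Y > 0")
  r1 <- X + Y; r2 <- X - Y
  if (is.null(p_alt)) {
    mags <- rep(c(r1, r2), length.out = n_trials)
  } else {
    stopifnot(p_alt > 0, p_alt < 1)
    if (!is.null(seed)) set.seed(seed)
    mags <- ifelse(runif(n_trials) < p_alt, r1, r2)
  }
  signals <- lapply(mags, function(m) {
    f <- function(t) ifelse(t < t_cue, R_pre, ifelse(t < t_rew, X, m))
    s <- reward_signal(f, breaks = c(t_cue, t_rew),
                       desc = sprintf("X+/-Y trial, magnitude %g", m))
    attr(s, "magnitude") <- m
    s
  })
  list(magnitudes = mags, signals = signals, r1 = r1, r2 = r2)
}

#' Simulate circuit responses across a cue-reward protocol
#'
#' Convenience harness for scale-invariance protocols: for each reward
#' magnitude, build the cue-reward schedule, simulate the circuit from an
#' adapted start, and report the cue-window and delivery-window peak
#' response amplitudes.
#'
#' @param params A [circuit_params()] object.
#' @param u Vector of reward magnitudes.
#' @param p,b,lam,R_pre,t_cue,t_rew As in [make_cue_reward()].
#' @param t_end,dt Simulation horizon and output step, s.
#' @param delivered Logical (recycled over `u`).
#' @return Data frame with columns `u`, `cue_response`, `delivery_response`.
#' @export
cue_reward_responses <- function(params, u, p = 0.5, b = 2, lam = 10,
                                 R_pre = 1, t_cue = 1, t_rew = 6,
                                 t_end = 11, dt = 1e-3, delivered = TRUE) {
  delivered <- rep_len(delivered, length(u))
  grid <- seq(0, t_end, by = dt)
  res <- lapply(seq_along(u), function(i) {
    sig <- make_cue_reward(u[i], p = p, b = b, lam = lam, R_pre = R_pre,
                           t_cue = t_cue, t_rew = t_rew,
                           delivered = delivered[i])
    tr <- simulate_circuit(params, sig, grid)
    data.frame(u = u[i],
               cue_response = response_amplitude(tr, c(t_cue, t_rew)),
               delivery_response = response_amplitude(tr, c(t_rew, t_end)))
  })
  do.call(rbind, res)
}
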