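#' Parameters for tabular temporal-difference learning
#'
#' Configures the linear chain task: the agent passes through states
#' \eqn{S_1, \ldots, S_N}; at the final state a reward is drawn from a
#' fixed-mean distribution and the episode ends. A logarithmic value
#' function \eqn{\log V(s)} is learned with the modified TD rule (see
#' [log_td_update()]); the classic rule is available for equivalence
#' checks.
#'
#' @param gamma_disc Discount factor per step, in (0, 1). Default 0.9.
#' @param alpha_lr Learning rate, in (0, 1). (This is the learning rate of
#'   the TD rule, unrelated to the circuit's inhibition strength.)
#' @param N Number of chain states, at least 2.
#' @param episodes Number of episodes.
#' @param reward_model `"deterministic"`, `"normal_cv"` (normal with fixed
#'   coefficient of variation), or `"bernoulli"` (reward `magnitude/p_bern`
#'   with probability `p_bern`, else 0 -- mean `magnitude`).
#' @param magnitude Mean reward magnitude, positive.
#' @param cv Coefficient of variation for `"normal_cv"` (default 0.3).
#' @param p_bern Success probability for `"bernoulli"` (default 0.5).
#' @return A `td_params` object.
#' @export
td_params <- function(gamma_disc = 0.9, alpha_lr = 0.02, N = 5,
                      episodes = 5000,
                      reward_model = c("deterministic", "normal_cv",
                                       "bernoulli"),
                      magnitude = 50, cv = 0.3, p_bern = 0.5) {
  reward_model <- match.arg(reward_model)
  if (gamma_disc <= 0 || gamma_disc >= 1) stop("`gamma_disc` must be in (0, 1)")
  if (alpha_lr <= 0 || alpha_lr >= 1) stop("`alpha_lr` must be in (0, 1)")
  if (N < 2) stop("`N` must be at least 2")
  if (magnitude <= 0) stop("`magnitude` must be positive")
  if (p_bern <= 0 || p_bern > 1) stop("`p_bern` must be in (0, 1]")
  structure(list(gamma_disc = gamma_disc, alpha_lr = alpha_lr,
                 N = as.integer(N), episodes = as.integer(episodes),
                 reward_model = reward_model, magnitude = magnitude,
                 cv = cv, p_bern = p_bern),
            class = "td_params")
}

#' Log-domain temporal-difference update
#'
#' Updates the logarithmic value estimate of state `s` with the modified
#' rule \deqn{\log V(s) \leftarrow \log V(s) +
#'   \alpha\,(e^{\delta_{\log}} - 1),}
#' where \eqn{\delta_{\log} = \log(r + \gamma V(s')) - \log V(s)} is the
#' logarithmic prediction error. The update is computed in the ratio form
#' \eqn{\alpha\,((r + \gamma V(s'))/V(s) - 1)}, which is identical and
#' stays defined when \eqn{r + \gamma V(s') = 0} (e.g. an unrewarded
#' Bernoulli trial at the terminal transition, where
#' \eqn{e^{\delta_{\log}} = 0}). To first order in \eqn{\delta_{\log}} the
#' rule is \eqn{\alpha\,\delta_{\log}}, the classic TD rule on the log
#' scale.
#'
#' @param table Numeric vector of \eqn{\log V} estimates, named or indexed
#'   by state.
#' @param s Index of the updated state.
#' @param s_prime Index of the successor, or `NA` for the terminal state
#'   (\eqn{V(\mathrm{terminal}) = 0}).
#' @param r Reward received on the transition.
#' @param params A [td_params()] object.
#' @return The updated table.
#' @export
log_td_update <- function(table, s, s_prime, r, params) {
  stopifnot(inherits(params, "td_params"))
  V_target <- r + params$gamma_disc *
    (if (is.na(s_prime)) 0 else exp(table[[s_prime]]))
  if (V_target < 0) stop("r + gamma * V(s') must be non-negative")
  table[[s]] <- table[[s]] +
    params$alpha_lr * (V_target / exp(table[[s]]) - 1)
  table
}

#' Classic temporal-difference update
#'
#' \eqn{V(s) \leftarrow V(s) + \alpha\,(r + \gamma V(s') - V(s))}.
#'
#' @param table Numeric vector of \eqn{V} estimates.
#' @param s,s_prime State and successor indices (`NA` successor =
#'   terminal, value 0).
#' @param r Reward.
#' @param params A [td_params()] object.
#' @return The updated table.
#' @export
classic_td_update <- function(table, s, s_prime, r, params) {
  stopifnot(inherits(params, "td_params"))
  V_next <- if (is.na(s_prime)) 0 else table[[s_prime]]
  table[[s]] <- table[[s]] +
    params$alpha_lr * (r + params$gamma_disc * V_next - table[[s]])
  table
}

draw_reward <- function(params) {
  switch(params$reward_model,
    deterministic = params$magnitude,
    normal_cv = max(0, rnorm(1, params$magnitude,
                             params$cv * params$magnitude)),
    bernoulli = if (runif(1) < params$p_bern)
      params$magnitude / params$p_bern else 0)
}

#' Run the chain learning experiment
#'
#' Repeats episodes through the \eqn{N}-state chain, applying
#' [log_td_update()] at every transition (reward only on the terminal
#' transition from \eqn{S_N}). Returns the learning curve of
#' \eqn{\log V(S_1)} together with the analytic target
#' \eqn{\log(\gamma^{N-1} E[r])}, the discounted value of the start state.
#' Multiplying all rewards by \eqn{\lambda} shifts every converged
#' \eqn{\log V} by exactly \eqn{\log \lambda} -- the learning-side face of
#' fold-change detection.
#'
#' @param params A [td_params()] object.
#' @param seed Integer seed (used by the stochastic reward models).
#' @param logV_init Initial \eqn{\log V} for every state (default 0,
#'   i.e. \eqn{V = 1}).
#' @param rule `"log"` (default) or `"classic"` (then the curve reports
#'   \eqn{\log} of the classic-TD \eqn{V(S_1)}).
#' @return A `td_chain_result` list: `logV_S1` (per-episode curve),
#'   `logV_final` (final table), `target` (analytic \eqn{\log V(S_1)}),
#'   `converged_value` (mean of the last 10% of the curve), and `params`.
#' @examples
#' res <- run_chain_experiment(td_params(magnitude = 50), seed = 1)
#' res$converged_value - res$target # ~0
#' @export
run_chain_experiment <- function(params, seed = NULL, logV_init = 0,
                                 rule = c("log", "classic")) {
  stopifnot(inherits(params, "td_params"))
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  curve <- numeric(params$episodes)
  if (rule == "log") {
    tab <- rep(logV_init, N)
    for (ep in seq_len(params$episodes)) {
      for (s in seq_len(N - 1L))
        tab <- log_td_update(tab, s, s + 1L, r = 0, params)
      tab <- log_td_update(tab, N, NA, r = draw_reward(params), params)
      curve[ep] <- tab[1L]
    }
    final <- tab
  } else {
    tab <- rep(exp(logV_init), N)
    for (ep in seq_len(params$episodes)) {
      for (s in seq_len(N - 1L))
        tab <- classic_td_update(tab, s, s + 1L, r = 0, params)
      tab <- classic_td_update(tab, N, NA, r = draw_reward(params), params)
      curve[ep] <- log(tab[1L])
    }
    final <- log(tab)
  }
  target <- log(params$gamma_disc^(N - 1L) * params$magnitude)
  tail_n <- max(1L, floor(0.1 * params$episodes))
  structure(list(logV_S1 = curve, logV_final = final, target = target,
                 converged_value = mean(curve[seq.int(params$episodes -
                                                        tail_n + 1L,
                                                      params$episodes)]),
                 rule = rule, params = params),
            class = "td_chain_result")
}

#' @export
print.td_chain_result <- function(x, ...) {
  cat(sprintf("chain TD learning (%s rule): logV(S1) converged to %.4f (analytic target %.4f)\n",
              x$rule, x$converged_value, x$target))
  invisible(x)
}
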