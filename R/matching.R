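#' Default circuit for the two-option matching experiment
#'
#' The mapping of the mechanistic agent onto the coarse-grained Langevin
#' dynamics -- and with it the prediction \eqn{\beta = \mu/d_0}, which
#' depends on no other circuit parameter -- holds when dopamine relaxation
#' is fast compared with runs and adaptation is slow compared with runs.
#' This constructor places the circuit in that regime once and for all:
#' the quasi-static dopamine limit (the same elimination used in the
#' model's own analysis) with the adaptation rate
#' \eqn{\omega\alpha/d_0 = 1} /s, ten-fold slower than the default run
#' rate \eqn{1/\tau = 10} /s. The two-option gain is \eqn{\mu = 4},
#' \eqn{d_0 = 5} (\eqn{\beta = 0.8}). Outside this regime -- e.g. with the
#' faster measured adaptation rates -- the emergent sensitivity falls
#' below \eqn{\mu/d_0} roughly as \eqn{1/(1 + \omega\alpha\tau/d_0)}, the
#' finite-run-time correction.
#'
#' @param mu,d0 Gain and baseline, spikes/s.
#' @param tau Run duration the regime is scaled to, s.
#' @param sep Timescale separation factor (default 10).
#' @return A `circuit_params` object (quasi-static variant).
#' @export
matching_default_circuit <- function(mu = 4, d0 = 5, tau = 0.1, sep = 10) {
  k_adapt <- 1 / (sep * tau) # adaptation rate, 1/s
  circuit_params(omega = k_adapt * d0 / 0.7, mu = mu, d0 = d0,
                 variant = "quasi_static")
}

#' Specification of a matching-law experiment
#'
#' The two-option operant setting on a double-Gaussian expected-reward
#' field: for each reward ratio \eqn{R_1/R_2} the agent is simulated for
#' `T` seconds (several replicates), and the response ratio is the ratio of
#' time spent within `window` cm of each peak.
#'
#' @param ratios Reward ratios \eqn{R_1/R_2} to sweep; at least 3 for the
#'   regression.
#' @param n_rep Replicates per ratio.
#' @param T Duration per replicate, s.
#' @param x1,x2 Peak centers, cm.
#' @param b Peak width, cm.
#' @param window Residence half-window, cm (the conventional 2.5 cm).
#' @param bias Multiplicative preference bias applied to \eqn{R_1}
#'   (default 1); a bias shifts the fitted \eqn{\hat k}, not
#'   \eqn{\hat\beta}.
#' @param dt Simulation step, s.
#' @return A `matching_spec` object.
#' @export
matching_spec <- function(ratios = c(1/8, 1/4, 1/2, 1, 2, 4, 8),
                          n_rep = 10, T = 20000, x1 = 30, x2 = -30,
                          b = 10, window = 2.5, bias = 1, dt = NULL) {
  if (any(ratios <= 0)) stop("`ratios` must be positive")
  if (length(ratios) < 3L) stop("need at least 3 ratios for the regression")
  if (n_rep < 1L) stop("`n_rep` must be at least 1")
  if (bias <= 0) stop("`bias` must be positive")
  structure(list(ratios = sort(ratios), n_rep = as.integer(n_rep), T = T,
                 x1 = x1, x2 = x2, b = b, window = window, bias = bias,
                 dt = dt),
            class = "matching_spec")
}

#' Fit the generalized matching law to response ratios
#'
#' Ordinary least squares of \eqn{\log(P_1/P_2)} on \eqn{\log(R_1/R_2)}:
#' \deqn{P(x_1)/P(x_2) = k\,(R_1/R_2)^\beta .}
#' The slope is the sensitivity \eqn{\hat\beta} (1 = perfect matching,
#' <1 undermatching) and the intercept is \eqn{\log \hat k} (bias).
#'
#' @param ratios Reward ratios \eqn{R_1/R_2}, positive.
#' @param occupancies Response (residence-time) ratios \eqn{P_1/P_2},
#'   positive, same length.
#' @param weights Optional regression weights.
#' @return A `matching_result` list: `beta_hat`, `k_hat`, `stderr_beta`,
#'   `ci_beta` (95%), `log_k_hat`, `stderr_log_k`, `fit` (the `lm`), and
#'   the per-point table.
#' @examples
#' r <- c(1/4, 1/2, 1, 2, 4)
#' fit_matching_law(r, 2 * r^0.8) # beta_hat = 0.8, k_hat = 2
#' @export
fit_matching_law <- function(ratios, occupancies, weights = NULL) {
  if (length(ratios) != length(occupancies))
    stop("`ratios` and `occupancies` must have the same length")
  if (any(!is.finite(ratios)) || any(ratios <= 0) ||
      any(!is.finite(occupancies)) || any(occupancies <= 0))
    stop("ratios and occupancies must be positive and finite")
  if (length(ratios) < 3L) stop("need at least 3 pairs")
  df <- data.frame(lr = log(ratios), lo = log(occupancies))
  fit <- if (is.null(weights)) lm(lo ~ lr, data = df) else
    lm(lo ~ lr, data = df, weights = weights)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  structure(list(beta_hat = unname(cf[2L]),
                 k_hat = unname(exp(cf[1L])),
                 log_k_hat = unname(cf[1L]),
                 stderr_beta = unname(se[2L]),
                 stderr_log_k = unname(se[1L]),
                 ci_beta = unname(cf[2L] + c(-1, 1) * tcrit * se[2L]),
                 table = data.frame(ratio = ratios, occupancy = occupancies),
                 fit = fit),
            class = "matching_result")
}

#' @export
print.matching_result <- function(x, ...) {
  cat(sprintf("generalized matching law fit: beta_hat = %.4f (SE %.4f, 95%% CI [%.4f, %.4f]), k_hat = %.4f\n",
              x$beta_hat, x$stderr_beta, x$ci_beta[1], x$ci_beta[2],
              x$k_hat))
  invisible(x)
}

#' Run a full matching-law experiment
#'
#' Sweeps the reward ratios of a [matching_spec()], simulating either the
#' mechanistic run-and-tumble agent (`engine = "taxis"`) or the
#' coarse-grained Langevin dynamics with coefficients derived from the same
#' agent and circuit (`engine = "langevin"`), accumulates residence times
#' in the two peak windows, and fits the matching law. Replicates with an
#' empty window are dropped with a warning (undersampled).
#'
#' @param spec A [matching_spec()].
#' @param agent An [agent_params()].
#' @param circuit A [circuit_params()]; defaults to
#'   [matching_default_circuit()], the coarse-graining regime.
#' @param engine `"taxis"` or `"langevin"`.
#' @param seed Base seed; replicate r of ratio i uses
#'   `seed + 1000L * i + r`.
#' @param langevin Optional [langevin_params()] overriding
#'   [coefficients_from_mechanism()] for the Langevin engine.
#' @param drift_mode Passed to [simulate_langevin()] (the `"gradR"` control
#'   breaks power-law matching).
#' @return A `matching_result` (see [fit_matching_law()]) with an extra
#'   `per_ratio` table of pooled occupancies.
#' @export
run_matching_experiment <- function(spec, agent = agent_params(),
                                    circuit = matching_default_circuit(),
                                    engine = c("taxis", "langevin"),
                                    seed = 1, langevin = NULL,
                                    drift_mode = "loggrad") {
  stopifnot(inherits(spec, "matching_spec"))
  engine <- match.arg(engine)
  m <- agent$m
  centers <- rbind(rep_len(spec$x1, m), rep_len(spec$x2, m))
  dt <- if (!is.null(spec$dt)) spec$dt else
    if (engine == "taxis") 0.005 else 0.01
  lp <- if (engine == "langevin") {
    if (is.null(langevin)) coefficients_from_mechanism(agent, circuit)
    else langevin
  } else NULL

  rows <- list()
  for (i in seq_along(spec$ratios)) {
    ratio <- spec$ratios[i]
    fld <- make_gaussian_field(R1 = spec$bias * ratio, R2 = 1,
                               x1 = spec$x1, x2 = spec$x2, b = spec$b,
                               m = m)
    for (r in seq_len(spec$n_rep)) {
      sd_r <- as.integer(seed + 1000L * i + r)
      # start on the side of the (unbiased) smaller peak half the time so
      # pooled occupancies are not tied to one basin
      start <- if (r %% 2L == 0L) rep_len(spec$x1, m) else rep_len(spec$x2, m)
      # first 20% of each path is equilibration, excluded from occupancy
      occ <- if (engine == "taxis") {
        simulate_taxis(agent, circuit, fld, T = spec$T, dt = dt,
                       seed = sd_r, x_init = start, centers = centers,
                       window = spec$window, burn_in = 0.2,
                       record_dt = max(1, spec$T / 2))$occupancy
      } else {
        simulate_langevin(lp, fld, T = spec$T, dt = dt, seed = sd_r,
                          x_init = start, centers = centers,
                          window = spec$window, burn_in = 0.2,
                          record_dt = max(1, spec$T / 2),
                          drift_mode = drift_mode)$occupancy
      }
      rows[[length(rows) + 1L]] <-
        data.frame(ratio = ratio, rep = r, t1 = occ[1L], t2 = occ[2L])
    }
  }
  tab <- do.call(rbind, rows)
  bad <- tab$t1 <= 0 | tab$t2 <= 0
  if (any(bad)) {
    warning(sum(bad), " replicate(s) with an empty window dropped ",
            "(undersampled)")
    tab <- tab[!bad, , drop = FALSE]
  }
  # pool replicates within each ratio: total time near peak 1 / peak 2
  per_ratio <- do.call(rbind, lapply(split(tab, tab$ratio), function(d) {
    data.frame(ratio = d$ratio[1L], t1 = sum(d$t1), t2 = sum(d$t2),
               occupancy_ratio = sum(d$t1) / sum(d$t2),
               n_rep = nrow(d))
  }))
  res <- fit_matching_law(tab$ratio, tab$t1 / tab$t2)
  res$per_ratio <- per_ratio
  res$replicates <- tab
  res$engine <- engine
  res
}
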