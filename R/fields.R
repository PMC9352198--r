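#' Spatial expected-reward fields R(x)
#'
#' A `reward_field` holds a positive evaluator of position, its log-value
#' and analytic log-gradient, and the spatial dimension. Fields built by
#' the package constructors additionally carry a parametric descriptor
#' (`kind`, `pars`) understood by the compiled run-and-tumble and Langevin
#' simulators.
#'
#' @param m Spatial dimension (1, 2 or 3).
#' @param f Evaluator: matrix of positions (rows = points, cols = dims) or
#'   numeric vector (1D) -> positive values.
#' @param grad_log Evaluator of \eqn{\nabla \log R}: positions -> matrix
#'   (rows = points) or numeric vector in 1D.
#' @param kind,pars Internal parametric descriptor for the compiled
#'   simulators (optional for fields only used from R).
#' @param desc Short description.
#' @return A `reward_field` object.
#' @export
reward_field <- function(m, f, grad_log, kind = NA_character_,
                         pars = numeric(0), desc = "custom") {
  stopifnot(m %in% 1:3, is.function(f), is.function(grad_log))
  structure(list(m = as.integer(m), f = f, grad_log = grad_log,
                 kind = kind, pars = as.numeric(pars), desc = desc),
            class = "reward_field")
}

#' @export
print.reward_field <- function(x, ...) {
  cat("reward_field (", x$m, "D): ", x$desc, "\n", sep = "")
  invisible(x)
}

as_points <- function(x, m) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == m)
    x
  } else {
    if (m == 1L) matrix(x, ncol = 1L) else matrix(x, ncol = m, byrow = TRUE)
  }
}

#' Evaluate a reward field or its log-gradient
#'
#' @param field A [reward_field()].
#' @param x Positions: numeric vector (1D) or matrix with one row per point.
#' @return `eval_field()`: positive values; `eval_grad_log()`: the
#'   log-gradient (vector in 1D, matrix otherwise).
#' @export
eval_field <- function(field, x) {
  stopifnot(inherits(field, "reward_field"))
  field$f(as_points(x, field$m))
}

#' @rdname eval_field
#' @export
eval_grad_log <- function(field, x) {
  stopifnot(inherits(field, "reward_field"))
  field$grad_log(as_points(x, field$m))
}

#' Uniform expected-reward field
#'
#' @param R0 Constant level, positive.
#' @param m Dimension.
#' @return A [reward_field()].
#' @export
make_uniform_field <- function(R0 = 1, m = 1) {
  stopifnot(R0 > 0)
  reward_field(m,
    f = function(x) rep(R0, nrow(x)),
    grad_log = function(x) matrix(0, nrow(x), ncol(x)),
    kind = "uniform", pars = R0,
    desc = sprintf("uniform R = %g", R0))
}

#' Two-peak Gaussian expected-reward field
#'
#' \deqn{R(x) = R_1 e^{-|x - x_1|^2 / (2 b_1^2)} +
#'              R_2 e^{-|x - x_2|^2 / (2 b_2^2)}}
#' The two-option operant setting: peaks of expected reward \eqn{R_1},
#' \eqn{R_2} at locations \eqn{x_1}, \eqn{x_2}. By default both peaks have
#' width `b` (`widths = "symmetric"`); `widths = "asymmetric"` doubles the
#' first peak's width (\eqn{b_1 = 2b}), a variant form used in the
#' literature. The exact shape does not matter for matching; only the peak
#' ratio does.
#'
#' @param R1,R2 Peak expected rewards, positive.
#' @param x1,x2 Peak centers, cm (scalars in 1D or length-`m` vectors).
#' @param b Width, cm, positive.
#' @param m Dimension.
#' @param widths `"symmetric"` (default) or `"asymmetric"`.
#' @return A [reward_field()].
#' @examples
#' fld <- make_gaussian_field(R1 = 4, R2 = 1, x1 = 30, x2 = -30, b = 10)
#' eval_field(fld, c(30, -30))
#' @export
make_gaussian_field <- function(R1, R2, x1 = 30, x2 = -30, b = 10, m = 1,
                                widths = c("symmetric", "asymmetric")) {
  widths <- match.arg(widths)
  stopifnot(R1 > 0, R2 > 0, b > 0)
  b1 <- if (widths == "asymmetric") 2 * b else b
  b2 <- b
  c1 <- rep_len(as.numeric(x1), m); c2 <- rep_len(as.numeric(x2), m)
  f <- function(x) {
    q1 <- rowSums((x - matrix(c1, nrow(x), m, byrow = TRUE))^2)
    q2 <- rowSums((x - matrix(c2, nrow(x), m, byrow = TRUE))^2)
    R1 * exp(-q1 / (2 * b1^2)) + R2 * exp(-q2 / (2 * b2^2))
  }
  grad_log <- function(x) {
    d1 <- x - matrix(c1, nrow(x), m, byrow = TRUE)
    d2 <- x - matrix(c2, nrow(x), m, byrow = TRUE)
    t1 <- R1 * exp(-rowSums(d1^2) / (2 * b1^2))
    t2 <- R2 * exp(-rowSums(d2^2) / (2 * b2^2))
    num <- -d1 * (t1 / b1^2) - d2 * (t2 / b2^2)
    g <- num / (t1 + t2)
    if (m == 1L) g[, 1L] else g
  }
  reward_field(m, f, grad_log, kind = "gauss2",
               pars = c(R1, R2, b1, b2, c1, c2),
               desc = sprintf("two Gaussians R1=%g, R2=%g at (%s)/(%s), b=%g%s",
                              R1, R2, paste(c1, collapse = ","),
                              paste(c2, collapse = ","), b,
                              if (widths == "asymmetric") " (b1=2b)" else ""))
}

#' Exponential-decay expected-reward field
#'
#' \eqn{R(x) = e^{-\gamma x^h}} on the approach axis \eqn{x \ge 0}: the
#' expected reward decays away from a target at the origin. The log-field
#' is \eqn{-\gamma x^h} with derivative \eqn{-\gamma h x^{h-1}}.
#'
#' @param gamma_field Decay coefficient, positive. Default 0.04.
#' @param h_field Exponent, positive. Default 1.5.
#' @return A 1D [reward_field()]; evaluating at negative `x` is an error.
#' @examples
#' fld <- make_expdecay_field()
#' eval_field(fld, 1)      # exp(-0.04)
#' eval_grad_log(fld, 1)   # -0.06
#' @export
make_expdecay_field <- function(gamma_field = 0.04, h_field = 1.5) {
  stopifnot(gamma_field > 0, h_field > 0)
  f <- function(x) {
    v <- x[, 1L]
    if (any(v < 0)) stop("exponential-decay field is defined for x >= 0")
    exp(-gamma_field * v^h_field)
  }
  grad_log <- function(x) {
    v <- x[, 1L]
    if (any(v < 0)) stop("exponential-decay field is defined for x >= 0")
    -gamma_field * h_field * v^(h_field - 1)
  }
  reward_field(1L, f, grad_log, kind = "expdecay",
               pars = c(gamma_field, h_field),
               desc = sprintf("exp decay gamma=%g, h=%g", gamma_field,
                              h_field))
}

#' Check an analytic log-gradient against central finite differences
#'
#' @param field A [reward_field()].
#' @param x Probe positions (vector in 1D or matrix).
#' @param eps Finite-difference half-step.
#' @return Maximum relative discrepancy over probes (absolute discrepancy
#'   where the gradient is near zero).
#' @export
check_grad_log <- function(field, x, eps = 1e-5) {
  pts <- as_points(x, field$m)
  g <- as_points(eval_grad_log(field, pts), field$m)
  worst <- 0
  for (j in seq_len(field$m)) {
    hi <- pts; hi[, j] <- hi[, j] + eps
    lo <- pts; lo[, j] <- lo[, j] - eps
    fd <- (log(eval_field(field, hi)) - log(eval_field(field, lo))) / (2 * eps)
    err <- abs(fd - g[, j]) / pmax(abs(g[, j]), 1)
    worst <- max(worst, err)
  }
  worst
}

# Compact numeric descriptor consumed by the compiled simulators.
field_descriptor <- function(field) {
  stopifnot(inherits(field, "reward_field"))
  kinds <- c(uniform = 0L, gauss2 = 1L, expdecay = 2L)
  if (is.na(field$kind) || !(field$kind %in% names(kinds)))
    stop("this field has no parametric descriptor; the compiled ",
         "simulators support uniform, gauss2 and expdecay fields")
  list(kind = kinds[[field$kind]], pars = field$pars, m = field$m)
}
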