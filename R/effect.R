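#' Effect specification for a two-arm trial with binary endpoints
#'
#' Bundles the event probabilities of the intervention and control group
#' together with the standardized treatment effect
#' \deqn{\lambda = \frac{p_I - p_C}{\sqrt{\bar p (1 - \bar p)}}, \qquad
#'   \bar p = \frac{p_I + p_C}{2},}
#' which fully indexes the asymptotic law of the normal approximation test
#' statistic. An effect can be specified either by the pair `(p_I, p_C)` or by
#' `(lambda, p_C)`; the missing quantity is derived. `|lambda| <= 2` always.
#'
#' @param p_I Event probability in the intervention group (in `[0, 1]`).
#' @param p_C Event probability in the control group (in `[0, 1]`).
#' @param lambda Standardized treatment effect; used together with `p_C` when
#'   `p_I` is not supplied.
#'
#' @return An object of class `effect_spec`: a list with elements `p_I`,
#'   `p_C` and `lambda`.
#' @examples
#' effect_spec(p_I = 0.42, p_C = 0.30)      # lambda = 0.25
#' effect_spec(lambda = 0.25, p_C = 0.30)   # p_I = 0.42
#' @export
effect_spec <- function(p_I = NULL, p_C = NULL, lambda = NULL) {
  if (is.null(p_C)) stop("p_C must be supplied", call. = FALSE)
  stopifnot(is.numeric(p_C), length(p_C) == 1L, p_C >= 0, p_C <= 1)
  if (!is.null(p_I)) {
    stopifnot(is.numeric(p_I), length(p_I) == 1L, p_I >= 0, p_I <= 1)
    lambda <- if (p_I == p_C) 0 else lambda_from_proportions(p_I, p_C)
  } else if (!is.null(lambda)) {
    stopifnot(is.numeric(lambda), length(lambda) == 1L, abs(lambda) <= 2)
    p_I <- p_C + effect_from_lambda(lambda, p_C)
  } else {
    stop("supply either p_I or lambda", call. = FALSE)
  }
  structure(list(p_I = p_I, p_C = p_C, lambda = lambda), class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  cat(sprintf(
    "Binary-endpoint effect: p_I = %.4f, p_C = %.4f, lambda = %.4f\n",
    x$p_I, x$p_C, x$lambda))
  invisible(x)
}

#' Normal approximation test statistic for two proportions
#'
#' Computes the pooled-variance z statistic
#' \deqn{Z = \sqrt{n/2}\,\frac{\bar X_I - \bar X_C}{\sqrt{\bar p(1-\bar p)}}}
#' with \eqn{\bar p} the pooled observed proportion. When the pooled variance
#' is zero (both observed proportions 0, or both 1) the statistic is defined
#' as 0: degenerate data carry no evidence in either direction.
#'
#' @param xbar_I,xbar_C Observed proportions in the two groups (vectorized).
#' @param n Per-group sample size (`>= 1`).
#' @return Numeric vector of z values.
#' @examples
#' compute_z(0.4, 0.2, 50)  # 2.1822
#' @export
compute_z <- function(xbar_I, xbar_C, n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(xbar_I < 0 | xbar_I > 1 | xbar_C < 0 | xbar_C > 1))
    stop("observed proportions must lie in [0, 1]", call. = FALSE)
  k <- max(length(xbar_I), length(xbar_C), length(n))
  xbar_I <- rep_len(xbar_I, k); xbar_C <- rep_len(xbar_C, k)
  n <- rep_len(n, k)
  pbar <- (xbar_I + xbar_C) / 2
  v <- pbar * (1 - pbar)
  ifelse(v > 0, sqrt(n / 2) * (xbar_I - xbar_C) / sqrt(v), 0)
}

#' Standardized treatment effect from two proportions
#'
#' @param p_I,p_C Event probabilities with pooled mean strictly inside (0, 1).
#' @return The standardized effect \eqn{\lambda}; antisymmetric in its
#'   arguments and bounded by 2 in absolute value.
#' @examples
#' lambda_from_proportions(0.42, 0.30)  # 0.25
#' lambda_from_proportions(0.04, 0.12)  # -0.295
#' @export
lambda_from_proportions <- function(p_I, p_C) {
  pbar <- (p_I + p_C) / 2
  if (any(pbar <= 0 | pbar >= 1))
    stop("lambda undefined: pooled proportion must lie strictly in (0, 1)",
         call. = FALSE)
  (p_I - p_C) / sqrt(pbar * (1 - pbar))
}

#' Treatment effect implied by a standardized effect and a control proportion
#'
#' Solves the definition of \eqn{\lambda} for the risk difference
#' \eqn{d = p_I - p_C} given the control-group proportion. The definition is
#' quadratic in `d`; the root with the sign of `lambda` is taken, so the
#' result round-trips through [lambda_from_proportions()].
#'
#' @param lambda Standardized treatment effect.
#' @param p_C Control-group event probability.
#' @return The risk difference `p_I - p_C`.
#' @examples
#' effect_from_lambda(0.25, 0.3)  # 0.120
#' @export
effect_from_lambda <- function(lambda, p_C) {
  stopifnot(length(lambda) == 1L, length(p_C) == 1L)
  if (lambda == 0) return(0)
  l2 <- lambda^2
  # d^2 (1 + l2/4) - d l2 (1 - 2 p_C)/2 - l2 p_C (1 - p_C) = 0
  a <- 1 + l2 / 4
  b <- -l2 * (1 - 2 * p_C) / 2
  cc <- -l2 * p_C * (1 - p_C)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no admissible root for this (lambda, p_C)", call. = FALSE)
  d <- if (lambda > 0) (-b + sqrt(disc)) / (2 * a) else (-b - sqrt(disc)) / (2 * a)
  if (d < -p_C - 1e-12 || d > 1 - p_C + 1e-12)
    stop("no admissible p_I in [0, 1] for this (lambda, p_C)", call. = FALSE)
  min(max(d, -p_C), 1 - p_C)
}

#' Observed standardized treatment effect
#'
#' The interim estimate \eqn{\hat\lambda} formed by substituting observed
#' proportions into the definition of \eqn{\lambda}. Equals
#' `compute_z(xbar_I, xbar_C, n) / sqrt(n/2)` for any `n`. Degenerate pooled
#' data (variance zero) yield 0 by convention.
#'
#' @inheritParams compute_z
#' @return Numeric vector of observed effects, bounded by 2 in magnitude.
#' @export
observed_lambda <- function(xbar_I, xbar_C) {
  pbar <- (xbar_I + xbar_C) / 2
  v <- pbar * (1 - pbar)
  ifelse(v > 0, (xbar_I - xbar_C) / sqrt(v), 0)
}

#' Asymptotic law of the test statistic under the one-parameter model
#'
#' For a true standardized effect \eqn{\lambda} and per-group size `n`, the
#' normal approximation statistic is asymptotically
#' \eqn{N(\lambda\sqrt{n/2},\, 1 - \lambda^2/4)}.
#'
#' @param lambda Standardized treatment effect, `|lambda| <= 2`.
#' @param n Per-group sample size.
#' @return A list with elements `mean` and `variance`.
#' @examples
#' asymptotic_z_law(0.3, 50)  # mean 1.5, variance 0.9775
#' @export
asymptotic_z_law <- function(lambda, n) {
  stopifnot(abs(lambda) <= 2, n >= 1)
  list(mean = lambda * sqrt(n / 2), variance = 1 - lambda^2 / 4)
}

#' Fixed-design per-group sample size for a binary endpoint
#'
#' Per-group size of a single-stage design achieving power `1 - beta` at the
#' standardized effect `lambda`, using the one-parameter law of the normal
#' approximation statistic:
#' \deqn{n_{fix}(\lambda) = \left(\sqrt{2}\,\frac{q_{1-level}}{\lambda}
#'   + q_{1-\beta}\sqrt{\frac{2}{\lambda^2} - \frac{1}{2}}\right)^2,}
#' rounded up to an integer. The rejection quantile level is an explicit
#' argument: the sample-size target of the performance score plugs in the
#' local final-analysis level of the adaptive design, while a plain
#' fixed-design benchmark uses the global one-sided alpha.
#'
#' @param lambda Standardized treatment effect (`> 0`).
#' @param level One-sided significance level for the rejection quantile.
#' @param beta Type II error rate (power `1 - beta`).
#' @return Integer per-group sample size.
#' @examples
#' fixed_design_n(lambda_from_proportions(0.12, 0.04), 0.025, 0.2)  # 180
#' @export
fixed_design_n <- function(lambda, level, beta) {
  stopifnot(level > 0, level < 0.5, beta > 0, beta < 1)
  if (lambda <= 0)
    stop("no finite fixed-design sample size for lambda <= 0", call. = FALSE)
  raw <- (sqrt(2) * stats::qnorm(1 - level) / lambda +
            stats::qnorm(1 - beta) * sqrt(2 / lambda^2 - 1 / 2))^2
  as.integer(ceiling(raw))
}

#' Power of a fixed design at a given per-group sample size
#'
#' Evaluates \eqn{1 - \Phi\!\left(\frac{q_{1-level} - \lambda\sqrt{n/2}}
#' {\sqrt{1 - \lambda^2/4}}\right)} from the one-parameter asymptotic law.
#' At `|lambda| = 2` the law is degenerate and the power is a 0/1 step.
#'
#' @inheritParams fixed_design_n
#' @param n Per-group sample size (vectorized).
#' @return Power in `[0, 1]`.
#' @examples
#' fixed_design_power(0, 100, 0.025)  # 0.025 under the null
#' @export
fixed_design_power <- function(lambda, n, level) {
  stopifnot(all(n >= 1), abs(lambda) <= 2)
  q <- stats::qnorm(1 - level)
  num <- q - lambda * sqrt(n / 2)
  if (abs(lambda) == 2) return(as.numeric(num <= 0))
  1 - stats::pnorm(num / sqrt(1 - lambda^2 / 4))
}
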