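# Two-stage adaptive design machinery: Pocock-type local levels for the
# inverse normal combination test, interim zone classification.

# P(Z1 < q1, Z12 < q2) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature of the conditional normal CDF. Avoids any
# dependence on a multivariate-normal routine's conventions.
.bvn_lower <- function(q1, q2, rho) {
  if (rho >= 1 - 1e-12) return(stats::pnorm(min(q1, q2)))
  s <- sqrt(1 - rho^2)
  stats::integrate(
    function(x) stats::dnorm(x) * stats::pnorm((q2 - rho * x) / s),
    lower = -Inf, upper = q1, rel.tol = 1e-10, abs.tol = 1e-12
  )$value
}

#' Pocock-type local significance levels for a two-stage combination test
#'
#' Finds the common local one-sided level `a` such that the design rejecting
#' when \eqn{Z_1 \ge q_{1-a}} or \eqn{Z_{1+2} \ge q_{1-a}} has global level
#' `alpha`, where \eqn{(Z_1, Z_{1+2})} is standard bivariate normal under the
#' null with correlation \eqn{w_1/\sqrt{w_1^2 + w_2^2}}. Solved by root
#' bracketing on `a` to absolute tolerance 1e-8.
#'
#' @param w1,w2 Combination-test weights (`> 0`).
#' @param alpha Global one-sided significance level.
#' @return Named numeric vector `c(alpha1, alpha12)` (equal by construction).
#' @examples
#' pocock_levels(sqrt(50), sqrt(50), 0.025)  # both 0.0147
#' @export
pocock_levels <- function(w1, w2, alpha) {
  stopifnot(w1 > 0, w2 > 0, alpha > 0, alpha < 0.5)
  rho <- w1 / sqrt(w1^2 + w2^2)
  f <- function(a) {
    q <- stats::qnorm(1 - a)
    (1 - .bvn_lower(q, q, rho)) - alpha
  }
  sol <- stats::uniroot(f, lower = alpha / 2, upper = alpha,
                        tol = 1e-10, extendInt = "upX")
  if (abs(f(sol$root)) > 1e-7)
    stop("local level root-finding did not converge (residual ",
         format(f(sol$root)), ")", call. = FALSE)
  a <- sol$root
  c(alpha1 = a, alpha12 = a)
}

#' Design specification for a two-stage adaptive trial
#'
#' Collects the fixed design parameters: first-stage and maximum per-group
#' sample sizes, global one-sided level, futility level, inverse normal
#' combination weights, and the targeted conditional power complement. The
#' Pocock-type local levels `alpha1 = alpha12` maintaining the global level
#' are computed on construction (or may be supplied to skip the root solve).
#'
#' @param n1 First-stage per-group sample size (integer `>= 2`).
#' @param n_max Maximum per-group total sample size (`> n1`).
#' @param alpha Global one-sided significance level (default 0.025).
#' @param alpha0 Futility level: the trial stops for futility when
#'   \eqn{Z_1 < q_{1-\alpha_0}} (default 0.5, i.e. boundary at 0).
#' @param w1,w2 Combination weights; default `sqrt(n1)` for both, so the
#'   combination weights mirror equal stage sizes of the group sequential
#'   reference design.
#' @param beta Targeted conditional-power complement (default 0.2).
#' @param alpha1,alpha12 Optional pre-computed local levels.
#' @return An object of class `design_spec` with the above fields plus the
#'   cached boundary quantiles `q_futility`, `q_efficacy` (\eqn{q_{1-\alpha_1}})
#'   and `q_final` (\eqn{q_{1-\alpha_{1+2}}}).
#' @examples
#' d <- design_spec(n1 = 50, n_max = 200)
#' round(d$alpha1, 4)  # 0.0147
#' @export
design_spec <- function(n1, n_max, alpha = 0.025, alpha0 = 0.5,
                        w1 = sqrt(n1), w2 = sqrt(n1), beta = 0.2,
                        alpha1 = NULL, alpha12 = NULL) {
  stopifnot(n1 >= 2, n_max > n1, alpha > 0, alpha < 0.5,
            alpha0 > alpha, alpha0 <= 1, w1 > 0, w2 > 0,
            beta > 0, beta < 1)
  if (is.null(alpha1) || is.null(alpha12)) {
    lv <- pocock_levels(w1, w2, alpha)
    alpha1 <- lv[["alpha1"]]; alpha12 <- lv[["alpha12"]]
  }
  if (stats::qnorm(1 - alpha0) > stats::qnorm(1 - alpha1))
    stop("empty recalculation area: need q_{1-alpha0} <= q_{1-alpha1}",
         call. = FALSE)
  structure(list(
    n1 = as.integer(n1), n_max = as.integer(n_max),
    alpha = alpha, alpha0 = alpha0, w1 = w1, w2 = w2, beta = beta,
    alpha1 = alpha1, alpha12 = alpha12,
    q_futility = stats::qnorm(1 - alpha0),
    q_efficacy = stats::qnorm(1 - alpha1),
    q_final = stats::qnorm(1 - alpha12)
  ), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Two-stage adaptive design (inverse normal combination test)\n")
  cat(sprintf("  n1 = %d, n_max = %d per group\n", x$n1, x$n_max))
  cat(sprintf("  alpha = %.4f (one-sided), local levels alpha1 = alpha12 = %.4f\n",
              x$alpha, x$alpha1))
  cat(sprintf("  futility: stop if Z1 < %.4f (alpha0 = %.2f); efficacy: Z1 >= %.4f\n",
              x$q_futility, x$alpha0, x$q_efficacy))
  cat(sprintf("  weights w1 = %.4f, w2 = %.4f; target conditional power %.2f\n",
              x$w1, x$w2, 1 - x$beta))
  invisible(x)
}

#' Inverse normal combination of stagewise z statistics
#'
#' \eqn{Z_{1+2} = (w_1 Z_1 + w_2 Z_2)/\sqrt{w_1^2 + w_2^2}}; standard normal
#' under the null when both inputs are.
#'
#' @param z1,z2 Stagewise z statistics (vectorized).
#' @param w1,w2 Pre-fixed weights (`> 0`).
#' @return Combined z statistic.
#' @export
combine_inverse_normal <- function(z1, z2, w1, w2) {
  stopifnot(w1 > 0, w2 > 0)
  (w1 * z1 + w2 * z2) / sqrt(w1^2 + w2^2)
}

#' Classify an interim statistic into futility / efficacy / recalculation
#'
#' Futility when \eqn{Z_1 < q_{1-\alpha_0}} (strict, binding stop), efficacy
#' when \eqn{Z_1 \ge q_{1-\alpha_1}}, otherwise the half-open recalculation
#' area \eqn{[q_{1-\alpha_0}, q_{1-\alpha_1})}.
#'
#' @param z1 Interim z statistic (vectorized).
#' @param design A [design_spec()].
#' @return Character vector with values `"futility"`, `"efficacy"`,
#'   `"recalculation"`.
#' @export
classify_interim <- function(z1, design) {
  stopifnot(inherits(design, "design_spec"))
  ifelse(z1 < design$q_futility, "futility",
         ifelse(z1 >= design$q_efficacy, "efficacy", "recalculation"))
}
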