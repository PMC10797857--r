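# True (known-parameter) conditional power, used for global power.

#' True conditional power of a continuing trial
#'
#' Probability, under the true effect, of rejecting at the final analysis
#' given the interim statistic `z1` and the recalculated stage-2 size `n2`:
#' the stage-2 statistic must exceed
#' \eqn{(q_{1-\alpha_{1+2}}\sqrt{w_1^2+w_2^2} - w_1 z_1)/w_2}.
#' The default estimates this probability by exact Bernoulli simulation of
#' the stage-2 data (the asymptotic law is only approximate for binary
#' endpoints at realistic sample sizes); `method = "asymptotic"` evaluates
#' the closed form from the one-parameter normal law instead.
#'
#' @param z1 Interim z statistic (scalar).
#' @param n2 Per-group stage-2 sample size (`>= 1`).
#' @param effect An [effect_spec()] giving the true `(p_I, p_C)`.
#' @param design A [design_spec()].
#' @param reps Number of simulated stage-2 datasets (default 1000).
#' @param method `"simulation"` (default, exact Bernoulli) or `"asymptotic"`.
#' @param seed Optional integer seed for the simulation draws.
#' @return Estimated conditional power in `[0, 1]`.
#' @export
true_conditional_power <- function(z1, n2, effect, design, reps = 1000,
                                   method = c("simulation", "asymptotic"),
                                   seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(effect, "effect_spec"), inherits(design, "design_spec"),
            n2 >= 1, reps >= 1)
  threshold <- (design$q_final * sqrt(design$w1^2 + design$w2^2) -
                  design$w1 * z1) / design$w2
  if (method == "asymptotic") {
    law <- asymptotic_z_law(effect$lambda, n2)
    if (law$variance <= 0) return(as.numeric(law$mean > threshold))
    return(1 - stats::pnorm((threshold - law$mean) / sqrt(law$variance)))
  }
  if (!is.null(seed)) set.seed(seed)
  xI <- stats::rbinom(reps, n2, effect$p_I) / n2
  xC <- stats::rbinom(reps, n2, effect$p_C) / n2
  mean(compute_z(xI, xC, n2) > threshold)
}
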