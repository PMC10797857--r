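# Conditional performance score: target values, four components, weighted
# combination, end-to-end pipeline.

#' Target values for the conditional performance score
#'
#' When the true standardized effect is positive and a fixed design with the
#' targeted power fits inside `n_max`, the score targets conditional power
#' `1 - beta` and sample size `n_fix(lambda)`; otherwise (no or non-positive
#' effect, or `n_fix > n_max`) the targets fall back to the significance
#' level `alpha` and the first-stage size `n1`. The fixed-design size is by
#' default evaluated at the local final-analysis level `alpha12`; set
#' `n_fix_level = "alpha"` to use the plain global level instead (the two
#' conventions differ only near the branch point, which both are made
#' available for).
#'
#' @param lambda True standardized treatment effect.
#' @param design A [design_spec()].
#' @param beta Conditional-power complement (defaults to `design$beta`).
#' @param n_fix_level `"alpha12"` (default) or `"alpha"`.
#' @return An object of class `score_targets`: list with `cp_target`,
#'   `n_target`, `branch` (`"powered"` or `"fallback"`).
#' @examples
#' d <- design_spec(50, 200)
#' score_targets(0.4, d)  # powered branch: cp 0.8, n_fix(0.4)
#' score_targets(0.1, d)  # fallback: cp 0.025, n 50
#' @export
score_targets <- function(lambda, design, beta = design$beta,
                          n_fix_level = c("alpha12", "alpha")) {
  stopifnot(inherits(design, "design_spec"))
  n_fix_level <- match.arg(n_fix_level)
  level <- if (n_fix_level == "alpha12") design$alpha12 else design$alpha
  n_fix <- if (lambda > 0) fixed_design_n(lambda, level, beta) else NA_integer_
  if (!is.na(n_fix) && n_fix <= design$n_max) {
    structure(list(cp_target = 1 - beta, n_target = n_fix,
                   branch = "powered"), class = "score_targets")
  } else {
    structure(list(cp_target = design$alpha, n_target = design$n1,
                   branch = "fallback"), class = "score_targets")
  }
}

#' Components of the conditional performance score
#'
#' Location components measure the deviation of the conditional means from
#' their targets relative to the maximal possible deviation; variation
#' components the ratio of the conditional standard deviations to the
#' maximal possible ones:
#' \deqn{l_{CP} = 1 - \frac{|E[CP] - CP_{target}|}{1-\alpha}, \quad
#'       v_{CP} = 1 - \sqrt{Var(CP) / (1/4)},}
#' \deqn{l_{N} = 1 - \frac{|E[N] - N_{target}|}{n_{max}-n_1}, \quad
#'       v_{N} = 1 - \sqrt{Var(N) / ((n_{max}-n_1)/2)^2}.}
#' Each component is clipped to `[0, 1]` (the location numerators can in
#' principle exceed the nominal maximal deviation; clipping enforces the
#' component range by contract).
#'
#' @param summary A [conditional_summary()].
#' @param targets A [score_targets()].
#' @param design A [design_spec()].
#' @return Named numeric vector `c(l_cp, v_cp, l_n, v_n)`.
#' @export
score_components <- function(summary, targets, design) {
  stopifnot(inherits(summary, "conditional_summary"),
            inherits(targets, "score_targets"),
            inherits(design, "design_spec"))
  span_n <- design$n_max - design$n1
  clip01 <- function(x) min(max(x, 0), 1)
  c(l_cp = clip01(1 - abs(summary$e_cp - targets$cp_target) / (1 - design$alpha)),
    v_cp = clip01(1 - sqrt(summary$var_cp / (1 / 4))),
    l_n  = clip01(1 - abs(summary$e_n - targets$n_target) / span_n),
    v_n  = clip01(1 - sqrt(summary$var_n / (span_n / 2)^2)))
}

#' Combine score components into the conditional performance score
#'
#' Weighted sum of the four components; the default weights of 1/4 give the
#' equally weighted score.
#'
#' @param components Numeric vector `c(l_cp, v_cp, l_n, v_n)`.
#' @param weights Nonnegative weights summing to 1 (default `rep(1/4, 4)`).
#' @return The score `S` in `[0, 1]`.
#' @export
combine_score <- function(components, weights = rep(1 / 4, 4)) {
  stopifnot(length(components) == 4, length(weights) == 4, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  sum(weights * components)
}

#' Conditional performance score of a recalculation rule
#'
#' End-to-end pipeline: simulates the design ([run_design()]), summarizes the
#' conditional distribution of observed conditional power and total sample
#' size ([conditional_summary()]), derives the target values
#' ([score_targets()]) and combines the four components into the score.
#'
#' @inheritParams run_design
#' @param weights Component weights (default equal, 1/4).
#' @param n_fix_level Quantile convention for the sample-size target, see
#'   [score_targets()].
#' @return An object of class `score_result`: list with `S`, `components`,
#'   `weights`, `targets`, `summary`, and the input specs.
#' @examples
#' eff <- effect_spec(lambda = 0.2, p_C = 0.3)
#' des <- design_spec(50, 200)
#' conditional_score(eff, des, rule_spec("classicGS"), n_sim = 500, seed = 1)
#' @export
conditional_score <- function(effect, design, rule, n_sim = 10000,
                              seed = NULL, weights = rep(1 / 4, 4),
                              n_fix_level = c("alpha12", "alpha")) {
  n_fix_level <- match.arg(n_fix_level)
  records <- run_design(effect, design, rule, n_sim = n_sim, seed = seed)
  summ <- conditional_summary(records)
  targets <- score_targets(effect$lambda, design, n_fix_level = n_fix_level)
  comps <- score_components(summ, targets, design)
  structure(list(
    S = combine_score(comps, weights), components = comps, weights = weights,
    targets = targets, summary = summ,
    effect = effect, design = design, rule = rule,
    n_sim = n_sim, seed = seed
  ), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("Conditional performance score: S = %.3f (%s, lambda = %.3f)\n",
              x$S, x$rule$kind, x$effect$lambda))
  cat(sprintf("  components: l_CP = %.3f, v_CP = %.3f, l_N = %.3f, v_N = %.3f\n",
              x$components["l_cp"], x$components["v_cp"],
              x$components["l_n"], x$components["v_n"]))
  cat(sprintf("  targets: CP %.3f, N %s (%s branch); %d conditional trials\n",
              x$targets$cp_target, format(x$targets$n_target),
              x$targets$branch, x$summary$n_cond))
  invisible(x)
}

#' Serialize one or more score results to a data frame
#'
#' @param results A `score_result` or list of them.
#' @return Data frame with one row per result, keyed by rule, lambda, p_C,
#'   seed and simulation size.
#' @export
score_result_table <- function(results) {
  if (inherits(results, "score_result")) results <- list(results)
  do.call(rbind, lapply(results, function(x) {
    data.frame(rule = x$rule$kind, lambda = x$effect$lambda,
               p_C = x$effect$p_C, n_sim = x$n_sim,
               seed = if (is.null(x$seed)) NA_integer_ else x$seed,
               l_cp = x$components[["l_cp"]], v_cp = x$components[["v_cp"]],
               l_n = x$components[["l_n"]], v_n = x$components[["v_n"]],
               S = x$S)
  }))
}
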