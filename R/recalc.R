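# Sample size recalculation rules and the observed-conditional-power
# calculus they share.

#' Specification of a sample size recalculation rule
#'
#' @param kind One of `"classicGS"` (constant group-sequential stage-2 size),
#'   `"OCP"` (observed conditional power), `"restrOCP"` (restricted observed
#'   conditional power with an interim futility threshold), `"promising"`
#'   (promising zone), `"optfunc"` (optimization function trading conditional
#'   power against sample size).
#' @param beta Target conditional-power complement (default 0.2, i.e. target
#'   conditional power 0.8).
#' @param beta0_restr Restricted-OCP complement: the trial stops at interim
#'   when even the maximal stage-2 size cannot deliver conditional power
#'   `1 - beta0_restr` (default 0.4).
#' @param beta0_prom Promising-zone lower complement: interim results with
#'   conditional power at the group-sequential size below `1 - beta0_prom`
#'   are "unfavourable" (default 0.64).
#' @param n_ini Initially planned per-group stage-2 size; also the
#'   group-sequential reference size used by the promising-zone and
#'   optimization rules. Defaults to the design's `n1` when a rule is applied.
#' @param gamma Optimization-function trade-off between conditional power and
#'   per-patient cost (default `0.005 / 4`).
#' @return An object of class `rule_spec`.
#' @examples
#' rule_spec("promising")
#' rule_spec("optfunc", gamma = 0.0022)
#' @export
rule_spec <- function(kind = c("classicGS", "OCP", "restrOCP", "promising",
                               "optfunc"),
                      beta = 0.2, beta0_restr = 0.4, beta0_prom = 0.64,
                      n_ini = NULL, gamma = 0.005 / 4) {
  kind <- match.arg(kind)
  stopifnot(beta > 0, beta < 1, beta0_restr >= beta, beta0_prom >= beta)
  if (kind == "optfunc" && (!is.numeric(gamma) || gamma <= 0))
    stop("gamma must be > 0 for the optimization function rule", call. = FALSE)
  structure(list(kind = kind, beta = beta, beta0_restr = beta0_restr,
                 beta0_prom = beta0_prom, n_ini = n_ini, gamma = gamma),
            class = "rule_spec")
}

#' @export
print.rule_spec <- function(x, ...) {
  cat(sprintf("Recalculation rule: %s (target CP %.2f)\n", x$kind, 1 - x$beta))
  invisible(x)
}

.n_ini <- function(rule, design) {
  if (is.null(rule$n_ini)) design$n1 else as.integer(rule$n_ini)
}

#' Observed conditional power of the combination test
#'
#' Probability of rejecting at the final analysis given the interim statistic
#' `z1`, evaluated under the observed standardized effect `lam_hat`:
#' \deqn{CP_{\hat\lambda}(z_1, n_2) = 1 - \Phi\!\left(
#'   \frac{\frac{\sqrt{w_1^2+w_2^2}}{w_2} q_{1-\alpha_{1+2}}
#'         - \frac{w_1}{w_2} z_1 - \hat\lambda\sqrt{n_2/2}}
#'        {\sqrt{1 - \hat\lambda^2/4}}\right).}
#' Strictly increasing in `z1`, in `lam_hat`, and (for positive `lam_hat`)
#' in `n2`. At `|lam_hat| = 2` the variance is zero and the value is a 0/1
#' step by the sign of the numerator.
#'
#' @param z1 Interim z statistic (vectorized).
#' @param lam_hat Observed standardized effect (vectorized).
#' @param n2 Per-group stage-2 sample size (vectorized).
#' @param design A [design_spec()].
#' @return Conditional power values in `[0, 1]`.
#' @examples
#' d <- design_spec(50, 200)
#' observed_conditional_power(1.0, 0.2, 150, d)  # 0.363
#' @export
observed_conditional_power <- function(z1, lam_hat, n2, design) {
  k <- max(length(z1), length(lam_hat), length(n2))
  z1 <- rep_len(z1, k); lam_hat <- rep_len(lam_hat, k); n2 <- rep_len(n2, k)
  sw <- sqrt(design$w1^2 + design$w2^2)
  num <- sw / design$w2 * design$q_final - design$w1 / design$w2 * z1 -
    lam_hat * sqrt(n2 / 2)
  s2 <- 1 - lam_hat^2 / 4
  out <- numeric(k)
  deg <- s2 <= 0  # |lam_hat| = 2: zero-variance step
  out[!deg] <- 1 - stats::pnorm(num[!deg] / sqrt(s2[!deg]))
  out[deg] <- as.numeric(num[deg] <= 0)
  out
}

#' Stage-2 sample size achieving a target observed conditional power
#'
#' Closed-form inversion of the observed conditional power in `n2` (unique
#' because the conditional power is strictly monotone in `n2` for positive
#' observed effects):
#' \deqn{n_2 = \frac{2}{\hat\lambda^2}\left(
#'   \frac{\sqrt{w_1^2+w_2^2}}{w_2} q_{1-\alpha_{1+2}}
#'   - \frac{w_1}{w_2} z_1 + q_{target}\sqrt{1-\hat\lambda^2/4}\right)^2}
#' when the bracket is positive, else 0. The unrounded value plugged back
#' into [observed_conditional_power()] returns the target.
#'
#' @inheritParams observed_conditional_power
#' @param target_cp Target conditional power in `(0, 1)`.
#' @return Real-valued (unrounded) stage-2 per-group size; `NA` signals an
#'   unattainable target (`lam_hat <= 0`), which callers clamp to the maximal
#'   stage-2 size.
#' @export
invert_cp_for_n2 <- function(z1, lam_hat, target_cp, design) {
  stopifnot(all(target_cp > 0), all(target_cp < 1))
  k <- max(length(z1), length(lam_hat), length(target_cp))
  z1 <- rep_len(z1, k); lam_hat <- rep_len(lam_hat, k)
  target_cp <- rep_len(target_cp, k)
  sw <- sqrt(design$w1^2 + design$w2^2)
  bracket <- sw / design$w2 * design$q_final - design$w1 / design$w2 * z1 +
    stats::qnorm(target_cp) * sqrt(pmax(1 - lam_hat^2 / 4, 0))
  out <- ifelse(bracket > 0, 2 / lam_hat^2 * bracket^2, 0)
  out[lam_hat <= 0] <- NA_real_
  out
}

# --- the five rules (vectorized over z1 / lam_hat) ------------------------
# Each returns list(n2 = integer vector, stopped = logical vector); n2 = 0
# with stopped = TRUE only for restricted-OCP interim stops.

#' Classic group sequential rule: constant stage-2 size
#'
#' @inheritParams observed_conditional_power
#' @param rule A [rule_spec()].
#' @return A list with integer vector `n2` and logical vector `stopped`.
#' @export
rule_classic_gs <- function(z1, design, rule) {
  list(n2 = rep(.n_ini(rule, design), length(z1)),
       stopped = rep(FALSE, length(z1)))
}

# ceiling + clamp of the OCP inversion; unattainable targets get the maximum
.ocp_n2 <- function(z1, lam_hat, design, rule) {
  nmx <- design$n_max - design$n1
  raw <- invert_cp_for_n2(z1, lam_hat, 1 - rule$beta, design)
  n2 <- ifelse(is.na(raw), nmx, pmin(pmax(ceiling(raw), 1), nmx))
  as.integer(n2)
}

#' Observed conditional power rule
#'
#' Chooses the smallest stage-2 size delivering the target conditional power
#' `1 - beta` under the observed effect, capped at `n_max - n1` (also used
#' when the target is unattainable) and floored at 1.
#'
#' @inheritParams rule_classic_gs
#' @param lam_hat Observed standardized effect (vectorized).
#' @export
rule_ocp <- function(z1, lam_hat, design, rule) {
  list(n2 = .ocp_n2(z1, lam_hat, design, rule),
       stopped = rep(FALSE, length(z1)))
}

#' Restricted observed conditional power rule
#'
#' As [rule_ocp()], but the trial stops at interim (stage-2 size 0) when even
#' the maximal stage-2 size yields conditional power below
#' `1 - beta0_restr` — continuing is then judged not worth the effort.
#'
#' @inheritParams rule_ocp
#' @export
rule_restricted_ocp <- function(z1, lam_hat, design, rule) {
  nmx <- design$n_max - design$n1
  cp_max <- observed_conditional_power(z1, lam_hat, nmx, design)
  stopped <- cp_max < 1 - rule$beta0_restr
  n2 <- .ocp_n2(z1, lam_hat, design, rule)
  n2[stopped] <- 0L
  list(n2 = n2, stopped = stopped)
}

#' Promising zone rule
#'
#' Evaluates the conditional power `c` at the group-sequential stage-2 size
#' `n_ini`. Unfavourable (`c < 1 - beta0_prom`) and favourable
#' (`c > 1 - beta`) interim results keep the group-sequential size; in the
#' promising zone in between, the observed conditional power rule applies.
#'
#' @inheritParams rule_ocp
#' @export
rule_promising_zone <- function(z1, lam_hat, design, rule) {
  n_gs <- .n_ini(rule, design)
  cp_gs <- observed_conditional_power(z1, lam_hat, n_gs, design)
  promising <- cp_gs >= 1 - rule$beta0_prom & cp_gs <= 1 - rule$beta
  n2 <- rep(as.integer(n_gs), length(z1))
  if (any(promising))
    n2[promising] <- .ocp_n2(z1[promising], lam_hat[promising], design, rule)
  list(n2 = n2, stopped = rep(FALSE, length(z1)))
}

#' Optimization function rule
#'
#' Maximizes \eqn{f(m) = CP_{\hat\lambda}(z_1, m) - \gamma\,(m - n_{ini})}
#' over integer stage-2 sizes `m` between the initially planned
#' group-sequential size `n_ini` and `n_max - n1`, by exhaustive scan (ties
#' broken toward the smaller size). The sample size is thus never reduced
#' below the group-sequential plan; `gamma` prices each additional patient
#' per group against the gain in conditional power.
#'
#' @inheritParams rule_ocp
#' @export
rule_optfunc <- function(z1, lam_hat, design, rule) {
  m <- seq.int(.n_ini(rule, design), design$n_max - design$n1)
  n2 <- vapply(seq_along(z1), function(i) {
    f <- observed_conditional_power(z1[i], lam_hat[i], m, design) -
      rule$gamma * (m - m[1L])
    m[which.max(f)]  # which.max takes the first maximum: smaller m on ties
  }, integer(1))
  list(n2 = n2, stopped = rep(FALSE, length(z1)))
}

#' Apply a recalculation rule to interim results
#'
#' Dispatches on `rule$kind`; inputs are vectors over simulated trials whose
#' interim statistic falls in the recalculation area.
#'
#' @inheritParams rule_ocp
#' @return A list with integer vector `n2` and logical vector `stopped`.
#' @export
recalc_n2 <- function(z1, lam_hat, design, rule) {
  stopifnot(inherits(design, "design_spec"), inherits(rule, "rule_spec"))
  switch(rule$kind,
    classicGS = rule_classic_gs(z1, design, rule),
    OCP       = rule_ocp(z1, lam_hat, design, rule),
    restrOCP  = rule_restricted_ocp(z1, lam_hat, design, rule),
    promising = rule_promising_zone(z1, lam_hat, design, rule),
    optfunc   = rule_optfunc(z1, lam_hat, design, rule)
  )
}
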