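# Outer Monte-Carlo engine: exact interim simulation, per-trial records,
# conditional summaries, global power and mean sample size.

#' Simulate the exact distribution of the interim test statistic
#'
#' Draws `n_sim` first-stage datasets (per-group Bernoulli samples of size
#' `n1`) and returns the interim z statistics. The exact small-sample
#' distribution is used, not the asymptotic normal law.
#'
#' @param effect An [effect_spec()].
#' @param n1 First-stage per-group sample size.
#' @param n_sim Number of simulated trials.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_sim` interim z values.
#' @export
simulate_interim <- function(effect, n1, n_sim, seed = NULL) {
  stopifnot(inherits(effect, "effect_spec"), n1 >= 1, n_sim >= 1)
  if (!is.null(seed)) set.seed(seed)
  xI <- stats::rbinom(n_sim, n1, effect$p_I) / n1
  xC <- stats::rbinom(n_sim, n1, effect$p_C) / n1
  compute_z(xI, xC, n1)
}

#' Simulate a two-stage adaptive design under a recalculation rule
#'
#' For each simulated interim statistic: classify the zone; within the
#' recalculation area, form the observed standardized effect
#' \eqn{\hat\lambda = z_1/\sqrt{n_1/2}}, apply the recalculation rule, and
#' record the stage-2 size, total per-group size and the observed conditional
#' power (0 for restricted-OCP interim stops, which remain part of the
#' conditional evaluation set).
#'
#' @param effect An [effect_spec()].
#' @param design A [design_spec()].
#' @param rule A [rule_spec()].
#' @param n_sim Number of simulated trials (default 10000).
#' @param seed Optional integer seed (drives the interim draws).
#' @return A data frame of class `trial_records` with one row per trial and
#'   columns `z1`, `zone`, `n2`, `N`, `cp_obs`, `stopped_restr`; the specs
#'   and seed are attached as attributes.
#' @examples
#' eff <- effect_spec(lambda = 0.2, p_C = 0.3)
#' des <- design_spec(50, 200)
#' rec <- run_design(eff, des, rule_spec("classicGS"), n_sim = 200, seed = 1)
#' table(rec$zone)
#' @export
run_design <- function(effect, design, rule, n_sim = 10000, seed = NULL) {
  stopifnot(inherits(design, "design_spec"), inherits(rule, "rule_spec"))
  z1 <- simulate_interim(effect, design$n1, n_sim, seed = seed)
  zone <- classify_interim(z1, design)
  n2 <- integer(n_sim)
  cp_obs <- numeric(n_sim)
  stopped <- logical(n_sim)
  rec <- zone == "recalculation"
  if (any(rec)) {
    lam_hat <- z1[rec] / sqrt(design$n1 / 2)
    res <- recalc_n2(z1[rec], lam_hat, design, rule)
    n2[rec] <- res$n2
    stopped[rec] <- res$stopped
    cont <- rec
    cont[rec] <- !res$stopped
    cp <- numeric(sum(rec))
    cp[!res$stopped] <- observed_conditional_power(
      z1[rec][!res$stopped], lam_hat[!res$stopped],
      res$n2[!res$stopped], design)
    cp_obs[rec] <- cp
  }
  out <- data.frame(z1 = z1, zone = zone, n2 = n2,
                    N = design$n1 + n2, cp_obs = cp_obs,
                    stopped_restr = stopped)
  class(out) <- c("trial_records", "data.frame")
  attr(out, "effect") <- effect
  attr(out, "design") <- design
  attr(out, "rule") <- rule
  attr(out, "seed") <- seed
  attr(out, "n_sim") <- n_sim
  out
}

#' Conditional summary of a simulated design
#'
#' Means and population variances (divide-by-n) of the observed conditional
#' power and the total per-group sample size, restricted to trials whose
#' interim statistic falls in the recalculation area. Restricted-OCP interim
#' stops contribute `(N = n1, CP = 0)`.
#'
#' @param records A `trial_records` data frame from [run_design()].
#' @return An object of class `conditional_summary`: list with `e_cp`,
#'   `var_cp`, `e_n`, `var_n`, `n_cond`, `n_sim`.
#' @export
conditional_summary <- function(records) {
  stopifnot(inherits(records, "trial_records"))
  cond <- records[records$zone == "recalculation", , drop = FALSE]
  if (nrow(cond) < 2)
    stop("insufficient data: fewer than 2 trials in the recalculation area",
         call. = FALSE)
  pop_var <- function(x) mean((x - mean(x))^2)
  structure(list(
    e_cp = mean(cond$cp_obs), var_cp = pop_var(cond$cp_obs),
    e_n = mean(cond$N), var_n = pop_var(cond$N),
    n_cond = nrow(cond), n_sim = nrow(records)
  ), class = "conditional_summary")
}

#' @export
print.conditional_summary <- function(x, ...) {
  cat(sprintf(
    "Conditional summary (%d of %d trials in recalculation area)\n",
    x$n_cond, x$n_sim))
  cat(sprintf("  E[CP] = %.4f, Var(CP) = %.5f\n", x$e_cp, x$var_cp))
  cat(sprintf("  E[N]  = %.2f, Var(N)  = %.2f (per group)\n", x$e_n, x$var_n))
  invisible(x)
}

#' Global power of a simulated adaptive design
#'
#' Estimates
#' \deqn{Pow = \frac{1}{N_{sim}}\sum_i \left[\mathbf{1}\{Z_{1,i} \ge
#'   q_{1-\alpha_1}\} + \mathbf{1}\{\text{continue}\}\,
#'   CP_\lambda(Z_{1,i}, n_{2,i})\right],}
#' where the true conditional power of each continuing trial is obtained by
#' inner Bernoulli simulation of the stage-2 statistic (see
#' [true_conditional_power()]). Futility and restricted-OCP stops contribute
#' zero. Inner-simulation seeds are derived per trial from `seed` by a
#' counter, so the interim draws (made in [run_design()]) are unaffected by
#' `cp_reps`.
#'
#' @param records A `trial_records` data frame from [run_design()].
#' @param cp_reps Inner simulation size per continuing trial (default 1000).
#' @param seed Optional integer seed for the inner simulations.
#' @param method Passed to [true_conditional_power()].
#' @return Estimated global power in `[0, 1]`.
#' @export
global_power <- function(records, cp_reps = 1000, seed = NULL,
                         method = c("simulation", "asymptotic")) {
  stopifnot(inherits(records, "trial_records"))
  method <- match.arg(method)
  effect <- attr(records, "effect")
  design <- attr(records, "design")
  cont <- which(records$zone == "recalculation" & !records$stopped_restr)
  cp <- numeric(length(cont))
  for (k in seq_along(cont)) {
    i <- cont[k]
    s <- if (is.null(seed)) NULL else (seed + 1009 * k) %% 2147483647
    cp[k] <- true_conditional_power(records$z1[i], records$n2[i], effect,
                                    design, reps = cp_reps, method = method,
                                    seed = s)
  }
  (sum(records$zone == "efficacy") + sum(cp)) / nrow(records)
}

#' Mean sample size of a simulated design
#'
#' Unconditional mean of the total per-group sample size over all simulated
#' trials (stopped trials contribute `n1`), together with the two-group
#' total.
#'
#' @param records A `trial_records` data frame from [run_design()].
#' @return Named numeric vector `c(per_group, total)`.
#' @export
mean_sample_size <- function(records) {
  stopifnot(inherits(records, "trial_records"), nrow(records) > 0)
  m <- mean(records$N)
  c(per_group = m, total = 2 * m)
}

#' Write simulated trial records to CSV
#'
#' @param records A `trial_records` data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
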