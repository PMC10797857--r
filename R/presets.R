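# Simulation presets, configuration I/O and tabular reporting.

#' Preset run configurations for the two built-in evaluation settings
#'
#' `"main"`: first-stage size 50, maximum 200 per group, one-sided alpha
#' 0.025 with Pocock-type local levels, futility level 0.5, control
#' proportion 0.3, target conditional power 0.8, promising-zone and
#' restricted-OCP thresholds 0.36 / 0.6, optimization trade-off 0.005/4, all
#' five rules, effect grid lambda = 0, 0.05, ..., 0.6.
#'
#' `"apsac"`: a thrombolytic-therapy mortality trial re-imagined as an
#' adaptive design: first-stage size 90, maximum 270 per group, assumed
#' mortality 4% vs 12% (standardized effect 0.295 after switching group
#' roles, since the treatment lowers a harmful endpoint), optimization
#' trade-off 0.0022 calibrated as the per-patient power gain of the fixed
#' design at its target size (180 per arm for 80% power at one-sided 2.5%).
#'
#' @param name `"main"` or `"apsac"`.
#' @return An object of class `run_config`: list with `design`, `rules`
#'   (named list of all five [rule_spec()]s), `lambda_grid`, `figure_grid`,
#'   `p_C`, `n_sim`, `cp_reps`, `seed`, and (for `"apsac"`) a `fixed_ref`
#'   reference design entry.
#' @examples
#' preset("main")$design$n1    # 50
#' preset("apsac")$design$n_max  # 270
#' @export
preset <- function(name = c("main", "apsac")) {
  name <- match.arg(name)
  if (name == "main") {
    design <- design_spec(n1 = 50, n_max = 200)
    gamma <- 0.005 / 4
    fixed_ref <- NULL
  } else {
    design <- design_spec(n1 = 90, n_max = 270)
    gamma <- 0.0022
    fixed_ref <- list(lambda = 0.295, n = 180, power = 0.8)
  }
  rules <- list(
    OCP       = rule_spec("OCP"),
    restrOCP  = rule_spec("restrOCP"),
    promising = rule_spec("promising"),
    optfunc   = rule_spec("optfunc", gamma = gamma),
    classicGS = rule_spec("classicGS")
  )
  structure(list(
    name = name, design = design, rules = rules,
    lambda_grid = seq(0, 0.6, by = 0.05),
    figure_grid = c(0, 0.1, 0.2, 0.3, 0.35, 0.4, 0.5, 0.6),
    p_C = 0.3, n_sim = 10000, cp_reps = 1000, seed = 1,
    fixed_ref = fixed_ref
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration '%s': %d rules x %d lambda values\n",
              x$name, length(x$rules), length(x$lambda_grid)))
  cat(sprintf("  p_C = %.2f, n_sim = %d, cp_reps = %d, seed = %d\n",
              x$p_C, x$n_sim, x$cp_reps, x$seed))
  print(x$design)
  invisible(x)
}

#' Write a run configuration to a YAML file
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  d <- config$design
  doc <- list(
    name = config$name,
    design = list(n1 = d$n1, n_max = d$n_max, alpha = d$alpha,
                  alpha0 = d$alpha0, w1 = d$w1, w2 = d$w2, beta = d$beta),
    rules = lapply(config$rules, function(r)
      list(kind = r$kind, beta = r$beta, beta0_restr = r$beta0_restr,
           beta0_prom = r$beta0_prom, n_ini = r$n_ini, gamma = r$gamma)),
    lambda_grid = config$lambda_grid, figure_grid = config$figure_grid,
    p_C = config$p_C, n_sim = config$n_sim, cp_reps = config$cp_reps,
    seed = config$seed, fixed_ref = config$fixed_ref
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file written by [write_run_config()] (or hand
#'   edited with the same structure).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  design <- do.call(design_spec, doc$design)
  rules <- lapply(doc$rules, function(r) {
    r$n_ini <- if (is.null(r$n_ini)) NULL else r$n_ini
    do.call(rule_spec, r)
  })
  structure(list(
    name = doc$name, design = design, rules = rules,
    lambda_grid = as.numeric(doc$lambda_grid),
    figure_grid = as.numeric(doc$figure_grid),
    p_C = doc$p_C, n_sim = doc$n_sim, cp_reps = doc$cp_reps,
    seed = doc$seed, fixed_ref = doc$fixed_ref
  ), class = "run_config")
}

#' Run a configuration and write score, power and sample-size tables
#'
#' For every (rule, lambda) pair: simulates the design, computes the
#' conditional performance score, the global mean per-group sample size and
#' (optionally, it is the expensive part) the global power with inner
#' Bernoulli simulation. Writes `scores.csv`, `mean_n.csv`, `power.csv`
#' (rows = lambda, columns = rules) and a JSON `manifest.json` recording the
#' configuration and seeds.
#'
#' @param config A `run_config` from [preset()] or [read_run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param include_power Compute the global power table (default `TRUE`).
#' @return A list with data frames `scores`, `mean_n`, `power` (NULL when
#'   skipped) and `details` (long-format per-run table), invisibly when
#'   `out_dir` is given.
#' @export
run_and_report <- function(config, out_dir = NULL, include_power = TRUE) {
  stopifnot(inherits(config, "run_config"))
  lam <- config$lambda_grid
  rules <- config$rules
  scores <- matrix(NA_real_, length(lam), length(rules),
                   dimnames = list(lambda = lam, rule = names(rules)))
  meann <- scores
  power <- if (include_power) scores else NULL
  details <- list()
  for (li in seq_along(lam)) {
    eff <- effect_spec(lambda = lam[li], p_C = config$p_C)
    for (ri in seq_along(rules)) {
      seed <- (config$seed + 101 * li + 10007 * ri) %% 2147483647
      rec <- run_design(eff, config$design, rules[[ri]],
                        n_sim = config$n_sim, seed = seed)
      sc <- conditional_score(eff, config$design, rules[[ri]],
                              n_sim = config$n_sim, seed = seed)
      scores[li, ri] <- sc$S
      meann[li, ri] <- mean_sample_size(rec)[["per_group"]]
      if (include_power)
        power[li, ri] <- global_power(rec, cp_reps = config$cp_reps,
                                      seed = seed + 1)
      details[[length(details) + 1L]] <- cbind(
        score_result_table(sc),
        mean_n = meann[li, ri],
        power = if (include_power) power[li, ri] else NA_real_)
    }
  }
  to_df <- function(m) {
    if (is.null(m)) return(NULL)
    cbind(data.frame(lambda = lam), as.data.frame(m))
  }
  out <- list(scores = to_df(scores), mean_n = to_df(meann),
              power = to_df(power), details = do.call(rbind, details))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(out$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(out$mean_n, file.path(out_dir, "mean_n.csv"),
                     row.names = FALSE)
    if (include_power)
      utils::write.csv(out$power, file.path(out_dir, "power.csv"),
                       row.names = FALSE)
    utils::write.csv(out$details, file.path(out_dir, "details.csv"),
                     row.names = FALSE)
    manifest <- list(
      name = config$name, seed = config$seed, n_sim = config$n_sim,
      cp_reps = config$cp_reps, p_C = config$p_C,
      lambda_grid = config$lambda_grid, rules = names(rules),
      fixed_ref = config$fixed_ref,
      package_version = as.character(utils::packageVersion("cpscore")),
      r_version = R.version.string
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
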