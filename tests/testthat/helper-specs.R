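# Shared fixtures: the two standard evaluation settings, built once per run.
# Local levels are pre-solved here so individual tests skip the root solve.

main_levels <- pocock_levels(sqrt(50), sqrt(50), 0.025)

main_design <- function() {
  design_spec(n1 = 50, n_max = 200,
              alpha1 = main_levels[["alpha1"]],
              alpha12 = main_levels[["alpha12"]])
}

apsac_design <- function() {
  design_spec(n1 = 90, n_max = 270,
              alpha1 = main_levels[["alpha1"]],
              alpha12 = main_levels[["alpha12"]])
}

all_rules <- function(gamma = 0.005 / 4) {
  list(
    OCP       = rule_spec("OCP"),
    restrOCP  = rule_spec("restrOCP"),
    promising = rule_spec("promising"),
    optfunc   = rule_spec("optfunc", gamma = gamma),
    classicGS = rule_spec("classicGS")
  )
}
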