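# cpscore

Evaluation of sample size recalculation rules in two-stage adaptive
clinical trials with **binary endpoints**, using a conditional performance
score.

## The problem

Adaptive two-stage designs let a trial stop early for futility or efficacy
at an interim analysis, or continue with a recalculated second-stage sample
size. Which recalculation rule to use is a real design decision: rules
differ not only in power and expected sample size but in how *variable*
the recalculated sample size and the conditional power are. This package
scores rules on exactly those four dimensions, conditionally on the interim
outcomes where recalculation actually happens.

For a binary endpoint the pooled normal approximation test statistic
$$Z = \sqrt{n/2}\,\frac{\bar X_I - \bar X_C}{\sqrt{\bar p(1-\bar p)}}$$
has asymptotic law $N(\lambda\sqrt{n/2},\, 1-\lambda^2/4)$ indexed by the
single standardized treatment effect
$$\lambda = \frac{p_I - p_C}{\sqrt{\tfrac{p_I+p_C}{2}(1-\tfrac{p_I+p_C}{2})}},$$
so every performance measure can be presented as a curve in one effect
parameter rather than a surface in $(p_I, p_C)$.

The conditional performance score combines, with equal weights, location
and variation components of the observed conditional power and of the total
per-group sample size, each normalized to $[0,1]$ against explicit target
values (the fixed-design sample size and target power when attainable
within $n_{max}$, else the first-stage size and the significance level):
$$S = \tfrac14 l_{CP} + \tfrac14 v_{CP} + \tfrac14 l_N + \tfrac14 v_N.$$

Implemented recalculation rules: classic group sequential (constant),
observed conditional power (OCP), restricted OCP, promising zone, and an
optimization-function rule trading conditional power against sample size.
Interim statistics are simulated from their exact Bernoulli distribution;
Pocock-type local levels for the inverse normal combination test are solved
numerically at construction time.

## Worked example

Score the group sequential rule against the OCP rule at standardized effect
0.25 (control event rate 30%, i.e. intervention rate 42%), in the standard
setting with 50 patients per group at interim and at most 200:

```r
library(cpscore)

design <- design_spec(n1 = 50, n_max = 200)   # solves alpha1 = alpha12 = 0.0147
effect <- effect_spec(lambda = 0.25, p_C = 0.3)
effect
#> Binary-endpoint effect: p_I = 0.4200, p_C = 0.3000, lambda = 0.2500

conditional_score(effect, design, rule_spec("classicGS"), n_sim = 10000, seed = 1)
#> Conditional performance score: S = 0.700 (classicGS, lambda = 0.250)
#>   components: l_CP = 0.712, v_CP = 0.424, l_N = 0.667, v_N = 1.000
#>   targets: CP 0.025, N 50 (fallback branch); 7296 conditional trials

conditional_score(effect, design, rule_spec("OCP"), n_sim = 10000, seed = 1)
#> Conditional performance score: S = 0.388 (OCP, lambda = 0.250)
#>   components: l_CP = 0.555, v_CP = 0.346, l_N = 0.155, v_N = 0.494
#>   targets: CP 0.025, N 50 (fallback branch); 7296 conditional trials
```

At this effect a fixed design with 80% power would need more patients than
the cap of 200 per group, so the score targets fall back to the
significance level and the first-stage size ("fallback branch"). The
constant rule wins mainly on the sample-size components: its stage-2 size
never varies (`v_N = 1`), while the OCP rule pushes most trials to the cap
(`l_N = 0.155`) with high variability (`v_N = 0.494`).

The global view for the same OCP run:

```r
records <- run_design(effect, design, rule_spec("OCP"), n_sim = 10000, seed = 1)
mean_sample_size(records)
#> per_group     total
#>  142.4707  284.9414
global_power(records, cp_reps = 500, seed = 2)
#> [1] 0.5510878
```

So the OCP rule spends on average 142 patients per group for 55% global
power at this effect — information the score's conditional perspective
complements rather than replaces.

The command-line tool wraps the same machinery:

```sh
Rscript exec/cpscore --preset main --out results/         # full main grid
Rscript exec/cpscore --preset apsac --no-power --out results-apsac/
Rscript exec/cpscore --config my_run.yaml --n-sim 2000 --seed 7 --out results/
```

writing `scores.csv`, `mean_n.csv`, `power.csv`, `details.csv` and a JSON
manifest (rows are effect sizes, columns are rules).

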