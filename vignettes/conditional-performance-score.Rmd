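---
title: "Scoring sample size recalculation rules for binary endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sample size recalculation rules for binary endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpscore)
```

## The problem

A two-stage adaptive trial compares an intervention with a control on a
binary endpoint (event probabilities $p_I$, $p_C$, equal per-group sizes,
one-sided alternative $p_I > p_C$). After $n_1$ patients per group an
interim analysis may stop the trial for futility or efficacy; otherwise the
second-stage sample size is *recalculated* from the interim data. Many
recalculation rules exist, and they trade power, expected sample size, and
the *variability* of both in different ways. This package implements a
conditional performance score that puts those trade-offs on a single 0–1
scale, restricted to the interim outcomes where recalculation actually
happens — the natural conditioning when the object of interest is the
recalculation rule itself.

## Test statistic and its one-parameter law

Both stages use the pooled normal approximation test,
$$Z = \sqrt{n/2}\;\frac{\bar X_I - \bar X_C}
       {\sqrt{\bar p(1-\bar p)}},\qquad \bar p = \tfrac{1}{2}(\bar X_I + \bar X_C).$$
Its asymptotic distribution depends on $(p_I, p_C)$ only through the
standardized treatment effect
$$\lambda = \frac{p_I - p_C}{\sqrt{\tfrac{p_I+p_C}{2}\bigl(1-\tfrac{p_I+p_C}{2}\bigr)}},
\qquad Z \sim N\!\left(\lambda\sqrt{n/2},\; 1 - \lambda^2/4\right).$$
$|\lambda| \le 2$ always, and for fixed $\lambda$ the law — and hence every
performance measure built on it — is essentially independent of the
particular $p_C$. `lambda_from_proportions()`, `effect_from_lambda()` and
`effect_spec()` convert between the two parameterizations (the conversion is
a quadratic in the risk difference; the root sharing the sign of $\lambda$
is unique and round-trips exactly). The approximation is good down to
surprisingly small per-group sizes; the test suite verifies mean and
variance against exact Bernoulli simulation for $n_1 = 10, 20, 50, 90$.

Because the variance $1 - \lambda^2/4$ is at most 0.09 below 1 for the
effect sizes of practical interest ($\lambda \le 0.6$), results closely
track those for normally distributed endpoints with standardized effect
$\Delta = \lambda$.

## The two-stage design

Stagewise statistics $Z_1$ (size $n_1$) and $Z_2$ (size $N_{rec}$) are
combined with the inverse normal combination test,
$Z_{1+2} = (w_1 Z_1 + w_2 Z_2)/\sqrt{w_1^2 + w_2^2}$, with pre-fixed weights
(default $w_1 = w_2 = \sqrt{n_1}$, mirroring equal stage sizes of the group
sequential reference). The null hypothesis is rejected when
$Z_1 \ge q_{1-\alpha_1}$ or $Z_{1+2} \ge q_{1-\alpha_{1+2}}$; Pocock-type
equal local levels $\alpha_1 = \alpha_{1+2}$ are solved on construction of a
`design_spec` so that the global one-sided level $\alpha$ holds under the
asymptotic bivariate normal law of $(Z_1, Z_{1+2})$ with correlation
$w_1/\sqrt{w_1^2+w_2^2}$. The bivariate tail probability is evaluated by
one-dimensional quadrature of the conditional normal CDF
(`stats::integrate`, relative tolerance `1e-10`) and the level solved by
root bracketing to better than `1e-8`; for the default weights and
$\alpha = 0.025$ this gives $\alpha_1 = \alpha_{1+2} = 0.0147$.

Futility stopping is *binding* and strict: the trial stops when
$Z_1 < q_{1-\alpha_0}$ (default $\alpha_0 = 0.5$, boundary 0) and never
tests at stage two. The recalculation area is the half-open interval
$[q_{1-\alpha_0},\, q_{1-\alpha_1})$; boundary values belong to
recalculation on the left and efficacy on the right.

Note the binary-endpoint caveat: the boundaries are asymptotic, so the
realized type I error rate depends on $n_1$ and the event rates. The test
suite checks empirically (exact Bernoulli simulation at $n_1 = 50$,
$p_C = 0.3$) that the realized level does not exceed the nominal one beyond
Monte-Carlo slack.

## Recalculation rules

Within the recalculation area each rule maps the interim statistic $z_1$ —
through the observed standardized effect
$\hat\lambda = z_1/\sqrt{n_1/2}$ — to a stage-2 per-group size
$N_{rec} \in [1, n_{max}-n_1]$. The shared primitive is the observed
conditional power
$$CP_{\hat\lambda}(z_1, n_2) = 1-\Phi\!\left(
  \frac{\tfrac{\sqrt{w_1^2+w_2^2}}{w_2} q_{1-\alpha_{1+2}}
        - \tfrac{w_1}{w_2} z_1 - \hat\lambda\sqrt{n_2/2}}
       {\sqrt{1-\hat\lambda^2/4}}\right),$$
and its closed-form inversion in $n_2$ (`invert_cp_for_n2()`), which is
exact because the expression is strictly monotone in $n_2$ for
$\hat\lambda > 0$ — a round-trip identity the tests verify to `1e-9`.

* **classicGS** — constant $N_{rec} = n_{ini}$ (default $n_1$): the group
  sequential reference.
* **OCP** — smallest $n_2$ reaching conditional power $1-\beta$ (default
  0.8) under $\hat\lambda$; ceiling, then clamped to $[1, n_{max}-n_1]$.
  An unattainable target ($\hat\lambda \le 0$, or a requirement beyond the
  cap) yields the cap.
* **restrOCP** — as OCP, but if even $n_{max}-n_1$ gives conditional power
  below $1-\beta_0^{restr}$ (default $0.6$) the trial stops at interim.
  Such stops are retained in the conditional evaluation set with total size
  $n_1$ and conditional power 0: the score conditions on the interim zone,
  not on continuation.
* **promising** — conditional power $c$ at the group-sequential size
  classifies the interim result: unfavourable ($c < 1-\beta_0^{prom}$,
  default threshold 0.36) and favourable ($c > 1-\beta$) keep $n_{ini}$;
  the promising zone in between applies OCP.
* **optfunc** — maximizes $f(m) = CP_{\hat\lambda}(z_1, m) - \gamma(m -
  n_{ini})$ over integer $m \in [n_{ini},\, n_{max}-n_1]$ by exhaustive
  scan, ties toward the smaller size. The grid is floored at the initially
  planned group-sequential size: the rule prices *additional* patients
  against conditional power gain and never shrinks the planned stage below
  it. (An unfloored variant that can fall to $m = 1$ was considered and
  rejected: it changes the conditional sample-size distribution
  substantially and no longer reproduces the reference behaviour of this
  rule family.) The default trade-off $\gamma = 0.005/4$; a natural
  calibration is the per-patient power gain of the fixed design at its
  target size, $\gamma = Pow_\lambda(n_{fix}) - Pow_\lambda(n_{fix}-1)$,
  which gives $\gamma = 0.0022$ in the mortality-trial preset.

Degenerate interim data (all events or no events in both groups) have zero
pooled variance; $Z$ and $\hat\lambda$ are then defined as 0 — no evidence
either way — which keeps every rule total.

## The conditional performance score

Conditioning on the recalculation area, the score combines four components,
each in $[0,1]$, with weights defaulting to $1/4$:
$$S = \tfrac14 l_{CP} + \tfrac14 v_{CP} + \tfrac14 l_N + \tfrac14 v_N,$$
$$l_{CP} = 1-\frac{|E[CP]-CP_{t}|}{1-\alpha},\quad
  v_{CP} = 1-\sqrt{\frac{Var(CP)}{1/4}},\quad
  l_{N} = 1-\frac{|E[N]-N_{t}|}{n_{max}-n_1},\quad
  v_{N} = 1-\sqrt{\frac{Var(N)}{((n_{max}-n_1)/2)^2}}.$$
The targets depend on whether a fixed design with power $1-\beta$ is
feasible within $n_{max}$: if $\lambda > 0$ and $n_{fix}(\lambda) \le
n_{max}$, the targets are $(1-\beta,\, n_{fix}(\lambda))$ with
$$n_{fix}(\lambda) = \left(\sqrt2\,\frac{q_{1-\alpha_{1+2}}}{\lambda}
  + q_{1-\beta}\sqrt{\frac{2}{\lambda^2}-\frac12}\right)^2$$
(rounded up); otherwise they fall back to $(\alpha,\, n_1)$. Variances are
population variances (divide by $n$) for a fixed, reproducible convention.
Components are clipped to $[0,1]$: the location numerators can in principle
exceed the nominal maximal deviation, and clipping enforces the component
range by contract.

Two details were genuinely open and are fixed as follows:

* The score distributions are those of the *observed* conditional power
  $CP_{\hat\lambda}$, not the true-parameter conditional power — the score
  evaluates what the trialist can see at interim.
* $n_{fix}$ inside the targets uses the local final-analysis quantile
  $q_{1-\alpha_{1+2}}$ by default, as the formula above is written. Near
  the branch point (main setting, $\lambda \approx 0.3$, where
  $n_{fix} \approx 201$ against $n_{max} = 200$) the choice between
  $\alpha_{1+2}$ and the plain $\alpha$ flips the target branch and visibly
  moves the score; both conventions are exposed via
  `score_targets(..., n_fix_level =)` so the discontinuity can be examined
  rather than hidden.

## Simulation design

`run_design()` draws the interim statistic from its *exact* distribution
(per-group Bernoulli samples pushed through the test statistic), not from
the asymptotic law — for binary data the difference is visible, e.g. the
atom at $Z_1 = 0$. The default outer simulation size is $n_{sim} =
10{,}000$ trials; the conditional summaries then carry Monte-Carlo standard
errors of roughly 0.003 on the score.

Global measures average over *all* interim outcomes: mean per-group sample
size (stopped trials contribute $n_1$) and global power
$$Pow = \frac{1}{N_{sim}}\sum_i\Bigl[\mathbf 1\{Z_{1,i} \ge q_{1-\alpha_1}\}
  + \mathbf 1\{\text{continue}\}\; CP_\lambda(Z_{1,i}, N_{rec,i})\Bigr],$$
where the true conditional power of each continuing trial is itself
estimated by simulating stage-2 Bernoulli data (default 1000 replicates per
trial; an asymptotic closed form is available as a fast alternative).
Inner-simulation seeds are derived from the master seed by a counter, so
changing the inner size never perturbs the interim draws.

## What the generator emulates — and what it does not

The simulation reproduces the idealized trial world in which the score is
defined: exact Bernoulli endpoint data, equal group sizes, immediate and
complete observation of every patient at the interim analysis, and
recalculation driven solely by the observed standardized effect. Real
trials add overrunning, dropout, delayed responses, unequal allocation,
estimation error in $p_C$ at the planning stage, and non-binding behaviour
around futility boundaries — none of which are modelled. Passing tests
therefore certify the score machinery and the rules' behaviour under their
own assumptions, not the operating characteristics of any particular real
trial.

## Numerical choices

* Local-level root solve: bracketing on $[\alpha/2, \alpha]$ with
  `extendInt = "upX"`, tolerance `1e-10`; residual checked below `1e-7`.
* Sample sizes integerized by ceiling (conservative); stage-2 minimum 1
  when continuing, so no zero-information stages.
* Ties in the optimization rule go to the smaller sample size.
* Boundary conventions: futility strict (`<`), efficacy closed (`>=`);
  restrOCP stops on strict `<`; the promising zone is closed on both sides.
* `|lam_hat| = 2` (all-or-nothing interim data): conditional power becomes
  a 0/1 step by the sign of the numerator.

## Presets and reproduction

`preset("main")` encodes the reference evaluation setting ($n_1 = 50$,
$n_{max} = 200$, $\alpha = 0.025$, $\alpha_0 = 0.5$, $p_C = 0.3$, target
conditional power 0.8, thresholds as above, $\gamma = 0.005/4$, effect grid
$\lambda = 0, 0.05, \dots, 0.6$). `preset("apsac")` encodes a mortality
trial of thrombolytic therapy re-imagined as an adaptive design: assumed
mortality 4% vs 12% ($\lambda = -0.295$; group roles are swapped for
analysis since the treatment lowers a harmful endpoint, giving
$\lambda = 0.295$), $n_1 = 90$, $n_{max} = 270$, $\gamma = 0.0022$, and a
fixed-design reference of 180 patients per arm for 80% power at one-sided
2.5%.

```{r, eval = FALSE}
cfg <- preset("main")
res <- run_and_report(cfg, out_dir = "main-results")
res$scores   # rows lambda, columns rule
```

At the default sizes the full main grid (13 effects, 5 rules, global power
included) is an hour-scale computation; set `include_power = FALSE` for the
score-only tables (minutes), or reduce `n_sim` / `cp_reps` for exploration.
The package's own checks run the score pipeline at $n_{sim} = 10{,}000$
for selected cells and the global-power bound at $\lambda = 0.1$, which
completes in a few minutes on one core.

## Known limitations

* All boundaries and conditional-power formulas are asymptotic; with small
  $n_1$ or extreme event rates the realized type I error can deviate from
  the nominal level (it is simulated, not controlled exactly).
* Only two stages, equal allocation, binding futility, and the five rules
  above; no error-spending boundaries, no Bayesian or fixed-effect interim
  estimation.
* The score's interpretation is relative: it ranks rules under a common
  design; absolute values have no free-standing meaning.
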