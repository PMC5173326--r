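# pubcanon

Publication bias and the canonization of scientific claims.

`pubcanon` models how a scientific community comes to accept a repeatedly
tested claim as fact — or discard it as false — when positive results are
published more readily than negative ones. It is aimed at metascience and
biostatistics researchers studying the file-drawer problem, the replication
crisis, and editorial policy: it answers questions like *how often is a
false claim canonized as fact when negative results are published at 10% of
the positive rate?* and *does raising the evidentiary bar help?*

## The model

A claim is either true or false. Each experiment on it yields a positive
result with probability 1 − β (true claim) or α (false claim); positive
results are published at rate ρ₁ (fixed at 1), negative results at rate
ρ₀ ≤ ρ₁. Conditional on publication, a test of a true claim reports a
positive outcome with probability

    ωT = (1 − β) ρ₁ / ((1 − β) ρ₁ + β ρ₀),

and of a false claim with probability

    ωF = α ρ₁ / (α ρ₁ + (1 − α) ρ₀).

Readers update a shared belief q that the claim is true from published
results only, *assuming no publication bias*: each published positive moves
the log odds of belief by d₁ = ln((1 − β)/α) > 0, each published negative by
d₀ = ln(β/(1 − α)) < 0. Belief therefore performs a biased random walk on
the log-odds scale, absorbed when it exceeds the canonization standard τ₁
(the claim becomes fact) or falls below the rejection standard τ₀. The
package computes first-passage (canonization/rejection) probabilities
exactly, by dynamic programming over the lattice of (publications,
positives), truncated when the undecided mass is at most ε = 10⁻⁴.

Two extensions: p-hacking is modeled by letting the *actual* false positive
rate α_act exceed the nominal α that readers use for updating, and a
belief-linked publication policy makes the negative publication rate rise
with current belief, ρ₀(q) = ρ_b + q(1 − ρ_b) — contradicting a
well-established claim is itself publishable.

## Worked example

A false claim tested with α = 0.05, β = 0.4, negative results published at
10% of the positive rate, strict evidentiary standards (τ₀ = 0.001,
τ₁ = 0.999), prior belief 0.5:

```r
library(pubcanon)
params <- model_params(alpha = 0.05, beta = 0.4, rho0 = 0.1, q0 = 0.5,
                       tau0 = 0.001, tau1 = 0.999)
absorption_probabilities(params, truth = "false")
#> Absorption probabilities (false claim)
#>   canonized as fact: 0.857902
#>   rejected as false: 0.142002
#>   undecided (residual): 9.65e-05 after k* = 148 publications
```

Despite a 5% false positive rate and a demanding standard of evidence, the
false claim becomes "fact" 86% of the time: the published record is so
dominated by (false) positives that belief drifts upward on average. The
Monte-Carlo simulator agrees:

```r
estimate_absorption(params, "false", n_reps = 10000, seed = 1)
#> Monte-Carlo absorption estimate (false claim, n = 10000)
#>   canonized 0.8536 (SE 0.0035)
#>   rejected  0.1464 (SE 0.0035)
#>   ...
```

How much negative publication would defuse the claim? The smallest ρ₀ (on a
0.01 grid) at which canonization of the false claim becomes less likely
than not:

```r
threshold_rho0(params)          # 0.15  (p_canonize = 0.486 there)
```

— negative results need to be published at roughly 15–20% of the positive
rate before a false claim of this kind is more likely rejected than
canonized. For scale, in a well-known registry of antidepressant trials,

```r
published_rate_ratio(37, 38, 3, 24)   # 12.84 (%)
```

negative trials were published as such at scarcely more than a tenth of the
positive rate — below that threshold.

Sweeps over ρ₀, the prior q₀, symmetric standards (τ₀, 1 − τ₀), drift
curves, ROC curves, and belief-linked policies are available through
`sweep_rho0()`, `sweep_q0()`, `sweep_tau()`, `drift_curve()`, `roc_curve()`,
`dynamic_policy_sweep()`, and a command-line driver
(`inst/cli/pubcanon.R`) writes them to CSV with JSON parameter sidecars.
See the vignette (`vignettes/canonization-model.Rmd`) for the model's
assumptions and numerical choices.

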