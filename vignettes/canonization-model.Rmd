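---
title: "How publication bias canonizes false facts: the model behind pubcanon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How publication bias canonizes false facts: the model behind pubcanon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubcanon)
```

## The process being modeled

A single claim is repeatedly tested by a research community. Each
experiment produces a positive result with probability $1-\beta$ if the
claim is true and $\alpha$ if it is false. Results then pass through an
editorial filter: positives are published at rate $\rho_1$, negatives at
rate $\rho_0$. Unpublished results vanish — they never reach readers.
Conditional on publication, a test of a true claim reports a positive with
probability
$$\omega_T = \frac{(1-\beta)\rho_1}{(1-\beta)\rho_1 + \beta\rho_0},$$
and of a false claim with probability
$$\omega_F = \frac{\alpha\rho_1}{\alpha\rho_1 + (1-\alpha)\rho_0}.$$
Only the ratio $\rho_0/\rho_1$ enters these laws, so the package fixes
$\rho_1 = 1$ by default and reads $\rho_0$ as a relative rate. Values
$\rho_0 > \rho_1$ are accepted but flagged (`grey`), since a regime where
negatives are *more* publishable than positives is unusual.

Readers hold a communal belief $q$ that the claim is true. Crucially, they
update it from the published record **as if there were no publication
bias**: after $y$ positives among $k$ published results,
$$\ln\frac{q_k(y)}{1-q_k(y)} = \ln\frac{q_0}{1-q_0} + y\,d_1 + (k-y)\,d_0,
\qquad d_1 = \ln\frac{1-\beta}{\alpha},\quad d_0 = \ln\frac{\beta}{1-\alpha}.$$
Belief is thus a random walk on the log-odds scale with a positive step per
published positive and a negative step per published negative. The walk is
absorbed at the evidentiary standards: above $\tau_1$ the claim is
canonized as fact, below $\tau_0$ it is rejected. The bias-aware posterior
(`informed_posterior()`), which replaces the outcome rates by $\omega_T$
and $\omega_F$, is provided for comparison; it coincides with the naive one
exactly when $\rho_0 = \rho_1$.

The expected log-odds drift per published result,
$d_1\omega + d_0(1-\omega)$ with $\omega$ the truth-appropriate published
positive probability, organizes most of the model's behavior: a false claim
with positive drift is carried toward canonization on average, and
`drift_zero_rho0()` returns the closed-form $\rho_0^* = s\rho_1(1-\omega^*)
/ ((1-s)\omega^*)$ (with $\omega^* = -d_0/(d_1-d_0)$ and $s$ the raw
positive rate) at which the drift changes sign.

## Exact absorption probabilities

`absorption_probabilities()` computes first-passage probabilities without
simulation. After $k$ publications the undecided ("interior") states are
the $y$ with $q_k(y) \in [\tau_0, \tau_1]$; their probability mass is
propagated one publication at a time ($y \to y+1$ with probability
$\omega$, $y \to y$ otherwise), and mass landing beyond a standard at step
$k$ is banked in the first-passage series $\varphi_k$. Iteration stops at
the horizon $k^\star$, the first $k$ at which the undecided mass is at most
$\varepsilon$ ($10^{-4}$ by default); the residual is reported as
`p_undecided`, never folded into either absorbing probability, so
`p_canonize + p_reject + p_undecided` is 1 to machine precision.

Numerical choices worth knowing:

* **All comparisons happen in log odds.** The product form of the
  posterior underflows ($\beta^k$) by $k$ of a few hundred; the log-odds
  lattice is exact. Threshold comparisons use an absolute tie tolerance of
  $10^{-12}$, and a state *exactly at* a standard counts as interior — the
  undecided band is the closed interval $[\tau_0, \tau_1]$. Strict
  inequality is required for absorption.
* **A prior outside the band** ($q_0 > \tau_1$ or $q_0 < \tau_0$) is
  treated as immediate absorption at $k^\star = 0$ rather than an error,
  which keeps prior sweeps total.
* **Termination** is guaranteed by a safety cap (default $10^5$
  publications); reaching it with undecided mass above $\varepsilon$
  raises a diagnosable non-convergence error reporting the residual. In
  practice $k^\star$ is a few dozen to a few hundred: the interior band
  spans only $(\mathrm{logit}\,\tau_1 - \mathrm{logit}\,\tau_0)/(d_1-d_0)$
  lattice columns, so each step costs a handful of multiplications.
* `expected_publications()` is the mean of the truncated first-passage
  distribution and is flagged as a lower bound.

### Publication policies

The constant policy publishes negatives at the fixed rate $\rho_0$. The
belief-linked policy makes negative results easier to publish against
established claims: $\rho_0(q) = \rho_b + q(1-\rho_b)$, rising from the
baseline $\rho_b$ to 1 as belief grows. The step probability then depends
on the *source* state's belief — the belief held before the new
publication decides whether the negative is published. The model leaves
the before/after choice open; evaluating at the source state is the
natural reading and keeps the chain Markov on $(k, y)$. With $\rho_b = 1$
the policy degenerates to the unbiased constant policy, which the tests
use as a consistency check.

### P-hacking

Questionable research practices are modeled by an *actual* false positive
rate $\alpha_{\mathrm{act}} \ge \alpha$: experiments on false claims come
up positive at $\alpha_{\mathrm{act}}$ (so $\omega_F$ uses it), while
readers keep updating with the nominal $\alpha$ (so $d_1, d_0$ do not
change). `alpha_act` defaults to `alpha`, making the base model the
$\alpha_{\mathrm{act}} = \alpha$ special case of a single code path.
Validation rejects $\alpha \ge 1-\beta$ (and likewise for
$\alpha_{\mathrm{act}}$): such a test is uninformative or perverse and
would silently flip the sign of $d_1$.

## The Monte-Carlo simulator

`simulate_trajectory()` and `estimate_absorption()` replay the process
literally: draw an experiment, draw its publication, update belief only on
publication. Experiment and publication are separate Bernoulli events —
equivalent in law to drawing published outcomes directly from $\omega$,
but it lets unpublished experiments be counted (`n_experiments`,
`mean_experiments`). Because the simulator shares no code with the exact
recursion beyond the parameter algebra, it serves as an independent check:
the test suite compares the two within three binomial standard errors at
$10^5$ trajectories across base, p-hacked, and belief-linked parameter
sets.

Reproducibility: trajectory $i$ of an ensemble runs on its own substream
seeded deterministically from the root seed ($\texttt{seed} + i - 1$,
reduced mod $2^{31}-2$), so ensembles are reproducible and independent of
evaluation order. Capped trajectories (the default cap is $10^6$
experiments) are reported as their own outcome category, never silently
folded into canonize/reject. The simulator requires $\rho_0, \rho_1 \le 1$
— there they are per-result probabilities, not relative rates.

## Sweeps and default grids

The sweep functions (`sweep_rho0()`, `sweep_q0()`, `sweep_tau()`,
`roc_curve()`, `drift_curve()`, `dynamic_policy_sweep()`) run the exact
engine per grid point and return tidy data frames with the parameter
snapshot attached. Defaults: $\rho_0$ and $\rho_b$ on
$\{0.01, 0.02, \dots, 1\}$, $q_0$ on $\{0.02, \dots, 0.98\}$ — fine enough
to resolve the step-like discontinuities in the $q_0$ sweeps, which are
real features (the number of net positives needed to cross a standard is
an integer), at a cost of seconds per sweep. `threshold_rho0()` reports a
grid point, not an interpolated root, and attaches the grid step so
comparisons are honest about resolution; its default probability level is
0.5, reading "likely to be canonized" as "more likely than not".

Behaviors the sweeps expose, each locked in by a test:

* false-claim canonization is monotone nonincreasing in $\rho_0$;
* true claims are canonized with probability $> 0.99$ under strict
  standards ($\tau_0 = 0.001$, $\tau_1 = 0.999$) at any $\rho_0 \in (0,1]$
  for $\alpha = 0.05$, $\beta = 0.2$;
* when false positives are common and negatives rarely published
  ($\alpha = 0.25$, $\rho_0 = 0.1$), *stricter* standards increase false
  canonization — the longer evidence-gathering phase gives the
  positive-biased record more time to accumulate;
* the belief-linked policy with baseline $\rho_b$ never canonizes false
  claims more than the constant policy at $\rho_0 = \rho_b$, point for
  point across $\alpha \in \{0.05,\dots,0.25\}$, $\beta \in \{0.2, 0.4\}$
  and both standard regimes.

## What the tests do and do not show

All inputs here are synthetic: the model generates its own publication
trajectories. The test suite demonstrates internal correctness (exact
engine vs. closed-form gambler's-ruin arithmetic on symmetric lattices,
vs. one-step enumeration, vs. an independent simulator) and the
qualitative phenomena above. It does not estimate $\alpha$, $\beta$ or
$\rho_0$ from any real literature; the one empirical touchpoint is the
registered-trial worked example (`published_rate_ratio(37, 38, 3, 24)`,
about 12.8%), which is plain arithmetic on published counts. Real
literatures violate several assumptions on purpose kept simple here: one
claim at a time, identical error rates across labs, a single shared
belief, and no correlation between experiments.

Problem sizes used by the checked examples — $10^5$ trajectories for the
simulator-vs-engine comparisons, $0.01$-step grids for sweeps, $4000$ to
$6000$ trajectories for distributional checks — were chosen once as
desk-scale settings that make binomial standard errors small relative to
the effects asserted.

## Known limitations

* Absorption probabilities are truncated at $\varepsilon$; quantities
  derived from the first-passage series inherit that bias (flagged where
  reported).
* Asymmetric standards ($\tau_1 \ne 1 - \tau_0$) are fully supported
  numerically but have no closed-form cross-check in the suite.
* The belief-linked policy assumes the linear form $\rho_b + q(1-\rho_b)$;
  other monotone links would need a one-line extension of
  `rho0_effective()`.
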