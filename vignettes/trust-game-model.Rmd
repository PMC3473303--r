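---
title: "The clinical-trial trust game: model, thresholds and probabilistic sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The clinical-trial trust game: model, thresholds and probabilistic sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trustgame)
```

## The model and its assumptions

The package models the decision to enroll in a randomized controlled trial
(RCT) as a single-play trust variant of the prisoner's dilemma. The patient
moves first: **trust** (consent, accepting vulnerability) or **no trust**
(take the standard treatment). The researcher then either **honors** the
trust — enrolls the patient in the RCT, where randomization assigns the
experimental arm with probability `r` — or **abuses** it, administering the
promising but unproven experimental treatment outside the trial. The
patient holds a subjective probability `p` that trust will be honored.

Assumptions baked into the algebra and enforced by the validators:

* Utilities are on a common scale (0–100 by default; any finite common
  scale with `allow_negative = TRUE`). Treatment success beats failure for
  each player and arm: `u1 ≥ u3 ≥ u2, u4` and `v1 ≥ v2`, `v1 ≥ v3 ≥ v4`.
* `v2 ≥ u2`: a failed experimental arm still yields knowledge, so the
  researcher's utility for experimental failure is not below the
  patient's.
* The game is played once; no state is carried between `solve_game()`
  calls and no repeated-game dynamics are modelled.
* Regret is outcome-based: a fraction `R` of the utility difference
  between the retrospectively best action and the obtained outcome,
  subtracted on failure branches only. Under no-trust the reference is
  experimental success (`u1 − u4`); under abused trust it is standard
  success (`u3 − u2`). The same fraction is used for both branches by
  default — they plausibly differ, so `psych_params()` accepts a separate
  `regret_abuse`. Process-based regret (regret about *how* the decision
  was made) is out of scope.
* Guilt is a fraction `G` of the researcher–patient utility gap
  `v2 − u2`, subtracted from the researcher's payoff only when an abused
  patient's experimental treatment fails.

`evaluate_tree_bruteforce()` re-derives every strategy value by enumerating
tree leaves (path probability × adjusted leaf payoff) and is kept free of
the closed-form algebra; the test suite holds the two routes to within
1e−9 on a thousand random scenarios.

## Parameters and defaults

All parameters are dimensionless; probabilities and psych fractions live in
[0, 1], utilities on the 0–100 elicitation scale.

| parameter | default | meaning |
|---|---|---|
| `u1`..`u4` | 90, 16.3, 84, 16.9 | patient utilities (exp. success/failure, std. success/failure), elicited from experienced investigators |
| `v1`..`v4` | 95, 54, 70, 44 | researcher utilities, same outcome order |
| `e`, `s` | 0.41, 0.59 | success probabilities of experimental and standard treatment, from a 50-year meta-analytic estimate of cancer RCTs |
| `r` | 0.5 | randomization probability to the experimental arm |
| `p` | 0.5 | probability the researcher honors trust |
| `R`, `G` | 0.2, 0.2 | regret and guilt fractions |

`baseline_scenario()` returns exactly this set; the bundled
`inst/extdata/table1_baseline.yaml` is its on-disk form (it carries
comments on two transcription oddities in the published source table: a
patient standard-success range printed as "50–1100", read as 50–100, and a
contingency-table row total printed as 50.2% where its cells sum to
59.2%).

## Thresholds and strategy regions

Both players' decisions are affine in one probability each, so thresholds
are closed-form:

* `researcher_randomization_threshold()` solves `E[Honor] ≥ E[Abuse]` for
  `r`: `r* = 1 − (1−e)G(v2−u2)/(E_V[Exp]−E_V[Std])`. At the baseline,
  `r* ≈ 0.612`: honoring needs at least 61% randomization to the
  experimental arm. With `G = 0` the only honor incentive is `r = 1`.
* `patient_trust_threshold()` solves the affine inequality in `p`. At the
  baseline `p* ≈ 0.922`.

Design choices where the algebra is degenerate:

* When `E_V[Exp] = E_V[Std]` the inequality no longer involves `r`; the
  solver reports the sentinel `always`/`never` by the sign of the guilt
  term instead of dividing by zero.
* When the patient's slope in `p` is zero (e.g. `r = 1` with no
  abuse-branch regret) the same sentinels are used. A strictly negative
  slope has a genuine interior solution of the opposite sense and is
  reported as `less_than` — the same two-sided convention the researcher
  threshold needs — rather than forced into a sentinel.
* Thresholds are reported unrounded and clamped to [0, 1], keeping the
  pre-clamp value; display rounding to whole percent happens only in
  `print()` and the CLI.
* Strategy comparison uses exact IEEE double comparison with ties resolved
  toward cooperation (trust, honor), matching the weak inequalities of the
  threshold derivations. No epsilon band: the model is algebraic, not
  iterative, so equal expected values arise only from exactly degenerate
  inputs.

The equipoise inset model (both players share utilities 100/0, no
psychology) reduces to `r = s/(s+e)`: the randomization weight that
balances the expected benefit drawn from each arm, exactly 0.5 under
equipoise `e = s`. The printed form of this equation in the published
source is typographically corrupted; `s/(s+e)` is the unique simple form
consistent with its stated value of 0.5 at `e = s`, and the test suite
cross-checks it against a root-finding re-derivation.

`sweep_2d()` evaluates the game on an axis-aligned grid of any two of
`e, s, r, p, regret, guilt` ("regret" moves both regret branches together).
The default 101 × 101 grid resolves one-percentage-point features such as
the 61% threshold; the per-cell choices are computed by the same vectorised
algebra as `solve_game()` and spot-checked against it cell-by-cell in the
tests.

## The Monte Carlo engine and what it does (not) show

`default_mc_config()` encodes the elicited uncertainty:

* all eight utilities: triangular at their (mode, low, high) — e.g.
  `u1 ~ tri(90; 50, 100)`, `v2 ~ tri(54; 10, 100)`;
* `e ~ Binomial(450, 0.41)/450` and `s ~ Binomial(316, 0.59)/316`:
  sampling error of the meta-analytic success-rate estimates at their
  source denominators (sd ≈ 0.023 and 0.028);
* `r ~ tri(0.5; 0.2, 0.8)`; `regret, guilt ~ tri(0.2; 0, 1)`;
* `p ~ Uniform(0, 1)`. The source states only a 0–1 range with no
  distribution for `p`, unlike every other sampled row; an uninformative
  uniform is the default and `p_dist` overrides it (e.g.
  `dist_triangular(0.5, 0, 1)`).

Each of 100,000 trials draws the fourteen parameters (as full vectors in a
fixed, documented order from one seeded stream, so runs reproduce across
platforms), determines each player's best strategy by the same
expected-value comparisons as `solve_game()`, and tabulates the 2×2
honor/abuse × trust/no-trust table. Utility draws that violate the payoff
orderings (e.g. a sampled `u3 < u2`) are accepted as-is by default, since
rejection would distort the elicited marginal distributions;
`enforce_payoff_invariants = TRUE` resamples them. The 0.2–0.8 annotations
on `e` and `s` are treated as the deterministic sensitivity-analysis range,
not truncation bounds on the binomial draws (whose spread makes truncation
irrelevant); probabilities are always clamped to [0, 1]. No
variance-reduction or quasi-random sequences are used.

What the simulation emulates is *parameter* uncertainty around a stylized
encounter. It does not emulate real enrollment data: utilities come from a
small convenience elicitation, success rates from one research field, and
the psychological fractions are modelling constructs without direct
measurement. Passing tests therefore demonstrate internal consistency of
the model and reproducibility of its published solution — not that real
patients or researchers behave this way.

## Known divergences from the published analysis

Two published numbers do not follow from the printed model and inputs, and
the package deliberately reproduces the model rather than the numbers:

* The published text quotes a patient trust threshold of "≥ 67%", but
  direct evaluation of the trust inequality at the baseline gives
  `p* ≈ 0.92` (0.67 would require a regret fraction near 0.4). The solver
  follows the algebra; the 67% figure is not reproduced.
* The published 100,000-trial contingency table (honor 40.8%, trust
  68.9%, joint 18.9%) is not recoverable from the printed distribution
  set: under it, this engine finds honor ≈ 49.5%, trust ≈ 38.3%, joint
  ≈ 16.0% (seed-stable to ±0.4 points). The joint cooperation proportion
  agrees to within about three points; the marginals do not. Plausible
  p-distributions and success-rate ranges were examined without finding a
  set that matches all three, so the discrepancy is documented rather
  than calibrated away — the published analysis was run in a spreadsheet
  whose exact sampling and comparison logic is not recoverable.

## Problem sizes and numerical choices

The test suite runs 1,000-scenario oracle comparisons, 51–101-point
threshold and sweep grids, and Monte Carlo runs of 10³–10⁵ trials (about
1.3 million total draws for the sampling-error scaling check) — sizes
chosen so the full suite completes in well under a minute while leaving
sampling error far below every tolerance asserted. Triangular sampling
uses the analytic inverse CDF; binomial-proportion draws use `rbinom`.
All computation is double precision with no iterative numerics anywhere.

## Limitations

Single clinical scenario (trial vs off-trial experimental treatment);
outcome-based regret only; no broader constructs of trust (virtue,
goodwill, institutional trust); no repeated play or mixed-strategy
equilibria beyond the expected-value comparisons; two-player interaction
without third parties (regulators, sponsors). These match the scope of the
model the package implements.
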