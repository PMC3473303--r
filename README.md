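# trustgame

Decision analysis of clinical-trial participation as a trust game.

Enrollment in a randomized controlled trial (RCT) is an interaction built on
trust: the patient decides whether to put themselves in a vulnerable
position (**trust** a researcher, or take the established **standard
treatment**), and the researcher decides whether to **honor** that trust
(enroll and randomize the patient) or **abuse** it (give the promising but
unproven experimental treatment outside the trial). `trustgame` implements
this single-play trust variant of the prisoner's dilemma for ethicists,
trial methodologists and decision modellers, with closed-form expected
utilities, threshold and two-way sensitivity analysis, and a seeded Monte
Carlo probabilistic-sensitivity engine.

## Model

Each outcome carries a utility on a common 0–100 scale: `u1`–`u4` for the
patient and `v1`–`v4` for the researcher (experimental success/failure,
standard success/failure), with `u1 ≥ u3 ≥ u2, u4`, `v1 ≥ v2`, `v1 ≥ v3 ≥ v4`
and `v2 ≥ u2` (society gains knowledge even from a failed trial arm). With
success probabilities `e` (experimental) and `s` (standard), randomization
probability `r` and honoring probability `p`, the per-arm expectations are

    E_U[Exp] = e·u1 + (1−e)·u2        E_U[Std] = s·u3 + (1−s)·u4

(and analogously `E_V[·]` for the researcher). The strategy values are

    E[Honor]   = r·E_V[Exp] + (1−r)·E_V[Std]
    E[Abuse]   = E_V[Exp] − (1−e)·G·(v2 − u2)                (guilt G)
    E[NoTrust] = E_U[Std] − (1−s)·R·(u1 − u4)                (regret R)
    E[Trust]   = p·[r·E_U[Exp] + (1−r)·E_U[Std]]
               + (1−p)·[E_U[Exp] − (1−e)·R·(u3 − u2)]

Regret subtracts a fraction `R` of the retrospectively lost utility on
failure branches; guilt subtracts a fraction `G` of the researcher–patient
utility gap when an abused patient's experimental treatment fails. In the
symmetric equipoise model (success utility 100, failure 0, no regret or
guilt) the rational randomization probability is `r = s/(s+e)`, i.e. exactly
50% under genuine equipoise (`e = s`).

## Worked example

```r
library(trustgame)
sc <- baseline_scenario()   # elicited utilities, e = 0.41, s = 0.59, r = p = 0.5, R = G = 0.2
solve_game(sc)
#> Trust-game solution: table1_baseline
#>   patient:    NO_TRUST (E[Trust] = 45.016 vs E[No Trust] = 50.495)
#>   researcher: ABUSE    (E[Honor] = 65.075 vs E[Abuse] = 66.361)
```

At the baseline, mutual defection is individually rational: the patient's
expected utility is higher outside the trial (50.5 vs 45.0) and the
researcher's is higher giving the experimental treatment off-trial
(66.4 vs 65.1) — even though both would prefer a world of full cooperation.

```r
researcher_randomization_threshold(sc)
#> Threshold on randomization probability r: researcher honors when r >= 0.6122 (61%)
patient_trust_threshold(sc)
#> Threshold on honoring probability p: patient trusts when p >= 0.9223 (92%)
```

Honoring becomes rational for the researcher only when at least 61% of
participants would be randomized to the experimental arm; the patient needs
to believe the researcher honors trust with probability ≥ 92% before
trusting beats the standard treatment.

Propagating the elicited uncertainty in all fourteen parameters:

```r
run_monte_carlo(default_mc_config(n_trials = 100000, seed = 1))
#> Monte Carlo trust-game analysis (100,000 trials, seed 1)
#>       trust no_trust  total
#> honor 15995    33491  49486
#> abuse 22324    28190  50514
#> total 38319    61681 100000
#>   honor marginal 49.5% | trust marginal 38.3% | joint honor & trust 16.0%
```

Full cooperation (honor ∧ trust) is the rational profile in about 16% of
sampled worlds. See the methods vignette
(`vignettes/trust-game-model.Rmd`) for the model's assumptions, the
distribution set behind the simulation and known divergences from the
published analysis.

## Command line

```sh
inst/cli/trustgame solve --config builtin:table1_baseline
inst/cli/trustgame thresholds --out thresholds.json
inst/cli/trustgame sweep --x e --y s --steps 101 --out grid.csv
inst/cli/trustgame mc --trials 100000 --seed 1 --out mc.json
```

Each command is deterministic given its flags and seed, and `--out` writes a
JSON run manifest alongside the output.

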