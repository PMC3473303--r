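# Baseline scenario for the clinical-trial trust game.
# Utilities are on the 0-100 scale; outcome order per player is
# (experimental success, experimental failure, standard success,
# standard failure).
#
# Notes on the published source table this file transcribes:
#   - the patient's standard-success range is printed as "(50-1100)";
#     read here as (50-100), a transcription typo;
#   - the Monte Carlo table's no-trust/abuse row total is printed as
#     "50.2%" where its cells sum to 59.2% (59,222/100,000).
label: table1_baseline
payoffs:
  u1: 90.0     # patient, experimental success (range 50-100)
  u2: 16.3     # patient, experimental failure (range 0-50)
  u3: 84.0     # patient, standard success (range 50-100)
  u4: 16.9     # patient, standard failure (range 0-50)
  v1: 95.0     # researcher, experimental success (range 80-100)
  v2: 54.0     # researcher, experimental failure (range 10-100)
  v3: 70.0     # researcher, standard success (range 40-80)
  v4: 44.0     # researcher, standard failure (range 0-80)
probabilities:
  e: 0.41      # experimental-treatment success
  s: 0.59      # standard-treatment success
  r: 0.5       # randomization to the experimental arm
  p: 0.5       # researcher honors trust
psych:
  regret: 0.2  # fraction of lost utility felt on failure branches
  guilt: 0.2   # fraction of the researcher-patient gap felt under abuse
# Probabilistic-sensitivity distributions (the `mc` command uses these when
# present; identical to the package default).
distributions:
  u1: {kind: triangular, mode: 90.0, low: 50.0, high: 100.0}
  u2: {kind: triangular, mode: 16.3, low: 0.0, high: 50.0}
  u3: {kind: triangular, mode: 84.0, low: 50.0, high: 100.0}
  u4: {kind: triangular, mode: 16.9, low: 0.0, high: 50.0}
  v1: {kind: triangular, mode: 95.0, low: 80.0, high: 100.0}
  v2: {kind: triangular, mode: 54.0, low: 10.0, high: 100.0}
  v3: {kind: triangular, mode: 70.0, low: 40.0, high: 80.0}
  v4: {kind: triangular, mode: 44.0, low: 0.0, high: 80.0}
  # "n" must be quoted: bare n is a YAML 1.1 boolean
  e: {kind: binomial_proportion, p0: 0.41, "n": 450}
  s: {kind: binomial_proportion, p0: 0.59, "n": 316}
  r: {kind: triangular, mode: 0.5, low: 0.2, high: 0.8}
  p: {kind: uniform, low: 0.0, high: 1.0}
  regret: {kind: triangular, mode: 0.2, low: 0.0, high: 1.0}
  guilt: {kind: triangular, mode: 0.2, low: 0.0, high: 1.0}
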