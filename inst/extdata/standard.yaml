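# Standard parameter preset for the protocell protometabolism model.
#
# Branch fractions, the fixation-catalysis constant KCN, and the nucleotide
# synthesis constants KNE/KNN are the standard simulation values; the
# remaining entries are this package's documented calibration:
#   * k_fix = log(2)/lambda_aa1 = 2.4579687253898772 per day, so the null
#     model (k_cn = k_nn = 0, all k_in = 0) divides exactly 1.0 times/day;
#   * fa_div = 10 x the initial fatty-acid count;
#   * vol_per_fa = 0.1 puts nucleotide synthesis in the substrate-limited
#     regime (the energy currency is ~97% consumed at the null steady state).
preset: standard
params:
  lambda: {fa: 0.376, aa1: 0.282, aa2: 0.282, s: 0.05, e: 0.01}
  k_fix: 2.4579687253898772
  co2: 1.0
  k_cn: 1000.0
  k_in: {fa: 0.0, aa1: 0.0, aa2: 0.0, s: 0.0, e: 0.0}
  k_sat: 1.0
  k_ne: 2.0
  k_nn: 2.0
  alpha: 0.0
  n_c2: {fa: 1, aa1: 1, aa2: 1, s: 1, e: 1}
  vol_per_fa: 0.1
  fa_div: 10000.0
  init: {fa: 1000.0, aa1: 750.0, aa2: 750.0, s: 130.0, e: 30.0, "n": 0.0}
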