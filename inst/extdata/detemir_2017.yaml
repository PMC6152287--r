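# Default simulation scenario: obese type-2 diabetics under six months of
# insulin detemir (40 paired patients) plus 27 healthy controls.
# Marginal moments are the published per-group summaries: mean/sd for
# symmetric parameters, median/quartiles (lognormal family) for the skewed
# ones.  Pairwise correlation targets are the published pooled Pearson
# coefficients; the 0.95 "twin" entries encode the structurally forced
# near-complete correlations (weight-BMI, waist-hips, the two WHRs,
# total-LDL cholesterol, insulin-HOMA-IR).  Cross-terms such as
# weight-leptin are the PSD-consistent products of a twin correlation with
# a printed target (0.95 * r); without them the assembled matrix has a
# negative eigenvalue and the repair would perturb the printed targets.
name: detemir_2017
n_diabetic: 40
n_healthy: 27
fraction_female: 0.5
within_patient_r: 0.8
marginals:
  - {index: 1,  healthy: {mean: 84.4,  sd: 22.4},  baseline: {mean: 94.9,   sd: 14.6},  month6: {mean: 95.2,  sd: 15.4}}
  - {index: 2,  healthy: {mean: 30.63, sd: 5.4},   baseline: {mean: 34.18,  sd: 5.43},  month6: {mean: 34.4,  sd: 5.5}}
  - {index: 3,  healthy: {mean: 100.0, sd: 15.3},  baseline: {mean: 112.7,  sd: 11.4},  month6: {mean: 111.2, sd: 10.2}}
  - {index: 4,  healthy: {mean: 105.6, sd: 15.9},  baseline: {mean: 112.6,  sd: 11.4},  month6: {mean: 111.5, sd: 10.6}}
  - {index: 5,  healthy: {mean: 0.95,  sd: 0.1},   baseline: {mean: 0.9995, sd: 0.049}, month6: {mean: 1.001, sd: 0.06}}
  - {index: 6,  healthy: {mean: 0.95,  sd: 0.1},   baseline: {mean: 0.9995, sd: 0.049}, month6: {mean: 1.003, sd: 0.06}}
  - {index: 7,  healthy: {mean: 5.17,  sd: 0.45},  baseline: {mean: 7.87,   sd: 1.4},   month6: {mean: 7.78,  sd: 0.89}}
  - {index: 8,  healthy: {mean: 192.3, sd: 34.5},  baseline: {mean: 196.4,  sd: 36.1},  month6: {mean: 188.8, sd: 30.3}}
  - {index: 9,  healthy: {mean: 46.8,  sd: 8.76},  baseline: {mean: 49.5,   sd: 13.6},  month6: {mean: 48.1,  sd: 12.9}}
  - {index: 10, healthy: {mean: 115.7, sd: 28.6},  baseline: {mean: 111.4,  sd: 32.9},  month6: {mean: 99.1,  sd: 29.9}}
  - {index: 11, healthy: {mean: 145.7, sd: 60.7},  baseline: {mean: 176.8,  sd: 88.4},  month6: {mean: 182.5, sd: 68.5}}
  - {index: 12, healthy: {mean: 0.84,  sd: 0.09},  baseline: {mean: 0.834,  sd: 0.528}, month6: {mean: 0.993, sd: 0.86}}
  - {index: 13, healthy: {median: 2.5,  q1: 2.5,  q3: 4.3},    baseline: {median: 4.3,  q1: 2.5,  q3: 15.5},  month6: {median: 2.5,  q1: 2.5,  q3: 8.4}}
  - {index: 14, healthy: {mean: 90.85, sd: 7.3},   baseline: {mean: 155.3,  sd: 45.2},  month6: {mean: 150.6, sd: 33.01}}
  - {index: 15, healthy: {median: 10.6, q1: 4.7,  q3: 23.8},   baseline: {median: 11.4, q1: 4.5,  q3: 25.6},  month6: {median: 16.0, q1: 7.6,  q3: 29.9}}
  - {index: 16, healthy: {median: 1.29, q1: 0.5,  q3: 2.4},    baseline: {median: 2.0,  q1: 1.2,  q3: 3.9},   month6: {median: 2.5,  q1: 1.6,  q3: 3.8}}
  - {index: 17, healthy: {median: 77.6, q1: 41.1, q3: 189.5},  baseline: {median: 50.7, q1: 25.8, q3: 86.8},  month6: {median: 40.2, q1: 26.4, q3: 63.9}}
  - {index: 18, healthy: {median: 98.8, q1: 70.6, q3: 171.0},  baseline: {median: 53.5, q1: 32.0, q3: 92.9},  month6: {median: 71.9, q1: 41.6, q3: 92.2}}
  - {index: 19, healthy: {mean: 56.9,  sd: 21.4},  baseline: {mean: 44.3,   sd: 16.4},  month6: {mean: 51.9,  sd: 18.9}}
  - {index: 20, healthy: {mean: 21.1,  sd: 10.8},  baseline: {mean: 39.0,   sd: 16.2},  month6: {mean: 39.6,  sd: 18.4}}
  - {index: 21, healthy: {mean: 9.01,  sd: 3.7},   baseline: {mean: 6.8,    sd: 4.2},   month6: {mean: 8.4,   sd: 4.6}}
correlations:
  default_r: 0.0
  targets:
    # structurally forced near-complete pairs, all groups
    - {i: 1,  j: 2,  r: 0.95,  groups: [healthy, baseline, month6]}
    - {i: 3,  j: 4,  r: 0.95,  groups: [healthy, baseline, month6]}
    - {i: 5,  j: 6,  r: 0.95,  groups: [healthy, baseline, month6]}
    - {i: 8,  j: 10, r: 0.95,  groups: [healthy, baseline, month6]}
    - {i: 15, j: 16, r: 0.95,  groups: [healthy, baseline, month6]}
    # published pooled correlations, untreated diabetics
    - {i: 2,  j: 20, r: 0.56,  groups: [baseline]}
    - {i: 19, j: 20, r: -0.55, groups: [baseline]}
    - {i: 2,  j: 19, r: -0.60, groups: [baseline]}
    - {i: 7,  j: 19, r: -0.32, groups: [baseline]}
    # published pooled correlations, after six months of therapy
    - {i: 2,  j: 20, r: 0.45,  groups: [month6]}
    - {i: 19, j: 20, r: -0.53, groups: [month6]}
    - {i: 2,  j: 19, r: -0.45, groups: [month6]}
    # PSD-consistent cross-terms induced by the weight-BMI twin
    - {i: 1,  j: 20, r: 0.532,  groups: [baseline]}
    - {i: 1,  j: 19, r: -0.57,  groups: [baseline]}
    - {i: 1,  j: 20, r: 0.4275, groups: [month6]}
    - {i: 1,  j: 19, r: -0.4275, groups: [month6]}
gender_effects:
  # multiplicative female-to-male ratios, applied mean- and SD-preservingly
  # (two-point mixture).  The leptin 2.0 anchor is applied in the healthy
  # group; in the diabetic groups the multipliers are kept mild so the
  # published pooled correlations above survive the gender mixture.
  - {index: 20, multiplier: 2.0,  groups: [healthy]}
  - {index: 20, multiplier: 1.15, groups: [baseline, month6]}
  - {index: 21, multiplier: 1.3,  groups: [healthy, month6]}
  - {index: 19, multiplier: 0.9,  groups: [month6]}
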