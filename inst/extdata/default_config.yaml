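# Default pipeline configuration: two-genotype synthetic study emulating
# an APPPS1-like (model_A) and an App-NL-G-F-like (model_B) amyloidosis
# cohort. Coverage values are percent of field area; the signal model is
# z = intercept + b_fibrillar*F + b_nonfibrillar*N + age_slope*age + h_i + eps.
seed: 1
n_boot: 1000
bootstrap_unit: row        # row | pet-mouse
ihc_aggregate: mouse       # mouse | mean
age_matched: false         # pooled wild-type z-scoring by default
validation_fibrillar_shift: 0.5

wt_suvr_mean: 1.0
wt_suvr_sd: 0.05
n_wt: 8

truth:
  b_fibrillar: 3.17        # z-units per % fibrillar coverage
  b_nonfibrillar: 0.20     # z-units per % nonfibrillar coverage
  intercept: 0.0
  age_slope: 0.25          # z-units per month
  heterogeneity_sd: 0.8    # persistent mouse-level intercept, z-units
  residual_sd: 0.3         # per-scan residual, z-units

profiles:
  model_A:
    ages: [3, 6, 12]
    total_mean: [1.5, 5.0, 16.0]
    total_sd: [0.25500000000000000, 0.85000000000000009, 2.72000000000000020]
    fibrillar_fraction_mean: [0.33333333333333331, 0.40000000000000002, 0.25000000000000000]
    fibrillar_fraction_sd: [0.080138768534475394, 0.083282651254628054, 0.073612159321677292]
    n_pet_mice: 14
    n_ihc_per_age: [4, 3, 4]
    longitudinal_enrollment: 0.56
    reference_region: white-matter
  model_B:
    ages: [3, 6, 12]
    total_mean: [4.0499999999999998, 7.2000000000000002, 10.5000000000000000]
    total_sd: [0.6885000000000000, 1.2240000000000002, 1.7850000000000001]
    fibrillar_fraction_mean: [0.012345679012345680, 0.027777777777777780, 0.047619047619047616]
    fibrillar_fraction_sd: [0.018771928699998237, 0.027937043420192632, 0.036203005349996598]
    n_pet_mice: 18
    n_ihc_per_age: [4, 3, 4]
    longitudinal_enrollment: 0.56
    reference_region: periaqueductal-gray
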