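# Small in-code fixtures shared across test files.

make_pet_df <- function() {
  data.frame(
    mouse_id = c("m1", "m1", "m2"),
    genotype = c("model_A", "model_A", "model_A"),
    age_months = c(3, 6, 3),
    suvr = c(1.2, 1.4, 1.1),
    reference_region = "white-matter",
    stringsAsFactors = FALSE)
}

make_wt_df <- function(suvr = c(0.9, 1.0, 1.1)) {
  data.frame(
    mouse_id = paste0("wt", seq_along(suvr)),
    genotype = "wild_type",
    age_months = 3,
    suvr = suvr,
    reference_region = "white-matter",
    stringsAsFactors = FALSE)
}

make_ihc_df <- function() {
  data.frame(
    mouse_id = c("i1", "i2", "i3"),
    genotype = "model_A",
    age_months = c(3, 3, 6),
    total_area_pct = c(5.0, 4.0, 6.0),
    fibrillar_area_pct = c(1.2, 4.0, 2.0),
    stringsAsFactors = FALSE)
}

# Noiseless study configuration: zero coverage dispersion, zero PET noise.
noiseless_config <- function(seed = 1, age_slope = 0, intercept = 0) {
  sim_config(profiles = default_profiles(rel_sd = 0),
             truth = ground_truth(intercept = intercept, age_slope = age_slope,
                                  heterogeneity_sd = 0, residual_sd = 0),
             seed = seed)
}

# Simulate + z-score + pair in one step.
pipeline_pairs <- function(config) {
  ihc <- generate_ihc(config)
  scans <- generate_pet(config)
  pet_z <- compute_z(scans$pet, scans$wt)
  list(pairs = build_pairs(pet_z, ihc), ihc = ihc, pet_z = pet_z,
       scans = scans)
}

# Independent least-squares oracle: SVD pseudoinverse of the design.
pinv_coefficients <- function(X, y) {
  s <- svd(X)
  drop(s$v %*% ((t(s$u) %*% y) / s$d))
}
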