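test_that("generation is deterministic in the seed and varies across seeds", {
  cfg1 <- sim_config(seed = 11)
  cfg1b <- sim_config(seed = 11)
  cfg2 <- sim_config(seed = 12)
  expect_identical(generate_ihc(cfg1), generate_ihc(cfg1b))
  expect_identical(generate_pet(cfg1), generate_pet(cfg1b))
  expect_false(identical(generate_ihc(cfg1), generate_ihc(cfg2)))
  expect_false(identical(generate_pet(cfg1)$pet, generate_pet(cfg2)$pet))
})

test_that("zero-dispersion cohorts collapse to the profile means", {
  cfg <- noiseless_config(seed = 5)
  ihc <- generate_ihc(cfg)
  lat <- profile_latent_means(cfg)
  merged <- merge(ihc, lat, by = c("genotype", "age_months"),
                  suffixes = c("", "_latent"))
  expect_equal(merged$fibrillar_area_pct, merged$fibrillar_area_pct_latent,
               tolerance = 1e-12)
  expect_equal(merged$nonfibrillar_area_pct, merged$nonfibrillar_area_pct_latent,
               tolerance = 1e-12)

  # zero fibrillar fraction puts all coverage in the nonfibrillar pool
  p <- genotype_profile("diffuse_only", total_mean = c(1, 2, 3), total_sd = 0.1,
                        fibrillar_fraction_mean = c(0, 0, 0),
                        fibrillar_fraction_sd = 0, n_pet_mice = 4,
                        n_ihc_per_age = 2)
  cfg0 <- sim_config(profiles = list(p), seed = 2)
  expect_true(all(generate_ihc(cfg0)$fibrillar_area_pct == 0))
})

test_that("noiseless PET z-scores equal the linear signal model exactly", {
  cfg <- noiseless_config(seed = 3)
  scans <- generate_pet(cfg)
  pet_z <- compute_z(scans$pet, scans$wt)
  lat <- profile_latent_means(cfg)
  merged <- merge(pet_z, lat, by = c("genotype", "age_months"))
  tr <- cfg$truth
  expect_equal(merged$z,
               tr$b_fibrillar * merged$fibrillar_area_pct +
                 tr$b_nonfibrillar * merged$nonfibrillar_area_pct,
               tolerance = 1e-8)
})

test_that("wild-type z-scores have mean 0 and unit variance by construction", {
  cfg <- sim_config(seed = 9)
  scans <- generate_pet(cfg)
  wtz <- compute_z(scans$wt, scans$wt)
  for (rr in unique(wtz$reference_region)) {
    zz <- wtz$z[wtz$reference_region == rr]
    expect_equal(mean(zz), 0, tolerance = 1e-10)
    expect_equal(sd(zz), 1, tolerance = 1e-10)
  }
})

test_that("default profiles reproduce the study's coverage orderings", {
  lat <- profile_latent_means(sim_config(seed = 1))
  a <- lat[lat$genotype == "model_A", ]
  b <- lat[lat$genotype == "model_B", ]
  a <- a[order(a$age_months), ]
  b <- b[order(b$age_months), ]
  # diffuse model leads on nonfibrillar coverage early, is overtaken at 12 mo
  expect_true(all(b$nonfibrillar_area_pct[1:2] > a$nonfibrillar_area_pct[1:2]))
  expect_true(a$nonfibrillar_area_pct[3] > b$nonfibrillar_area_pct[3])
  # compact model leads on fibrillar coverage at every age
  expect_true(all(a$fibrillar_area_pct > b$fibrillar_area_pct))
})

test_that("longitudinal enrollment splits baseline ages as configured", {
  cfg <- sim_config(seed = 4)
  pet <- generate_pet(cfg)$pet
  for (p in cfg$profiles) {
    sub <- pet[pet$genotype == p$label, ]
    n_baseline <- length(unique(sub$mouse_id[sub$age_months == p$ages[1]]))
    expect_equal(n_baseline, round(p$n_pet_mice * p$longitudinal_enrollment))
    expect_equal(length(unique(sub$mouse_id)), p$n_pet_mice)
    # every mouse is measured at all its enrolled ages
    late <- unique(sub$mouse_id[sub$age_months == p$ages[2]])
    expect_equal(length(late), p$n_pet_mice)
  }
})

test_that("Trem2-like scenario lowers fibrillarity at unchanged total coverage", {
  base <- default_profiles(rel_sd = 0)$model_A
  shifted <- trem2_scenario(base, 0.5)
  expect_equal(shifted$fibrillar_fraction_mean,
               0.5 * base$fibrillar_fraction_mean)
  expect_equal(shifted$total_mean, base$total_mean)
  expect_match(shifted$label, "trem2ko")
  expect_error(trem2_scenario(base, 1.0), "strictly in")
  expect_error(trem2_scenario(base, 0), "strictly in")

  # at zero dispersion the generated cohort has strictly lower fibrillar
  # coverage than the base cohort at every age
  cfg <- sim_config(profiles = list(base, shifted),
                    truth = ground_truth(heterogeneity_sd = 0, residual_sd = 0),
                    seed = 8)
  ihc <- generate_ihc(cfg)
  for (a in base$ages) {
    fib_base <- mean(ihc$fibrillar_area_pct[ihc$genotype == "model_A" &
                                              ihc$age_months == a])
    fib_ko <- mean(ihc$fibrillar_area_pct[ihc$genotype == "model_A_trem2ko" &
                                            ihc$age_months == a])
    expect_lt(fib_ko, fib_base)
  }
})

test_that("profile validation rejects inconsistent configurations", {
  expect_error(genotype_profile("x", total_mean = c(3, 2, 1), total_sd = 0,
                                fibrillar_fraction_mean = c(.1, .1, .1),
                                fibrillar_fraction_sd = 0, n_pet_mice = 2,
                                n_ihc_per_age = 2),
               "nondecreasing")
  expect_error(genotype_profile("x", total_mean = c(1, 2, 3), total_sd = -1,
                                fibrillar_fraction_mean = c(.1, .1, .1),
                                fibrillar_fraction_sd = 0, n_pet_mice = 2,
                                n_ihc_per_age = 2),
               "nonnegative")
  expect_error(genotype_profile("x", total_mean = c(1, 2, 3), total_sd = 0,
                                fibrillar_fraction_mean = c(.1, .1, 1.2),
                                fibrillar_fraction_sd = 0, n_pet_mice = 2,
                                n_ihc_per_age = 2),
               "\\[0, 1\\]")
})
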