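make_pairs_df <- function(n, seed = 1, b_f = 2, b_n = 0.5, noise_sd = 0) {
  withr::with_seed(seed, {
    data.frame(
      pet_mouse_id = paste0("p", seq_len(n)),
      ihc_mouse_id = paste0("i", seq_len(n)),
      genotype = "g", age_months = sample(c(3, 6, 12), n, TRUE),
      fibrillar_area_pct = runif(n, 0, 4),
      nonfibrillar_area_pct = runif(n, 0, 12),
      heterogeneity = rnorm(n)) |>
      transform(z = b_f * fibrillar_area_pct + b_n * nonfibrillar_area_pct +
                  rnorm(n, 0, noise_sd))
  })
}

test_that("least squares interpolates a noiseless linear signal exactly", {
  pairs <- make_pairs_df(40)
  fit <- fit_ols(pairs, c("fibrillar", "nonfibrillar"))
  expect_equal(unname(fit$coefficients[c("fibrillar", "nonfibrillar")]),
               c(2, 0.5), tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-10)
})

test_that("coefficients agree with an independent pseudoinverse oracle", {
  withr::with_seed(99, {
    for (rep in 1:100) {
      n <- sample(10:50, 1)
      p <- sample(1:4, 1)
      preds <- sample(c("fibrillar", "nonfibrillar", "heterogeneity", "age"), p)
      pairs <- data.frame(
        fibrillar_area_pct = runif(n, 0, 5),
        nonfibrillar_area_pct = runif(n, 0, 15),
        heterogeneity = rnorm(n),
        age_months = sample(c(3, 6, 12), n, TRUE),
        z = rnorm(n, 0, 2))
      fit <- fit_ols(pairs, preds)
      cols <- c(fibrillar = "fibrillar_area_pct",
                nonfibrillar = "nonfibrillar_area_pct",
                heterogeneity = "heterogeneity", age = "age_months")
      X <- cbind(1, as.matrix(pairs[, cols[preds], drop = FALSE]))
      expect_equal(unname(fit$coefficients[c("(Intercept)", preds)]),
                   unname(pinv_coefficients(X, pairs$z)), tolerance = 1e-8)
    }
  })
})

test_that("degenerate designs are rejected, identically-zero covariates dropped", {
  pairs <- make_pairs_df(20)
  pairs$fibrillar_area_pct <- 2  # constant, collinear with the intercept
  expect_error(fit_ols(pairs, "fibrillar"), "singular design.*fibrillar")

  pairs2 <- make_pairs_df(20)
  pairs2$heterogeneity <- 0
  fit <- fit_ols(pairs2, c("fibrillar", "nonfibrillar", "heterogeneity"))
  expect_equal(fit$dropped, "heterogeneity")
  expect_true(is.na(fit$coefficients["heterogeneity"]))
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  expect_error(fit_ols(make_pairs_df(3), c("fibrillar", "nonfibrillar", "age")),
               "too few rows")
})

test_that("the model ladder is reported in canonical order with nested R2", {
  expect_identical(names(model_ladder()),
                   c("fibrillar", "nonfibrillar", "fibrillar x nonfibrillar",
                     "fibrillar x nonfibrillar x heterogeneity",
                     "fibrillar x nonfibrillar x heterogeneity x age"))
  pp <- pipeline_pairs(sim_config(seed = 21))
  lad <- fit_ladder(pp$pairs)
  r2 <- vapply(lad, `[[`, 0, "r2")
  # nested models: R2 nondecreasing from the two-predictor model onward
  expect_true(all(diff(r2[3:5]) >= -1e-12))
  # heterogeneity carries real signal when simulated with nonzero spread
  expect_gt(r2[4], r2[3])
  adj <- vapply(lad, `[[`, 0, "adjusted_r2")
  expect_true(all(adj <= r2 + 1e-12))
  expect_true(all(vapply(lad, function(f) abs(sum(f$residuals)) < 1e-8,
                         logical(1))))
})

test_that("ladder on noiseless data is exact for all both-predictor models", {
  pp <- pipeline_pairs(noiseless_config(seed = 2))
  lad <- fit_ladder(pp$pairs)
  for (nm in names(model_ladder())[3:5]) {
    expect_equal(lad[[nm]]$r2, 1, tolerance = 1e-10)
  }
  full <- lad[["fibrillar x nonfibrillar x heterogeneity x age"]]
  expect_equal(unname(full$coefficients["fibrillar"]), 3.17, tolerance = 1e-8)
  expect_equal(unname(full$coefficients["nonfibrillar"]), 0.20, tolerance = 1e-8)

  # a genuine age effect is recovered by the only model that carries it
  pp2 <- pipeline_pairs(noiseless_config(seed = 2, age_slope = 0.1))
  full2 <- fit_ols(pp2$pairs,
                   c("fibrillar", "nonfibrillar", "heterogeneity", "age"))
  expect_equal(unname(full2$coefficients["age"]), 0.1, tolerance = 1e-8)
  expect_equal(full2$r2, 1, tolerance = 1e-10)
})

test_that("bootstrap intervals are seed-deterministic and degenerate without noise", {
  pairs <- make_pairs_df(30, noise_sd = 0.5)
  ci1 <- bootstrap_ci(pairs, c("fibrillar", "nonfibrillar"), n_boot = 200,
                      seed = 7)
  ci2 <- bootstrap_ci(pairs, c("fibrillar", "nonfibrillar"), n_boot = 200,
                      seed = 7)
  expect_identical(ci1$ci, ci2$ci)
  ci3 <- bootstrap_ci(pairs, c("fibrillar", "nonfibrillar"), n_boot = 200,
                      seed = 8)
  expect_false(identical(ci1$ci, ci3$ci))
  # point estimate inside the percentile interval
  fit <- fit_ols(pairs, c("fibrillar", "nonfibrillar"))
  expect_true(all(ci1$ci[, "lower"] <= fit$coefficients &
                    fit$coefficients <= ci1$ci[, "upper"]))

  exact <- make_pairs_df(30)
  ci0 <- bootstrap_ci(exact, c("fibrillar", "nonfibrillar"), n_boot = 100,
                      seed = 1)
  expect_equal(unname(ci0$ci[, "upper"] - ci0$ci[, "lower"]),
               rep(0, 3), tolerance = 1e-10)

  # resampling whole PET mice is supported
  cim <- bootstrap_ci(pairs, c("fibrillar", "nonfibrillar"), n_boot = 50,
                      seed = 2, unit = "pet-mouse")
  expect_equal(dim(cim$ci), c(3L, 2L))
})

test_that("bootstrap intervals shrink with sample size", {
  small <- make_pairs_df(130, seed = 5, noise_sd = 2)
  large <- make_pairs_df(520, seed = 5, noise_sd = 2)
  ci_s <- bootstrap_ci(small, c("fibrillar", "nonfibrillar"), n_boot = 300,
                       seed = 3)
  ci_l <- bootstrap_ci(large, c("fibrillar", "nonfibrillar"), n_boot = 300,
                       seed = 3)
  w <- function(ci) ci$ci["fibrillar", "upper"] - ci$ci["fibrillar", "lower"]
  expect_lt(w(ci_l), w(ci_s))
})

test_that("coefficient synthesis reproduces the published headline numbers", {
  tab <- utils::read.csv(system.file("extdata", "table1_coefficients.csv",
                                     package = "abdecomp"))
  summ <- summarize_coefficient_table(tab)
  expect_equal(round(summ$b_fib_mean, 2), 3.17)
  expect_equal(round(summ$b_nonfib_mean, 2), 0.20)
  expect_equal(round(summ$fold_ratio), 16)
  expect_equal(round(unname(summ$fold_range)), c(11, 26))

  bad <- tab
  bad$b_nonfibrillar <- c(0.1, -0.1)
  expect_error(summarize_coefficient_table(bad), "undefined fold ratio")
})
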