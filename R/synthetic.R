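# Truncated-normal draws by inverse-CDF; sd = 0 collapses to the
# (clamped) mean so noiseless configurations are exactly degenerate.
rtnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Define a genotype simulation profile
#'
#' Describes one amyloidosis genotype for the synthetic-cohort generator:
#' per-age means and SDs of total plaque area coverage and of the
#' fibrillar fraction (fibrillar/total), the PET cohort size with its
#' longitudinal enrollment split, and the per-age IHC cohort sizes.
#'
#' @param label Genotype label.
#' @param ages Ages in months at which cohorts are examined.
#' @param total_mean,total_sd Per-age mean and SD of total area coverage
#'   (percent); means must be nondecreasing in age (amyloid accumulates).
#' @param fibrillar_fraction_mean,fibrillar_fraction_sd Per-age mean and
#'   SD of the fibrillar fraction, in \[0, 1\].
#' @param n_pet_mice Number of PET mice followed longitudinally.
#' @param n_ihc_per_age Per-age number of cross-sectional IHC mice.
#' @param longitudinal_enrollment Fraction of PET mice whose baseline scan
#'   is at the first age; the remainder enter at the second age.
#' @param reference_region PET reference-region label used for this
#'   genotype (wild-type controls are generated per region).
#' @return A `genotype_profile` list.
#' @export
genotype_profile <- function(label, ages = c(3, 6, 12),
                             total_mean, total_sd,
                             fibrillar_fraction_mean, fibrillar_fraction_sd,
                             n_pet_mice, n_ihc_per_age,
                             longitudinal_enrollment = 0.56,
                             reference_region = "white-matter") {
  k <- length(ages)
  stopifnot(length(total_mean) == k, length(fibrillar_fraction_mean) == k)
  total_sd <- rep_len(total_sd, k)
  fibrillar_fraction_sd <- rep_len(fibrillar_fraction_sd, k)
  n_ihc_per_age <- rep_len(n_ihc_per_age, k)
  if (any(total_mean < 0) || any(total_sd < 0) || any(fibrillar_fraction_sd < 0)) {
    stop("coverage means and sds must be nonnegative", call. = FALSE)
  }
  if (any(fibrillar_fraction_mean < 0 | fibrillar_fraction_mean > 1)) {
    stop("fibrillar_fraction_mean must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(total_mean)) {
    stop("total coverage means must be nondecreasing in age", call. = FALSE)
  }
  if (longitudinal_enrollment <= 0 || longitudinal_enrollment > 1) {
    stop("longitudinal_enrollment must lie in (0, 1]", call. = FALSE)
  }
  structure(list(label = label, ages = ages,
                 total_mean = total_mean, total_sd = total_sd,
                 fibrillar_fraction_mean = fibrillar_fraction_mean,
                 fibrillar_fraction_sd = fibrillar_fraction_sd,
                 n_pet_mice = n_pet_mice, n_ihc_per_age = n_ihc_per_age,
                 longitudinal_enrollment = longitudinal_enrollment,
                 reference_region = reference_region),
            class = "genotype_profile")
}

#' Default two-genotype study profiles
#'
#' Emulates the two amyloidosis models of the study design: `model_A`
#' (APPPS1-like, compact plaques, high fibrillar fraction at every age)
#' and `model_B` (App-NL-G-F-like, diffuse plaques, low fibrillar
#' fraction, nonfibrillar-dominant early). Coverage means reproduce the
#' qualitative orderings of the study: model_B nonfibrillar coverage
#' exceeds model_A at 3 and 6 months and is overtaken at 12 months, while
#' model_A fibrillar coverage exceeds model_B at every age. Between-mouse
#' dispersion is `rel_sd` of the mean for total coverage; the
#' fibrillar-fraction SD is `rel_sd * sqrt(phi * (1 - phi))`, which makes
#' the induced fibrillar and nonfibrillar coverage errors approximately
#' uncorrelated (independent variation of the two compartments).
#'
#' @param rel_sd Relative between-mouse coverage dispersion; the default
#'   puts the full-model fit on synthetic default cohorts at about 93%
#'   explained variance.
#' @return List of two `genotype_profile` objects.
#' @export
default_profiles <- function(rel_sd = 0.17) {
  # fibrillar/nonfibrillar means: A = 0.5/1, 2/3, 4/12 %; B = 0.05/4, 0.2/7, 0.5/10 %
  mk <- function(label, fib, non, n_pet, rr) {
    tot <- fib + non
    phi <- fib / tot
    genotype_profile(label, ages = c(3, 6, 12),
                     total_mean = tot, total_sd = rel_sd * tot,
                     fibrillar_fraction_mean = phi,
                     fibrillar_fraction_sd = rel_sd * sqrt(phi * (1 - phi)),
                     n_pet_mice = n_pet, n_ihc_per_age = c(4, 3, 4),
                     reference_region = rr)
  }
  list(
    model_A = mk("model_A", c(0.5, 2, 4), c(1, 3, 12), 14, "white-matter"),
    model_B = mk("model_B", c(0.05, 0.2, 0.5), c(4, 7, 10), 18,
                 "periaqueductal-gray")
  )
}

#' Generative ground truth for the PET signal model
#'
#' Coefficients of the latent linear signal model used to generate PET
#' z-scores: `z = intercept + b_fibrillar * F + b_nonfibrillar * N +
#' age_slope * age + h_i + eps`, where `F`/`N` are the stratum-latent
#' fibrillar/nonfibrillar coverages (percent), `h_i` is a persistent
#' mouse-level heterogeneity draw and `eps` per-scan residual noise.
#'
#' @param b_fibrillar,b_nonfibrillar Signal per percent area covered
#'   (z-units/%); defaults are the headline coefficient synthesis values.
#' @param intercept,age_slope Intercept (z-units) and linear age term
#'   (z-units/month).
#' @param heterogeneity_sd SD of the persistent mouse-level intercept
#'   (z-units).
#' @param residual_sd SD of per-observation residual noise (z-units).
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(b_fibrillar = 3.17, b_nonfibrillar = 0.20,
                         intercept = 0, age_slope = 0.25,
                         heterogeneity_sd = 0.8, residual_sd = 0.3) {
  stopifnot(b_fibrillar > 0, b_nonfibrillar >= 0,
            heterogeneity_sd >= 0, residual_sd >= 0)
  structure(list(b_fibrillar = b_fibrillar, b_nonfibrillar = b_nonfibrillar,
                 intercept = intercept, age_slope = age_slope,
                 heterogeneity_sd = heterogeneity_sd, residual_sd = residual_sd),
            class = "ground_truth")
}

#' Assemble a simulation configuration
#'
#' @param profiles List of [genotype_profile()] objects.
#' @param truth A [ground_truth()] object.
#' @param wt_suvr_mean,wt_suvr_sd Wild-type SUVR distribution.
#' @param n_wt Number of wild-type mice (each measured with every
#'   reference region used by the profiles, at every age).
#' @param seed Integer RNG seed; all generator randomness derives from it
#'   (deterministic sub-streams per cohort), so identical configurations
#'   regenerate identical tables.
#' @return A `sim_config` list.
#' @export
sim_config <- function(profiles = default_profiles(), truth = ground_truth(),
                       wt_suvr_mean = 1.0, wt_suvr_sd = 0.05, n_wt = 8,
                       seed = 1L) {
  stopifnot(wt_suvr_sd > 0, n_wt >= 2)
  structure(list(profiles = profiles, truth = truth,
                 wt_suvr_mean = wt_suvr_mean, wt_suvr_sd = wt_suvr_sd,
                 n_wt = n_wt, seed = as.integer(seed)),
            class = "sim_config")
}

#' Latent per-stratum coverage means implied by the profiles
#'
#' The generator's PET arm conditions on these latent means (not on the
#' finite IHC sample): fibrillar = total x fibrillar fraction,
#' nonfibrillar its complement.
#'
#' @param config A [sim_config()].
#' @return Data frame `genotype, age_months, fibrillar_area_pct,
#'   nonfibrillar_area_pct`.
#' @export
profile_latent_means <- function(config) {
  do.call(rbind, lapply(config$profiles, function(p) {
    fib <- p$total_mean * p$fibrillar_fraction_mean
    data.frame(genotype = p$label, age_months = p$ages,
               fibrillar_area_pct = fib,
               nonfibrillar_area_pct = p$total_mean - fib,
               row.names = NULL)
  }))
}

#' Generate a cross-sectional IHC cohort
#'
#' Independent mice per (genotype, age). Total coverage is drawn from a
#' normal truncated at zero with the profile mean/SD; the fibrillar
#' fraction from a normal truncated to \[0, 1\]; fibrillar coverage is
#' their product and nonfibrillar coverage the exact complement.
#'
#' @param config A [sim_config()].
#' @return IHC cohort data frame (schema of [read_cohort()] `"ihc"`, with
#'   derived `nonfibrillar_area_pct`).
#' @export
generate_ihc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    out <- do.call(rbind, lapply(config$profiles, function(p) {
      do.call(rbind, lapply(seq_along(p$ages), function(j) {
        n <- p$n_ihc_per_age[j]
        if (n == 0) return(NULL)
        total <- rtnorm(n, p$total_mean[j], p$total_sd[j], lower = 0)
        frac <- rtnorm(n, p$fibrillar_fraction_mean[j],
                       p$fibrillar_fraction_sd[j], lower = 0, upper = 1)
        data.frame(mouse_id = sprintf("%s_ihc_%gm_%02d", p$label, p$ages[j],
                                      seq_len(n)),
                   genotype = p$label, age_months = p$ages[j],
                   total_area_pct = total, fibrillar_area_pct = total * frac,
                   row.names = NULL)
      }))
    }))
  })
  if (is.null(out)) {
    out <- data.frame(mouse_id = character(), genotype = character(),
                      age_months = numeric(), total_area_pct = numeric(),
                      fibrillar_area_pct = numeric())
  }
  rownames(out) <- NULL
  validate_ihc(out)
}

#' Generate a longitudinal PET cohort and its wild-type controls
#'
#' Each amyloid-model mouse receives a persistent heterogeneity draw
#' `h_i ~ N(0, heterogeneity_sd)` applied at all its scans; its latent PET
#' z-score at each age is the linear signal model of [ground_truth()]
#' evaluated at the stratum-latent coverages, plus `h_i` and per-scan
#' residual noise. z is mapped to SUVR as `wt_suvr_mean + z * wt_suvr_sd`.
#' A `longitudinal_enrollment` fraction of mice is scanned from the first
#' age; the remainder enter at the second age. Wild-type mice are
#' generated for every reference region in use, at every age.
#'
#' @param config A [sim_config()].
#' @param latent_means Per-stratum latent coverages; defaults to
#'   [profile_latent_means()]`(config)`.
#' @return List with elements `pet` and `wt`, both PET-schema data frames.
#' @export
generate_pet <- function(config, latent_means = profile_latent_means(config)) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$truth
  withr::with_seed(config$seed + 2L, {
    pet <- do.call(rbind, lapply(config$profiles, function(p) {
      n <- p$n_pet_mice
      n_base <- round(n * p$longitudinal_enrollment)
      h <- stats::rnorm(n, 0, tr$heterogeneity_sd)
      do.call(rbind, lapply(seq_len(n), function(i) {
        ages <- if (i <= n_base) p$ages else p$ages[-1]
        lat <- latent_means[latent_means$genotype == p$label &
                              latent_means$age_months %in% ages, , drop = FALSE]
        if (nrow(lat) != length(ages)) {
          stop("missing latent stratum means for genotype '", p$label, "'",
               call. = FALSE)
        }
        lat <- lat[match(ages, lat$age_months), ]
        z <- tr$intercept + tr$b_fibrillar * lat$fibrillar_area_pct +
          tr$b_nonfibrillar * lat$nonfibrillar_area_pct +
          tr$age_slope * ages + h[i] +
          stats::rnorm(length(ages), 0, tr$residual_sd)
        data.frame(mouse_id = sprintf("%s_pet_%02d", p$label, i),
                   genotype = p$label, age_months = ages,
                   suvr = config$wt_suvr_mean + z * config$wt_suvr_sd,
                   reference_region = p$reference_region, row.names = NULL)
      }))
    }))
    regions <- unique(vapply(config$profiles, `[[`, "", "reference_region"))
    ages_all <- sort(unique(unlist(lapply(config$profiles, `[[`, "ages"))))
    wt <- do.call(rbind, lapply(regions, function(rr) {
      # Moment-matched controls: the wild-type sample is rescaled to have
      # exactly the nominal mean/SD per reference region, so the z-scale
      # estimated downstream equals the scale the z-scores were generated
      # on and the ground-truth coefficients are recoverable.
      x <- stats::rnorm(config$n_wt * length(ages_all))
      x <- config$wt_suvr_mean + config$wt_suvr_sd * (x - mean(x)) / stats::sd(x)
      data.frame(mouse_id = sprintf("wt_%02d", rep(seq_len(config$n_wt),
                                                   each = length(ages_all))),
                 genotype = "wild_type",
                 age_months = rep(ages_all, config$n_wt),
                 suvr = x, reference_region = rr, row.names = NULL)
    }))
  })
  rownames(pet) <- rownames(wt) <- NULL
  list(pet = validate_pet(pet), wt = validate_pet(wt))
}

#' Derive a Trem2-knockout-like scenario profile
#'
#' Models loss of microglial plaque compaction: the fibrillar fraction is
#' scaled down by a multiplicative factor while total plaque coverage is
#' unchanged, so nonfibrillar coverage rises one-for-one.
#'
#' @param base_profile A [genotype_profile()].
#' @param fibrillar_shift Multiplicative factor in (0, 1) applied to the
#'   per-age fibrillar-fraction means.
#' @return A new `genotype_profile` with suffixed label.
#' @export
trem2_scenario <- function(base_profile, fibrillar_shift) {
  stopifnot(inherits(base_profile, "genotype_profile"))
  if (!is.numeric(fibrillar_shift) || length(fibrillar_shift) != 1 ||
      fibrillar_shift <= 0 || fibrillar_shift >= 1) {
    stop("fibrillar_shift must lie strictly in (0, 1)", call. = FALSE)
  }
  p <- base_profile
  p$fibrillar_fraction_mean <- p$fibrillar_fraction_mean * fibrillar_shift
  p$label <- paste0(p$label, "_trem2ko")
  p
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration (seed ", x$seed, ")\n", sep = "")
  for (p in x$profiles) {
    cat(sprintf("  %s: %d PET mice, IHC n = %s at %s mo, ref region %s\n",
                p$label, p$n_pet_mice,
                paste(p$n_ihc_per_age, collapse = "/"),
                paste(p$ages, collapse = "/"), p$reference_region))
  }
  tr <- x$truth
  cat(sprintf("  truth: b_fib = %.3g, b_nonfib = %.3g, age slope = %.3g, het sd = %.3g, resid sd = %.3g\n",
              tr$b_fibrillar, tr$b_nonfibrillar, tr$age_slope,
              tr$heterogeneity_sd, tr$residual_sd))
  invisible(x)
}
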