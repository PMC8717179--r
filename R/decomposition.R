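# Pull (b_fibrillar, b_nonfibrillar, intercept, age term) out of either a
# fitted model or a coefficient summary. A summary carries no intercept or
# age term: the synthesized coefficients attribute plaque signal only.
signal_coefficients <- function(coefs) {
  if (inherits(coefs, "ab_coef_summary")) {
    c(b_fib = coefs$b_fib_mean, b_nonfib = coefs$b_nonfib_mean,
      intercept = 0, age = 0)
  } else if (inherits(coefs, "ab_fit")) {
    cf <- coefs$coefficients
    get <- function(term) if (term %in% names(cf) && !is.na(cf[term])) unname(cf[term]) else 0
    if (!"fibrillar" %in% names(cf) || !"nonfibrillar" %in% names(cf)) {
      stop("fit lacks fibrillar/nonfibrillar coefficients", call. = FALSE)
    }
    if (anyNA(cf[c("fibrillar", "nonfibrillar")])) {
      stop("missing coefficient: fibrillar/nonfibrillar not estimated",
           call. = FALSE)
    }
    c(b_fib = unname(cf["fibrillar"]), b_nonfib = unname(cf["nonfibrillar"]),
      intercept = get("(Intercept)"), age = get("age"))
  } else if (is.numeric(coefs)) {
    c(b_fib = unname(coefs["b_fib"]), b_nonfib = unname(coefs["b_nonfib"]),
      intercept = if ("intercept" %in% names(coefs)) unname(coefs["intercept"]) else 0,
      age = if ("age" %in% names(coefs)) unname(coefs["age"]) else 0)
  } else {
    stop("coefs must be an ab_fit, ab_coef_summary, or named numeric vector",
         call. = FALSE)
  }
}

#' Fibrillar / nonfibrillar contribution shares of the PET signal
#'
#' Under the linear signal model, the share of the modelled plaque signal
#' attributed to the nonfibrillar component is
#' `b_nonfib * N / (b_fib * F + b_nonfib * N)`, with the fibrillar share
#' its complement. Intercept and age terms are excluded from the
#' attribution: they are not plaque signal. Shares are undefined (NA,
#' flagged) when both components are zero, and invariant to rescaling
#' both coefficients by a common positive factor.
#'
#' @param fibrillar_area_pct,nonfibrillar_area_pct Nonnegative coverages
#'   (percent), vectorized.
#' @param coefs An `ab_coef_summary`, `ab_fit`, or named vector with
#'   `b_fib`/`b_nonfib`.
#' @return Data frame `fibrillar_share, nonfibrillar_share, undefined`.
#' @export
contribution_shares <- function(fibrillar_area_pct, nonfibrillar_area_pct, coefs) {
  stopifnot(length(fibrillar_area_pct) == length(nonfibrillar_area_pct))
  if (any(fibrillar_area_pct < 0 | nonfibrillar_area_pct < 0, na.rm = TRUE)) {
    stop("coverages must be nonnegative", call. = FALSE)
  }
  b <- signal_coefficients(coefs)
  sig_f <- b["b_fib"] * fibrillar_area_pct
  sig_n <- b["b_nonfib"] * nonfibrillar_area_pct
  denom <- sig_f + sig_n
  undef <- fibrillar_area_pct == 0 & nonfibrillar_area_pct == 0
  nf_share <- unname(ifelse(undef, NA_real_, sig_n / denom))
  data.frame(fibrillar_share = 1 - nf_share, nonfibrillar_share = nf_share,
             undefined = undef)
}

#' Genotype-level contribution shares with dispersion
#'
#' Computes per-mouse contribution shares across an IHC cohort and
#' summarizes them per genotype (pooled across ages, the default) or per
#' genotype x age. The dispersion is the sample SD of the per-mouse
#' nonfibrillar shares.
#'
#' @param ihc IHC data frame with derived `nonfibrillar_area_pct`.
#' @param coefs As in [contribution_shares()].
#' @param by `"genotype"` or `"genotype_age"`.
#' @return Data frame with mean and SD of both shares and `n`.
#' @export
cohort_shares <- function(ihc, coefs, by = c("genotype", "genotype_age")) {
  by <- match.arg(by)
  sh <- contribution_shares(ihc$fibrillar_area_pct, ihc$nonfibrillar_area_pct,
                            coefs)
  keys <- if (by == "genotype") list(genotype = ihc$genotype) else
    list(genotype = ihc$genotype, age_months = ihc$age_months)
  ok <- !sh$undefined
  agg <- stats::aggregate(sh$nonfibrillar_share[ok],
                          by = lapply(keys, `[`, ok),
                          FUN = function(x) c(mean = mean(x),
                                              sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                                              n = length(x)))
  out <- cbind(agg[setdiff(names(agg), "x")], as.data.frame(agg$x))
  names(out)[names(out) %in% c("mean", "sd", "n")] <-
    c("nonfibrillar_share_mean", "nonfibrillar_share_sd", "n")
  out$fibrillar_share_mean <- 1 - out$nonfibrillar_share_mean
  out$fibrillar_share_sd <- out$nonfibrillar_share_sd
  out$n <- as.integer(out$n)
  out
}

#' Predict a PET z-score from plaque coverage
#'
#' Applies fitted (or synthesized) regression factors to IHC coverages:
#' `z = intercept + b_fib * F [+ b_nonfib * N] [+ b_age * age]`. In
#' `"fibrillar_only"` mode the nonfibrillar term is dropped with all else
#' unchanged, so `full - fibrillar_only == b_nonfib * N` exactly.
#'
#' @param fibrillar_area_pct,nonfibrillar_area_pct Coverages (percent).
#' @param age_months Ages; required when `coefs` carries an age term.
#' @param coefs As in [contribution_shares()].
#' @param mode `"full"` or `"fibrillar_only"`.
#' @return Numeric vector of predicted z-scores.
#' @export
predict_z <- function(fibrillar_area_pct, nonfibrillar_area_pct,
                      age_months = NULL, coefs,
                      mode = c("full", "fibrillar_only")) {
  mode <- match.arg(mode)
  b <- signal_coefficients(coefs)
  z <- b["intercept"] + b["b_fib"] * fibrillar_area_pct
  if (mode == "full") z <- z + b["b_nonfib"] * nonfibrillar_area_pct
  if (b["age"] != 0) {
    if (is.null(age_months)) {
      stop("coefs include an age term: age_months is required", call. = FALSE)
    }
    z <- z + b["age"] * age_months
  }
  unname(z)
}

#' Prediction bias on an independent validation cohort
#'
#' Applies the fitted regression factors to stratum-mean IHC coverages of
#' an independent cohort and compares predicted with actual stratum-mean
#' PET z-scores, once with both plaque components and once considering
#' fibrillar coverage alone. Whether the full model is less biased is
#' reported, not assumed.
#'
#' @param val_pet_z Validation PET data frame with `z` (see
#'   [compute_z()]); wild-type rows excluded by the caller or via
#'   `wt_label`.
#' @param val_ihc Validation IHC data frame with derived
#'   `nonfibrillar_area_pct`.
#' @param coefs As in [contribution_shares()].
#' @param wt_label Wild-type genotype label to drop from the PET side.
#' @return Data frame with one row per (genotype, age) stratum:
#'   `actual_z, predicted_z_full, predicted_z_fibrillar_only,
#'   deviation_full, deviation_fibrillar_only`.
#' @export
validation_bias <- function(val_pet_z, val_ihc, coefs, wt_label = "wild_type") {
  stopifnot("z" %in% names(val_pet_z))
  val_pet_z <- val_pet_z[val_pet_z$genotype != wt_label, , drop = FALSE]
  if (!nrow(val_ihc)) stop("empty validation IHC table", call. = FALSE)
  if (!nrow(val_pet_z)) stop("empty validation PET table", call. = FALSE)
  pet_strata <- unique(paste(val_pet_z$genotype, round(val_pet_z$age_months)))
  ihc_strata <- unique(paste(val_ihc$genotype, round(val_ihc$age_months)))
  missing_strata <- setdiff(pet_strata, ihc_strata)
  if (length(missing_strata)) {
    stop("validation strata missing from IHC table: ",
         paste(missing_strata, collapse = "; "), call. = FALSE)
  }
  zbar <- stats::aggregate(list(actual_z = val_pet_z$z),
                           by = list(genotype = val_pet_z$genotype,
                                     age_months = round(val_pet_z$age_months)),
                           FUN = mean)
  cov_bar <- stats::aggregate(
    val_ihc[, c("fibrillar_area_pct", "nonfibrillar_area_pct")],
    by = list(genotype = val_ihc$genotype,
              age_months = round(val_ihc$age_months)), FUN = mean)
  out <- merge(zbar, cov_bar, by = c("genotype", "age_months"))
  out$predicted_z_full <- predict_z(out$fibrillar_area_pct,
                                    out$nonfibrillar_area_pct,
                                    out$age_months, coefs, mode = "full")
  out$predicted_z_fibrillar_only <- predict_z(out$fibrillar_area_pct,
                                              out$nonfibrillar_area_pct,
                                              out$age_months, coefs,
                                              mode = "fibrillar_only")
  out$deviation_full <- out$predicted_z_full - out$actual_z
  out$deviation_fibrillar_only <- out$predicted_z_fibrillar_only - out$actual_z
  out[order(out$genotype, out$age_months), ]
}

#' Signed gap between two genotypes' group-level regression lines
#'
#' Fits one straight line per genotype through its per-age (predictor
#' mean, z-score mean) points and integrates the vertical difference
#' between the lines over a predictor range: the signed mean gap
#' (`gap_index`, z-units, normalized by the range width) indexes the
#' bias incurred by reading PET burden off a single predictor axis; the
#' raw signed area is also returned. Crossing lines can cancel to zero
#' by design.
#'
#' @param groups_a,groups_b Data frames with columns `x` (per-age
#'   predictor mean) and `z` (per-age mean PET z-score), >= 2 rows each.
#' @param range `"intersection"` (default) or `"union"` of the two
#'   observed x-ranges.
#' @return Object of class `ab_gap`: `gap_index`, `raw_area`,
#'   `line_a`/`line_b` (intercept, slope), `x_range`.
#' @export
group_line_gap <- function(groups_a, groups_b,
                           range = c("intersection", "union")) {
  range <- match.arg(range)
  stopifnot(nrow(groups_a) >= 2, nrow(groups_b) >= 2)
  fa <- stats::coef(stats::lm(z ~ x, data = groups_a))
  fb <- stats::coef(stats::lm(z ~ x, data = groups_b))
  lo <- if (range == "intersection") max(min(groups_a$x), min(groups_b$x)) else
    min(groups_a$x, groups_b$x)
  hi <- if (range == "intersection") min(max(groups_a$x), max(groups_b$x)) else
    max(groups_a$x, groups_b$x)
  w <- hi - lo
  if (w <= 0) {
    stop("degenerate predictor range (width ", signif(w, 3),
         "): the two genotypes' x-ranges do not overlap", call. = FALSE)
  }
  d_int <- fa[1] - fb[1]
  d_slope <- fa[2] - fb[2]
  gap <- unname(d_int + d_slope * (lo + hi) / 2)  # mean of a linear gap
  structure(list(gap_index = gap, raw_area = gap * w,
                 line_a = stats::setNames(unname(fa), c("intercept", "slope")),
                 line_b = stats::setNames(unname(fb), c("intercept", "slope")),
                 x_range = c(lo, hi)),
            class = "ab_gap")
}

#' @export
print.ab_gap <- function(x, ...) {
  cat(sprintf("Group-line gap over x in [%.3g, %.3g]: %+.3f z (raw area %+.3f)\n",
              x$x_range[1], x$x_range[2], x$gap_index, x$raw_area))
  invisible(x)
}
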