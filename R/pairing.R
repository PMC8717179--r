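#' Heterogeneity covariate: deviation from the genotype x age group mean
#'
#' A mouse's heterogeneity is its PET z-score deviation from the mean
#' z-score of its own (genotype, age) stratum. It is a property of the
#' PET observation and is computed once, before pairing, so that the
#' cross-product duplication of observations across IHC partners does not
#' re-center it. Within each stratum the values sum to zero (one term per
#' distinct PET observation); a singleton stratum gets h = 0 with a
#' warning.
#'
#' @param pet_z PET data frame carrying a `z` column (see [compute_z()]).
#' @return `pet_z` with a `heterogeneity` column appended.
#' @export
compute_heterogeneity <- function(pet_z) {
  stopifnot("z" %in% names(pet_z))
  if (!nrow(pet_z)) stop("empty PET input", call. = FALSE)
  stratum <- interaction(pet_z$genotype, pet_z$age_months, drop = TRUE)
  n_per <- table(stratum)
  if (any(n_per == 1)) {
    warning("singleton stratum(s) ", paste(names(n_per)[n_per == 1], collapse = ", "),
            ": heterogeneity set to 0", call. = FALSE)
  }
  pet_z$heterogeneity <- pet_z$z - stats::ave(pet_z$z, stratum)
  pet_z
}

#' Build the individual-level paired regression design
#'
#' Enumerates every age- and genotype-matched combination of one PET
#' observation with one IHC mouse: the full cross product within each
#' (genotype, age) stratum. Strata present in only one modality contribute
#' no rows. Wild-type observations are excluded. The per-stratum pair
#' counts are attached as attribute `"stratum_counts"`.
#'
#' @param pet_z PET data frame with `z` (and optionally `heterogeneity`,
#'   computed via [compute_heterogeneity()] if absent).
#' @param ihc IHC data frame with derived `nonfibrillar_area_pct`.
#' @param ihc_aggregate `"mouse"` (default) pairs each PET observation
#'   with each individual IHC mouse; `"mean"` pairs it with the stratum
#'   mean coverages (one row per PET observation).
#' @param wt_label Genotype label identifying wild-type rows to drop.
#' @param age_tolerance Maximal |PET age - IHC age| in months treated as a
#'   match (0 = exact equality after rounding to integer months; use 1 to
#'   pair e.g. 13-month PET with 12-month IHC). When matching within a
#'   tolerance the paired record carries the IHC age.
#' @return Data frame of paired records: `pet_mouse_id, ihc_mouse_id,
#'   genotype, age_months, z, fibrillar_area_pct, nonfibrillar_area_pct,
#'   heterogeneity`.
#' @export
build_pairs <- function(pet_z, ihc, ihc_aggregate = c("mouse", "mean"),
                        wt_label = "wild_type", age_tolerance = 0) {
  ihc_aggregate <- match.arg(ihc_aggregate)
  stopifnot("z" %in% names(pet_z), "nonfibrillar_area_pct" %in% names(ihc))
  pet_z <- pet_z[pet_z$genotype != wt_label, , drop = FALSE]
  ihc <- ihc[ihc$genotype != wt_label, , drop = FALSE]
  if (!nrow(pet_z) || !nrow(ihc)) {
    stop("empty design: no non-wild-type observations to pair", call. = FALSE)
  }
  if (!"heterogeneity" %in% names(pet_z)) {
    pet_z <- compute_heterogeneity(pet_z)
  }
  if (ihc_aggregate == "mean") {
    agg <- stats::aggregate(
      ihc[, c("fibrillar_area_pct", "nonfibrillar_area_pct")],
      by = list(genotype = ihc$genotype, age_months = ihc$age_months), mean)
    agg$mouse_id <- sprintf("%s_%gm_mean", agg$genotype, agg$age_months)
    ihc <- agg
  }
  pet_age <- round(pet_z$age_months)
  ihc_age <- round(ihc$age_months)
  rows <- vector("list", nrow(pet_z))
  for (i in seq_len(nrow(pet_z))) {
    sel <- ihc$genotype == pet_z$genotype[i] &
      abs(ihc_age - pet_age[i]) <= age_tolerance
    if (!any(sel)) next
    rows[[i]] <- data.frame(
      pet_mouse_id = pet_z$mouse_id[i], ihc_mouse_id = ihc$mouse_id[sel],
      genotype = pet_z$genotype[i], age_months = ihc$age_months[sel],
      z = pet_z$z[i],
      fibrillar_area_pct = ihc$fibrillar_area_pct[sel],
      nonfibrillar_area_pct = ihc$nonfibrillar_area_pct[sel],
      heterogeneity = pet_z$heterogeneity[i], row.names = NULL)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || !nrow(pairs)) {
    stop("empty design: no (genotype, age)-matched PET-IHC combinations",
         call. = FALSE)
  }
  pairs <- pairs[order(pairs$genotype, pairs$age_months,
                       pairs$pet_mouse_id, pairs$ihc_mouse_id), , drop = FALSE]
  rownames(pairs) <- NULL
  counts <- stats::aggregate(list(n_pairs = pairs$z),
                             by = list(genotype = pairs$genotype,
                                       age_months = pairs$age_months),
                             FUN = length)
  attr(pairs, "stratum_counts") <- counts
  pairs
}
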