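#' abdecomp: decomposing the amyloid-PET signal into plaque source components
#'
#' Tools for quantifying how much of the in vivo amyloid-PET signal in
#' mouse models of cerebral amyloidosis derives from fibrillar versus
#' nonfibrillar (diffuse) beta-amyloid plaque components. The pipeline
#' z-scores PET SUV ratios against wild-type controls, pairs PET
#' observations with age- and genotype-matched immunohistochemistry (IHC)
#' estimates of plaque area coverage, fits a nested ladder of linear
#' models with bootstrap confidence intervals, and converts the fitted
#' coefficients into per-component contribution shares and prediction-bias
#' reports for independent validation cohorts. A seeded synthetic-cohort
#' generator with known ground truth supports end-to-end testing.
#'
#' @keywords internal
"_PACKAGE"

PET_COLUMNS <- c("mouse_id", "genotype", "age_months", "suvr", "reference_region")
IHC_COLUMNS <- c("mouse_id", "genotype", "age_months", "total_area_pct",
                 "fibrillar_area_pct")

#' Derive nonfibrillar plaque coverage
#'
#' Nonfibrillar (diffuse) beta-amyloid area coverage is defined as the
#' total coverage (pan-Abeta stain) minus the fibrillar coverage
#' (beta-sheet dye): exact subtraction, never clipped. Fibrillar coverage
#' exceeding total coverage is a data error, not a rounding case, and is
#' rejected.
#'
#' @param total_area_pct Percent of field area positive for the total
#'   amyloid stain, in \[0, 100\].
#' @param fibrillar_area_pct Percent of field area positive for the
#'   fibrillar stain, in \[0, 100\]; must not exceed `total_area_pct`.
#' @return Numeric vector of nonfibrillar coverage, in percent.
#' @examples
#' derive_nonfibrillar(5.0, 1.2)   # 3.8
#' @export
derive_nonfibrillar <- function(total_area_pct, fibrillar_area_pct) {
  stopifnot(is.numeric(total_area_pct), is.numeric(fibrillar_area_pct),
            length(total_area_pct) == length(fibrillar_area_pct))
  if (any(total_area_pct < 0 | total_area_pct > 100, na.rm = TRUE) ||
      any(fibrillar_area_pct < 0 | fibrillar_area_pct > 100, na.rm = TRUE)) {
    stop("area coverage must lie in [0, 100] percent", call. = FALSE)
  }
  bad <- which(fibrillar_area_pct > total_area_pct)
  if (length(bad)) {
    stop("fibrillar coverage exceeds total coverage at position(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  total_area_pct - fibrillar_area_pct
}

validate_pet <- function(df) {
  missing_cols <- setdiff(PET_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("PET table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$age_months <- as.numeric(df$age_months)
  df$suvr <- as.numeric(df$suvr)
  bad <- which(!is.finite(df$suvr) | df$suvr <= 0 |
                 !is.finite(df$age_months) | df$age_months <= 0)
  if (length(bad)) {
    stop("invalid PET row(s) (suvr and age_months must be positive): rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$mouse_id, df$age_months, df$reference_region)
  if (anyDuplicated(key)) {
    stop("duplicate (mouse_id, age_months, reference_region) in PET table: rows ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  df
}

validate_ihc <- function(df) {
  missing_cols <- setdiff(IHC_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("IHC table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("age_months", "total_area_pct", "fibrillar_area_pct")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(!is.finite(df$age_months) | df$age_months <= 0)
  if (length(bad)) {
    stop("invalid IHC row(s) (age_months must be positive): rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  over <- which(df$fibrillar_area_pct > df$total_area_pct)
  if (length(over)) {
    stop("fibrillar coverage exceeds total coverage for mouse(s) ",
         paste(unique(df$mouse_id[over]), collapse = ", "),
         " (rows ", paste(over, collapse = ", "), ")", call. = FALSE)
  }
  df$nonfibrillar_area_pct <- derive_nonfibrillar(df$total_area_pct,
                                                  df$fibrillar_area_pct)
  df
}

#' Read a cohort table
#'
#' Reads a comma-delimited cohort table with a header line. Lines starting
#' with `#` (provenance headers written by [write_cohort()]) are skipped.
#' Rows violating the schema invariants are rejected with their row
#' numbers. For the IHC schema the nonfibrillar coverage column is always
#' derived from total minus fibrillar, never read from the file.
#'
#' @param path Path to a CSV file.
#' @param schema `"pet"` (columns `mouse_id, genotype, age_months, suvr,
#'   reference_region`) or `"ihc"` (columns `mouse_id, genotype,
#'   age_months, total_area_pct, fibrillar_area_pct`).
#' @return A data frame of validated observations; IHC tables gain a
#'   derived `nonfibrillar_area_pct` column.
#' @export
read_cohort <- function(path, schema = c("pet", "ihc")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  switch(schema, pet = validate_pet(df), ihc = validate_ihc(df))
}

#' Write a cohort table with a provenance header
#'
#' Writes a cohort table as CSV preceded by a single `#` comment line
#' recording provenance (free-form key=value pairs, typically the
#' generator parameters and seed). [read_cohort()] skips this line.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param provenance Named character/numeric vector recorded in the header
#'   comment, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path, provenance = NULL) {
  header <- "# written by abdecomp"
  if (!is.null(provenance)) {
    header <- paste0(header, "; ",
                     paste(names(provenance), unlist(provenance),
                           sep = "=", collapse = "; "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize PET SUVRs against wild-type controls (z-scores)
#'
#' Each amyloid-model SUVR is expressed in standard-deviation units of the
#' wild-type control distribution measured with the same reference region:
#' `z = (suvr - mean(wt suvr)) / sd(wt suvr)`, with the sample (n-1)
#' standard deviation. Controls are pooled across ages by default;
#' `age_matched = TRUE` restricts the control set to the observation's
#' own age.
#'
#' @param pet Data frame of PET observations (see [read_cohort()]).
#' @param wt Data frame of wild-type PET observations with the same
#'   columns; matched to `pet` on `reference_region` (and on `age_months`
#'   when `age_matched = TRUE`).
#' @param age_matched Logical; use age-matched rather than pooled
#'   wild-type statistics.
#' @return `pet` with columns `z`, `wt_mean`, `wt_sd` appended.
#' @export
compute_z <- function(pet, wt, age_matched = FALSE) {
  pet <- validate_pet(pet)
  wt <- validate_pet(wt)
  pet$z <- pet$wt_mean <- pet$wt_sd <- NA_real_
  for (i in seq_len(nrow(pet))) {
    sel <- wt$reference_region == pet$reference_region[i]
    if (age_matched) sel <- sel & wt$age_months == pet$age_months[i]
    ctrl <- wt$suvr[sel]
    if (length(ctrl) < 2) {
      stop("fewer than 2 wild-type controls for reference region '",
           pet$reference_region[i], "'",
           if (age_matched) paste0(" at age ", pet$age_months[i]),
           call. = FALSE)
    }
    m <- mean(ctrl)
    s <- stats::sd(ctrl)
    if (s == 0) {
      stop("degenerate wild-type controls (zero SD) for reference region '",
           pet$reference_region[i], "'", call. = FALSE)
    }
    pet$wt_mean[i] <- m
    pet$wt_sd[i] <- s
    pet$z[i] <- (pet$suvr[i] - m) / s
  }
  pet
}

#' Per-stratum summary statistics
#'
#' Mean, sample SD (n-1 denominator) and count of one or more variables
#' within each (genotype, age) stratum. Singleton strata have an
#' undefined SD, reported as `NA` and flagged.
#'
#' @param df Data frame with `genotype` and `age_months` columns.
#' @param vars Character vector of numeric column names to summarize.
#' @return Data frame with one row per stratum x variable:
#'   `genotype, age_months, variable, mean, sd, n, sd_undefined`.
#' @export
group_summary <- function(df, vars) {
  stopifnot(all(vars %in% names(df)))
  if (!nrow(df)) stop("empty input: no observations to summarize", call. = FALSE)
  strata <- unique(df[, c("genotype", "age_months")])
  strata <- strata[order(strata$genotype, strata$age_months), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- df$genotype == strata$genotype[i] & df$age_months == strata$age_months[i]
    do.call(rbind, lapply(vars, function(v) {
      x <- df[[v]][sel]
      data.frame(genotype = strata$genotype[i], age_months = strata$age_months[i],
                 variable = v, mean = mean(x),
                 sd = if (length(x) > 1) stats::sd(x) else NA_real_,
                 n = length(x), sd_undefined = length(x) == 1)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Unpaired two-sample Student t test
#'
#' Classical pooled-variance (equal-variance) Student t test with a
#' two-sided p-value, as used for the group-level comparisons of plaque
#' coverage and PET z-scores between genotypes at each age.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with elements `t`, `df`, `p`.
#' @export
unpaired_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
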