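PREDICTOR_COLUMNS <- c(fibrillar = "fibrillar_area_pct",
                       nonfibrillar = "nonfibrillar_area_pct",
                       heterogeneity = "heterogeneity",
                       age = "age_months")

# Design matrix (with intercept) for a predictor subset; drops columns
# that are identically zero (e.g. the heterogeneity covariate on
# noiseless data, where it is a well-defined degenerate regressor rather
# than a collinearity between informative predictors).
build_design <- function(pairs, predictors) {
  unknown <- setdiff(predictors, names(PREDICTOR_COLUMNS))
  if (length(unknown)) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(pairs[, PREDICTOR_COLUMNS[predictors], drop = FALSE])
  colnames(X) <- predictors
  zero <- colSums(X != 0) == 0
  dropped <- colnames(X)[zero]
  X <- X[, !zero, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, X)
  list(X = X, dropped = dropped)
}

check_rank <- function(X, cond_threshold = 1e10) {
  d <- svd(scale(X, center = FALSE, scale = sqrt(colSums(X^2))), nu = 0, nv = 0)$d
  if (min(d) == 0 || max(d) / min(d) > cond_threshold) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    if (!length(bad)) bad <- colnames(X)[-1]
    stop("singular design: collinear predictor(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit one linear model of the PET z-score on plaque predictors
#'
#' Ordinary least squares with intercept, regressing the PET z-score of
#' every paired record on a subset of \{fibrillar, nonfibrillar,
#' heterogeneity, age\}. Coefficients are in z-units per predictor unit
#' (percent area covered for the plaque terms, months for age). A
#' predictor column that is identically zero is dropped from the design
#' (coefficient `NA`, recorded in `$dropped`); a genuinely collinear
#' design is an error naming the offending predictors.
#'
#' @param pairs Paired design from [build_pairs()].
#' @param predictors Ordered character subset of
#'   `c("fibrillar", "nonfibrillar", "heterogeneity", "age")`.
#' @param name Optional model label (defaults to predictors joined by
#'   `" x "`).
#' @return An object of class `ab_fit`: coefficients (including
#'   intercept), per-coefficient standard errors and t-based p-values,
#'   `r2`, `adjusted_r2`, overall F-test p, residuals, `n_rows`.
#' @export
fit_ols <- function(pairs, predictors, name = NULL) {
  if (is.null(name)) name <- paste(predictors, collapse = " x ")
  des <- build_design(pairs, predictors)
  X <- des$X
  y <- pairs$z
  p_fit <- ncol(X)
  if (nrow(X) <= p_fit) {
    stop("too few rows (", nrow(X), ") for ", p_fit, " parameters", call. = FALSE)
  }
  check_rank(X)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  n <- length(y)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p_fit)
  sigma2 <- rss / (n - p_fit)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p_fit)
  f_p <- if (p_fit > 1 && tss > rss) {
    f <- ((tss - rss) / (p_fit - 1)) / sigma2
    stats::pf(f, p_fit - 1, n - p_fit, lower.tail = FALSE)
  } else NA_real_
  coefs <- stats::setNames(rep(NA_real_, length(predictors) + 1),
                           c("(Intercept)", predictors))
  coefs[names(beta)] <- beta
  structure(list(name = name, predictors = predictors, dropped = des$dropped,
                 coefficients = coefs, se = se, p_values = pval,
                 r2 = r2, adjusted_r2 = adj_r2, f_p = f_p,
                 residuals = res, fitted = fit$fitted.values, n_rows = n),
            class = "ab_fit")
}

#' @export
print.ab_fit <- function(x, ...) {
  cat("Linear model: z ~ ", x$name, "\n", sep = "")
  cat(sprintf("  n = %d, R2 = %.3f, adjusted R2 = %.3f, F-test p = %.3g\n",
              x$n_rows, x$r2, x$adjusted_r2, x$f_p))
  print(round(x$coefficients, 4))
  if (length(x$dropped)) {
    cat("  dropped identically-zero predictor(s):",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' The nested five-model ladder
#'
#' Canonical model specifications of the nested regression ladder, in
#' reporting order: each of the two plaque components alone, both
#' together, plus the individual-heterogeneity covariate, plus age.
#'
#' @return Named list of predictor vectors.
#' @export
model_ladder <- function() {
  list(
    "fibrillar" = "fibrillar",
    "nonfibrillar" = "nonfibrillar",
    "fibrillar x nonfibrillar" = c("fibrillar", "nonfibrillar"),
    "fibrillar x nonfibrillar x heterogeneity" =
      c("fibrillar", "nonfibrillar", "heterogeneity"),
    "fibrillar x nonfibrillar x heterogeneity x age" =
      c("fibrillar", "nonfibrillar", "heterogeneity", "age")
  )
}

#' Fit the whole nested model ladder
#'
#' @param pairs Paired design from [build_pairs()].
#' @return Object of class `ab_ladder`: a named list of [fit_ols()]
#'   results in ladder order.
#' @seealso [ladder_table()] for the tabular report.
#' @export
fit_ladder <- function(pairs) {
  specs <- model_ladder()
  fits <- lapply(names(specs), function(nm) fit_ols(pairs, specs[[nm]], name = nm))
  names(fits) <- names(specs)
  structure(fits, class = "ab_ladder")
}

#' Tabulate a fitted ladder in report layout
#'
#' One row per model with R2, adjusted R2, fibrillar and nonfibrillar
#' coefficients (with bootstrap CIs when supplied) and the overall-model
#' p-value (F test).
#'
#' @param ladder An `ab_ladder` from [fit_ladder()].
#' @param cis Optional named list of [bootstrap_ci()] results, keyed by
#'   model name.
#' @return Data frame.
#' @export
ladder_table <- function(ladder, cis = NULL) {
  fmt <- function(b, ci) {
    if (is.na(b)) return("")
    if (is.null(ci)) return(sprintf("%.3f", b))
    sprintf("%.3f (%.3f-%.3f)", b, ci[1], ci[2])
  }
  do.call(rbind, lapply(names(ladder), function(nm) {
    f <- ladder[[nm]]
    bootci <- cis[[nm]]
    get_ci <- function(term) {
      if (!is.null(bootci) && term %in% rownames(bootci$ci)) bootci$ci[term, ]
    }
    data.frame(model = nm, r2 = f$r2, adjusted_r2 = f$adjusted_r2,
               b_fibrillar = fmt(f$coefficients["fibrillar"], get_ci("fibrillar")),
               b_nonfibrillar = fmt(f$coefficients["nonfibrillar"],
                                    get_ci("nonfibrillar")),
               p = f$f_p, row.names = NULL)
  }))
}

#' @export
print.ab_ladder <- function(x, ...) {
  print(ladder_table(x))
  invisible(x)
}

#' Percentile bootstrap confidence intervals for model coefficients
#'
#' Case resampling: rows of the paired design are drawn with replacement
#' (same n), the model refitted, and per-coefficient 95% percentile
#' intervals taken over the resamples. With `unit = "pet-mouse"` whole
#' PET mice (all their paired rows) are resampled instead. A
#' rank-deficient resample is redrawn; the redraw count is reported and
#' more than 10% redraws triggers a warning.
#'
#' @param pairs Paired design from [build_pairs()].
#' @param predictors Predictor subset as in [fit_ols()].
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param unit Resampling unit, `"row"` or `"pet-mouse"`.
#' @param level Confidence level.
#' @return Object of class `ab_boot`: `ci` matrix (rows = coefficients,
#'   columns `lower`/`upper`), `estimates` draw matrix, `n_boot`, `seed`,
#'   `n_redrawn`.
#' @export
bootstrap_ci <- function(pairs, predictors, n_boot = 1000, seed = 1L,
                         unit = c("row", "pet-mouse"), level = 0.95) {
  unit <- match.arg(unit)
  des <- build_design(pairs, predictors)
  X <- des$X
  y <- pairs$z
  check_rank(X)
  p_fit <- ncol(X)
  groups <- if (unit == "pet-mouse") split(seq_len(nrow(X)), pairs$pet_mouse_id)
  draws <- matrix(NA_real_, n_boot, p_fit, dimnames = list(NULL, colnames(X)))
  n_redrawn <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- if (unit == "row") {
          sample.int(nrow(X), replace = TRUE)
        } else {
          unlist(groups[sample.int(length(groups), replace = TRUE)],
                 use.names = FALSE)
        }
        fb <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])
        if (fb$rank == p_fit) break
        n_redrawn <- n_redrawn + 1L
      }
      draws[b, ] <- fb$coefficients
    }
  })
  if (n_redrawn > 0.1 * n_boot) {
    warning(n_redrawn, " rank-deficient resamples redrawn (> 10% of n_boot)",
            call. = FALSE)
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                type = 7))
  colnames(ci) <- c("lower", "upper")
  structure(list(ci = ci, estimates = draws, n_boot = n_boot,
                 seed = as.integer(seed), level = level,
                 n_redrawn = n_redrawn, dropped = des$dropped),
            class = "ab_boot")
}

#' @export
print.ab_boot <- function(x, ...) {
  cat(sprintf("Percentile bootstrap CIs (%d resamples, seed %d, level %.0f%%)\n",
              x$n_boot, x$seed, 100 * x$level))
  print(round(x$ci, 4))
  invisible(x)
}

#' Synthesize the headline fibrillar/nonfibrillar coefficient summary
#'
#' Averages the fibrillar and nonfibrillar coefficients of the two most
#' complete ladder models (with and without the age covariate) and forms
#' the fold ratio of the mean fibrillar to the mean nonfibrillar signal
#' per percent area covered. The plausible fold range comes from the
#' opposite edges of the per-model bootstrap CIs: the lower bound is the
#' mean over models of (fibrillar lower / nonfibrillar upper), the upper
#' bound the mean of (fibrillar upper / nonfibrillar lower).
#'
#' @param fit_het,fit_full The two most complete `ab_fit` models (without
#'   and with age), each containing fibrillar and nonfibrillar terms.
#' @param ci_het,ci_full Their [bootstrap_ci()] results.
#' @return Object of class `ab_coef_summary`: `b_fib_mean`,
#'   `b_nonfib_mean`, `fold_ratio`, `fold_range`, plus per-model inputs.
#' @export
summarize_coefficients <- function(fit_het, fit_full, ci_het, ci_full) {
  get_b <- function(f, term) {
    b <- if (inherits(f, "ab_fit")) f$coefficients[term] else f[[term]]
    if (is.null(b) || is.na(b)) {
      stop("model lacks a ", term, " coefficient", call. = FALSE)
    }
    unname(b)
  }
  get_ci <- function(ci, term) {
    m <- if (inherits(ci, "ab_boot")) ci$ci else ci
    if (!term %in% rownames(m)) {
      stop("confidence intervals lack a ", term, " interval", call. = FALSE)
    }
    m[term, ]
  }
  b_fib <- c(get_b(fit_het, "fibrillar"), get_b(fit_full, "fibrillar"))
  b_nonfib <- c(get_b(fit_het, "nonfibrillar"), get_b(fit_full, "nonfibrillar"))
  ci_fib <- rbind(get_ci(ci_het, "fibrillar"), get_ci(ci_full, "fibrillar"))
  ci_nonfib <- rbind(get_ci(ci_het, "nonfibrillar"), get_ci(ci_full, "nonfibrillar"))
  b_fib_mean <- mean(b_fib)
  b_nonfib_mean <- mean(b_nonfib)
  if (b_nonfib_mean == 0) {
    stop("undefined fold ratio: mean nonfibrillar coefficient is zero",
         call. = FALSE)
  }
  fold_low <- mean(ci_fib[, 1] / ci_nonfib[, 2])
  fold_high <- mean(ci_fib[, 2] / ci_nonfib[, 1])
  structure(list(b_fib_mean = b_fib_mean, b_nonfib_mean = b_nonfib_mean,
                 fold_ratio = b_fib_mean / b_nonfib_mean,
                 fold_range = c(low = fold_low, high = fold_high),
                 per_model = list(b_fibrillar = b_fib, b_nonfibrillar = b_nonfib,
                                  ci_fibrillar = ci_fib,
                                  ci_nonfibrillar = ci_nonfib)),
            class = "ab_coef_summary")
}

#' Coefficient synthesis from a published-style coefficient table
#'
#' Convenience wrapper around [summarize_coefficients()] for a
#' two-row coefficient table (one row per model) with columns
#' `b_fibrillar, fibrillar_lower, fibrillar_upper, b_nonfibrillar,
#' nonfibrillar_lower, nonfibrillar_upper`, e.g. the shipped
#' `table1_coefficients.csv` reporting fixture.
#'
#' @param tab Data frame with exactly two rows in ladder order (the
#'   heterogeneity model first, the age-including model second).
#' @return An `ab_coef_summary`.
#' @export
summarize_coefficient_table <- function(tab) {
  stopifnot(nrow(tab) == 2)
  mk_ci <- function(i) {
    matrix(c(tab$fibrillar_lower[i], tab$fibrillar_upper[i],
             tab$nonfibrillar_lower[i], tab$nonfibrillar_upper[i]),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("fibrillar", "nonfibrillar"),
                           c("lower", "upper")))
  }
  summarize_coefficients(
    list(fibrillar = tab$b_fibrillar[1], nonfibrillar = tab$b_nonfibrillar[1]),
    list(fibrillar = tab$b_fibrillar[2], nonfibrillar = tab$b_nonfibrillar[2]),
    mk_ci(1), mk_ci(2))
}

#' @export
print.ab_coef_summary <- function(x, ...) {
  cat(sprintf("Signal per 1%% area covered: fibrillar %.2f z, nonfibrillar %.2f z\n",
              x$b_fib_mean, x$b_nonfib_mean))
  cat(sprintf("Fibrillar-to-nonfibrillar fold ratio: %d-fold (range %d- to %d-fold)\n",
              round(x$fold_ratio), round(x$fold_range["low"]),
              round(x$fold_range["high"])))
  invisible(x)
}
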