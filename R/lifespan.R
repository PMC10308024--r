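# Lifespan trajectory analytics: per-sex natural cubic spline fits with AIC
# degrees-of-freedom selection, knee-point (kneedle) inflection detection,
# per-period OLS with age-by-sex interaction under BH-FDR correction, and the
# normalized anteroposterior subfield composition profile.

#' Fit a natural cubic spline volume trajectory
#'
#' Ordinary least squares of volume on a natural cubic spline basis of age
#' (quantile-placed interior knots, linear beyond the boundary knots).
#'
#' @param table long-format subject table (`age`, `sex`, `region`,
#'   `volume_mm3`).
#' @param region region to fit.
#' @param sex `"F"`, `"M"`, or `NULL` to pool sexes.
#' @param df spline degrees of freedom (>= 2).
#' @return a `trajectory_fit`: region, sex, df, knots, coefficients, AIC,
#'   R^2, overall-F p-value, and `curve(ages)` evaluator.
#' @export
fit_ncs <- function(table, region, sex = NULL, df = 4L) {
  assert_that(df >= 2, "df must be >= 2")
  d <- table[table$region == region, ]
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  assert_that(nrow(d) >= df + 2, "need at least df + 2 observations (have %d)",
              nrow(d))
  basis <- splines::ns(d$age, df = df)
  fit <- lm(d$volume_mm3 ~ basis)
  if (any(is.na(coef(fit)))) stopf("rank-deficient spline design")
  sm <- summary(fit)
  fstat <- sm$fstatistic
  pv <- if (!is.null(fstat))
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)) else NA_real_
  knots <- attr(basis, "knots")
  bknots <- attr(basis, "Boundary.knots")
  curve <- function(ages) {
    # ns() warns about extrapolation beyond the boundary knots, where the
    # basis is linear by construction; that is exactly the intended behavior
    nb <- suppressWarnings(predict(basis, ages))
    as.numeric(cbind(1, nb) %*% coef(fit))
  }
  structure(list(region = region, sex = sex, df = df,
                 knots = as.numeric(knots), boundary_knots = bknots,
                 coefficients = coef(fit), aic = AIC(fit),
                 r_squared = sm$r.squared, p_value = pv,
                 n = nrow(d), curve = curve, lm = fit),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %s / %s: df=%d, AIC=%.1f, R2=%.3f, p=%.3g\n",
              x$region, x$sex %||% "pooled", x$df, x$aic, x$r_squared,
              x$p_value))
  invisible(x)
}

#' Select spline degrees of freedom by AIC
#'
#' Fits the trajectory at every df in `df_range` and returns the df with
#' minimal AIC; ties go to the smallest df.
#'
#' @inheritParams fit_ncs
#' @param df_range candidate degrees of freedom.
#' @return the selected df (integer).
#' @export
select_df_aic <- function(table, region, sex = NULL, df_range = 2:15) {
  assert_that(length(df_range) >= 1, "df_range must be non-empty")
  aics <- vapply(df_range, function(df)
    fit_ncs(table, region, sex, df)$aic, numeric(1))
  df_range[which.min(aics)]  # which.min takes the first (smallest df) on ties
}

# ---- kneedle ---------------------------------------------------------------

# Offline kneedle on one monotone segment: normalize to the unit square, flip
# decreasing/convex shapes onto the concave-increasing case, and return the
# age at the maximum of the difference-from-chord curve if it clears the
# sensitivity threshold.
kneedle_segment <- function(x, y, sensitivity = 1.0) {
  n <- length(x)
  if (n < 5) return(numeric(0))
  rng_x <- diff(range(x)); rng_y <- diff(range(y))
  if (rng_x == 0 || rng_y == 0) return(numeric(0))
  xn <- (x - min(x)) / rng_x
  yn <- (y - min(y)) / rng_y
  decreasing <- y[n] < y[1]
  if (decreasing) yn <- 1 - yn        # map onto an increasing curve
  concave <- mean(yn - xn) >= 0
  d <- if (concave) yn - xn else xn - yn
  if (!concave) d <- rev(d)           # convex-increasing: knee from the right
  i <- which.max(d)
  thr <- sensitivity * mean(diff(xn))
  if (d[i] <= thr) return(numeric(0))
  if (!concave) i <- n - i + 1
  x[i]
}

#' Detect inflection ages of a fitted trajectory
#'
#' Evaluates the fitted curve on a dense age grid and applies the kneedle
#' knee-point procedure separately to the rising and falling segments split at
#' the curve's global maximum, so both the growth-end and the decay-onset
#' knees can be found. Straight lines yield no inflections.
#'
#' @param fit a `trajectory_fit` (or any list with `curve` and
#'   `boundary_knots`).
#' @param age_grid evaluation ages (default 0.5-year grid over the fit range).
#' @param sensitivity kneedle sensitivity (default 1.0).
#' @return numeric vector of inflection ages (possibly empty), sorted.
#' @export
detect_inflections <- function(fit, age_grid = NULL, sensitivity = 1.0) {
  if (is.null(age_grid)) {
    r <- fit$boundary_knots %||% range(fit$knots)
    age_grid <- seq(r[1], r[2], by = 0.5)
  }
  y <- fit$curve(age_grid)
  # flat curve: no inflections
  if (diff(range(y)) < 1e-8 * max(abs(y), 1)) return(numeric(0))
  imax <- which.max(y)
  out <- c(
    if (imax >= 5) kneedle_segment(age_grid[1:imax], y[1:imax], sensitivity),
    if (imax <= length(y) - 4)
      kneedle_segment(age_grid[imax:length(y)], y[imax:length(y)], sensitivity))
  sort(unique(out))
}

# ---- per-period regressions -------------------------------------------------

#' Per-period OLS of volume on age, sex and their interaction
#'
#' Within each period (assumed linear between inflection points), fits
#' `volume ~ age * sex` and reports the age slope, sex effect and age-by-sex
#' interaction with raw p-values. Single-sex periods drop the sex terms.
#' Periods with fewer than 4 observations per present sex are skipped with a
#' warning.
#'
#' @param table long-format subject table.
#' @param region region to analyze.
#' @param periods list of `c(lo, hi)` age intervals (half-open).
#' @return data.frame with one row per period and term: `period_lo`,
#'   `period_hi`, `term`, `estimate`, `std_error`, `p_value`, `n`.
#' @export
period_regressions <- function(table, region, periods) {
  d0 <- table[table$region == region, ]
  rows <- list()
  for (p in periods) {
    d <- d0[d0$age >= p[1] & d0$age < p[2], ]
    sexes <- unique(d$sex)
    if (nrow(d) == 0 || any(table(factor(d$sex, levels = sexes)) < 4)) {
      warning(sprintf("period [%g, %g) skipped: too few observations",
                      p[1], p[2]))
      next
    }
    if (length(sexes) >= 2) {
      fit <- lm(volume_mm3 ~ age * sex, data = d)
      terms <- c(age = "age_slope", sexM = "sex_effect",
                 `age:sexM` = "age_sex_interaction")
    } else {
      fit <- lm(volume_mm3 ~ age, data = d)
      terms <- c(age = "age_slope")
    }
    sm <- coef(summary(fit))
    for (tn in names(terms)) {
      if (!tn %in% rownames(sm)) next
      rows[[length(rows) + 1]] <- data.frame(
        region = region, period_lo = p[1], period_hi = p[2],
        term = terms[[tn]], estimate = sm[tn, 1], std_error = sm[tn, 2],
        p_value = sm[tn, 4], n = nrow(d))
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in sorted order and capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  assert_that(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# ---- orchestration ----------------------------------------------------------

#' Full lifespan trajectory analysis
#'
#' Per (region, sex): AIC-selected natural-spline fit and inflection
#' detection. Per region: periods built from the merged per-sex inflection
#' ages (ages closer than `merge_tol` years are averaged) plus the age-range
#' boundaries, then pooled per-period regressions with age-by-sex interaction.
#' BH correction is applied over the family of all regions and terms.
#'
#' @param table long-format subject table.
#' @param regions regions to analyze (default: all present).
#' @param df_range candidate spline degrees of freedom.
#' @param merge_tol years within which per-sex inflection ages are merged.
#' @return list with `fits` (per region/sex), `inflections`, `periods`, and
#'   `period_tests` (with `p_adjusted`).
#' @export
lifespan_analysis <- function(table, regions = unique(table$region),
                              df_range = 2:15, merge_tol = 5) {
  fits <- list()
  inflections <- list()
  periods <- list()
  tests <- list()
  for (r in regions) {
    ages_r <- range(table$age[table$region == r])
    infl_r <- numeric(0)
    for (s in intersect(c("F", "M"), unique(table$sex))) {
      df <- select_df_aic(table, r, s, df_range)
      f <- fit_ncs(table, r, s, df)
      fits[[paste(r, s, sep = ".")]] <- f
      infl_r <- c(infl_r, detect_inflections(f))
    }
    infl_r <- merge_close(sort(infl_r), merge_tol)
    inflections[[r]] <- infl_r
    cuts <- c(ages_r[1], infl_r, ages_r[2] + 1e-9)
    pds <- lapply(seq_len(length(cuts) - 1), function(i) c(cuts[i], cuts[i + 1]))
    periods[[r]] <- pds
    tests[[r]] <- period_regressions(table, r, pds)
  }
  pt <- do.call(rbind, tests)
  if (!is.null(pt)) pt$p_adjusted <- bh_fdr(pt$p_value)
  list(fits = fits, inflections = inflections, periods = periods,
       period_tests = pt)
}

merge_close <- function(x, tol) {
  if (length(x) <= 1) return(x)
  groups <- cumsum(c(TRUE, diff(x) > tol))
  as.numeric(tapply(x, groups, mean))
}

# ---- anteroposterior profile ------------------------------------------------

#' Normalized anteroposterior subfield composition
#'
#' For each label map: per slice along the anteroposterior axis, the fraction
#' of each subfield among hippocampus voxels in that slice; slice positions
#' are normalized to 0%% (head) .. 100%% (tail) between the first and last
#' non-empty slices, resampled to a common grid and averaged across subjects.
#'
#' @param labelmaps list of [labelmap()]s (or integer arrays).
#' @param axis anteroposterior voxel axis (default 2; never auto-guessed).
#' @param classes label ids counted as hippocampus (default: all non-zero
#'   labels of the first map).
#' @param grid positions (percent) of the common output grid.
#' @return data.frame with columns `position` (percent), one column per class
#'   name, and `n_subjects`.
#' @export
anteroposterior_profile <- function(labelmaps, axis = 2L, classes = NULL,
                                    grid = seq(0, 100, by = 1)) {
  assert_that(length(labelmaps) >= 1, "need at least one label map")
  first <- labelmaps[[1]]
  schema <- if (inherits(first, "labelmap")) first$schema else NULL
  arr1 <- if (inherits(first, "volume")) first$data else first
  if (is.null(classes)) classes <- sort(setdiff(unique(as.integer(arr1)), 0L))
  cls_names <- if (!is.null(schema))
    names(schema)[match(classes, schema)] else paste0("class", classes)
  curves <- array(NA_real_, dim = c(length(labelmaps), length(grid),
                                    length(classes)))
  for (i in seq_along(labelmaps)) {
    arr <- if (inherits(labelmaps[[i]], "volume")) labelmaps[[i]]$data
           else labelmaps[[i]]
    hip <- array(arr %in% classes, dim = dim(arr))
    per_slice <- apply(hip, axis, sum)
    nz <- which(per_slice > 0)
    if (length(nz) == 0) stopf("label map %d contains no hippocampus voxel", i)
    pos <- if (length(nz) == 1) 50 else
      (nz - nz[1]) / (nz[length(nz)] - nz[1]) * 100
    frac <- vapply(classes, function(cl)
      apply(array(arr == cl, dim = dim(arr)), axis, sum)[nz] / per_slice[nz],
      numeric(length(nz)))
    frac <- matrix(frac, nrow = length(nz))
    for (k in seq_along(classes)) {
      curves[i, , k] <- if (length(nz) == 1) rep(frac[1, k], length(grid))
        else approx(pos, frac[, k], xout = grid, rule = 2)$y
    }
  }
  avg <- apply(curves, c(2, 3), mean)
  out <- data.frame(position = grid)
  for (k in seq_along(classes)) out[[cls_names[k]]] <- avg[, k]
  out$n_subjects <- length(labelmaps)
  out
}
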