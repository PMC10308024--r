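# Synthetic lifespan cohort generator: per-region, per-sex
# growth / stability / decay volume trajectories.
#
# The noiseless generating curve is a natural cubic interpolating spline
# through control points laid on a piecewise-linear growth-plateau-decay
# skeleton, so it is continuous, piecewise-cubic and linear in the tails,
# smoothly bending at the growth-end and decay-onset knots.

#' Default region parameters for the lifespan generator
#'
#' Plateau volumes are of the order of adult subfield volumes (mm^3); males
#' carry a +5% plateau offset and steeper growth and decay slopes (faster
#' dynamics in men), which makes the sex main effect and age-by-sex
#' interaction recoverable.
#'
#' @param plateaus named plateau volumes (mm^3) per region (female).
#' @param male_offset relative male plateau offset.
#' @param growth_frac fraction of plateau gained over the growth period.
#' @param decay_rate relative volume loss per year after decay onset.
#' @param male_slope_factor multiplier on male growth/decay slopes.
#' @return data.frame with columns region, sex, growth_slope, plateau,
#'   decay_slope.
#' @export
default_region_params <- function(plateaus = c(DG = 300, CA1 = 600,
                                               `CA2-3` = 180, SUB = 250),
                                  male_offset = 0.05, growth_frac = 0.35,
                                  decay_rate = 0.02,
                                  male_slope_factor = 1.3) {
  rows <- list()
  for (r in names(plateaus)) for (s in c("F", "M")) {
    pl <- plateaus[[r]] * (1 + if (s == "M") male_offset else 0)
    fac <- if (s == "M") male_slope_factor else 1
    rows[[length(rows) + 1]] <- data.frame(
      region = r, sex = s,
      growth_slope = fac * growth_frac * pl / 17,  # rise spread over ~17 y
      plateau = pl,
      decay_slope = -fac * decay_rate * pl)
  }
  do.call(rbind, rows)
}

#' Lifespan cohort specification
#'
#' @param n_subjects total subjects (>= 10), split evenly between sexes.
#' @param age_range years, within \[0, 120\].
#' @param knot_ages `c(growth_end, decay_onset)` in years.
#' @param region_params data.frame as from [default_region_params()].
#' @param noise_sd residual standard deviation in mm^3; a single value or a
#'   named vector per region (default 5% of each region's female plateau).
#' @param seed integer seed.
#' @return a `lifespan_spec` list.
#' @export
lifespan_spec <- function(n_subjects = 2000L, age_range = c(5, 100),
                          knot_ages = c(22, 70),
                          region_params = default_region_params(),
                          noise_sd = NULL, seed = 1L) {
  assert_that(n_subjects >= 10, "n_subjects must be >= 10")
  assert_that(age_range[1] >= 0 && age_range[2] <= 120 &&
                age_range[1] < age_range[2],
              "age_range must be increasing and within [0, 120]")
  if (is.null(noise_sd)) {
    f <- region_params[region_params$sex == "F", ]
    noise_sd <- setNames(0.05 * f$plateau, f$region)
  }
  assert_that(all(noise_sd >= 0), "noise_sd must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 knot_ages = knot_ages, region_params = region_params,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "lifespan_spec")
}

#' Noiseless generating curve of the lifespan generator
#'
#' @param spec a [lifespan_spec()].
#' @param region region name.
#' @param sex `"F"` or `"M"`.
#' @param ages ages (years) at which to evaluate.
#' @return volumes in mm^3.
#' @export
lifespan_curve <- function(spec, region, sex, ages) {
  p <- spec$region_params
  row <- p[p$region == region & p$sex == sex, ]
  assert_that(nrow(row) == 1, "no parameters for region %s sex %s", region, sex)
  k1 <- spec$knot_ages[1]; k2 <- spec$knot_ages[2]
  a0 <- spec$age_range[1]; a1 <- spec$age_range[2]
  skeleton <- function(a) {
    ifelse(a < k1, row$plateau - row$growth_slope * (k1 - a),
           ifelse(a <= k2, row$plateau,
                  row$plateau + row$decay_slope * (a - k2)))
  }
  # symmetric, tight control points around each knot so the generating curve
  # bends exactly at the stated growth-end / decay-onset ages
  ctrl <- sort(unique(pmax(a0, pmin(a1, c(
    a0, (a0 + k1) / 2, k1 - 4, k1, k1 + 4, (k1 + k2) / 2, k2 - 4, k2, k2 + 4,
    (k2 + a1) / 2, a1)))))
  spline(ctrl, skeleton(ctrl), xout = ages, method = "natural")$y
}

#' Generate a synthetic lifespan cohort
#'
#' Volumes are the generating curve evaluated at each subject's age plus
#' Gaussian noise; deterministic under the spec's seed.
#'
#' @param spec a [lifespan_spec()].
#' @return long-format data.frame with columns `subject_id`, `age`, `sex`,
#'   `region`, `volume_mm3`.
#' @export
make_lifespan_cohort <- function(spec) {
  regions <- unique(spec$region_params$region)
  noise <- spec$noise_sd
  if (length(noise) == 1) noise <- setNames(rep(noise, length(regions)), regions)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    sex <- rep(c("F", "M"), length.out = n)
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    out <- vector("list", length(regions))
    for (i in seq_along(regions)) {
      r <- regions[i]
      vol <- numeric(n)
      for (s in c("F", "M")) {
        sel <- sex == s
        vol[sel] <- lifespan_curve(spec, r, s, age[sel])
      }
      vol <- vol + rnorm(n, sd = noise[[r]])
      out[[i]] <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                             age = age, sex = sex, region = r,
                             volume_mm3 = vol)
    }
    do.call(rbind, out)
  })
}
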