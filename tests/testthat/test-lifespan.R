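make_table <- function(age, vol, sex = "F", region = "R") {
  data.frame(subject_id = seq_along(age), age = age, sex = sex,
             region = region, volume_mm3 = vol)
}

test_that("natural spline fits recover their own generating curve", {
  set.seed(1)
  age <- runif(500, 5, 100)
  B <- splines::ns(age, df = 4)
  truth <- 400 + as.numeric(B %*% c(120, -60, 90, -40))
  f <- suppressWarnings(fit_ncs(make_table(age, truth), "R", "F", df = 4))
  expect_gte(f$r_squared, 0.999)
  expect_equal(f$curve(age), truth, tolerance = 1e-6)
  # boundary linearity: second difference ~ 0 beyond the boundary knots
  gr <- seq(101, 120, by = 0.5)
  d2 <- diff(f$curve(gr), differences = 2)
  expect_lt(max(abs(d2)), 1e-6 * max(abs(truth)))
})

test_that("linear data collapses the spline to the line", {
  set.seed(2)
  age <- runif(300, 10, 90)
  vol <- 100 + 2.5 * age
  f <- suppressWarnings(fit_ncs(make_table(age, vol), "R", "F", df = 4))
  expect_lt(max(abs(f$curve(age) - vol)), 1e-6 * 2.5 * 80)
  expect_length(detect_inflections(f), 0)
})

test_that("too few observations error out", {
  expect_error(fit_ncs(make_table(c(1, 2, 3), c(1, 2, 3)), "R", "F", df = 4),
               "observations")
})

test_that("AIC selection is scale-equivariant with smallest-df ties", {
  set.seed(3)
  age <- runif(400, 5, 100)
  vol <- 300 + 50 * sin(age / 15) + rnorm(400, sd = 5)
  t1 <- make_table(age, vol)
  t2 <- make_table(age, vol * 1000)
  expect_equal(select_df_aic(t1, "R", "F", 2:8),
               select_df_aic(t2, "R", "F", 2:8))
  expect_equal(select_df_aic(t1, "R", "F", 5L), 5L)
})

test_that("kneedle finds the canonical corner and ignores straight lines", {
  x <- seq(0, 4, by = 0.01)
  k <- hippseg:::kneedle_segment(x, pmin(x, 1), 1.0)
  expect_lt(abs(k - 1), 0.02)
  expect_length(hippseg:::kneedle_segment(x, 2 * x + 1, 1.0), 0)
  # decreasing concave corner (plateau then drop)
  k2 <- hippseg:::kneedle_segment(x, pmin(1, 1 - (x - 1) * 0.5), 1.0)
  expect_lt(abs(k2 - 1), 0.02)
})

test_that("the full trajectory pipeline recovers the decay onset", {
  tab <- make_lifespan_cohort(lifespan_spec(seed = 42))
  df <- select_df_aic(tab, "DG", "F")
  f <- fit_ncs(tab, "DG", "F", df)
  infl <- detect_inflections(f)
  onset <- infl[infl > 50][1]
  expect_false(is.na(onset))
  expect_lte(abs(onset - 70), 3)
  # growth-end knee near the first knot (22) as well
  growth <- infl[infl < 40][1]
  expect_lte(abs(growth - 22), 6)
})

test_that("period regressions estimate slopes, sex effects and interactions", {
  set.seed(4)
  n <- 400
  age <- runif(n, 20, 60)
  sex <- rep(c("F", "M"), n / 2)
  vol <- 500 + 2 * age + 30 * (sex == "M") + 1.5 * age * (sex == "M") +
    rnorm(n, sd = 10)
  tab <- make_table(age, vol); tab$sex <- sex
  res <- period_regressions(tab, "R", list(c(20, 60)))
  expect_setequal(res$term, c("age_slope", "sex_effect", "age_sex_interaction"))
  est <- setNames(res$estimate, res$term)
  expect_equal(unname(est["age_slope"]), 2, tolerance = 0.2)
  expect_equal(unname(est["age_sex_interaction"]), 1.5, tolerance = 0.3)
  # single-sex table: sex terms dropped, slope still estimated
  resF <- period_regressions(tab[tab$sex == "F", ], "R", list(c(20, 60)))
  expect_equal(resF$term, "age_slope")
  expect_equal(resF$estimate, 2, tolerance = 0.3)
  # undersized period skipped with warning
  expect_warning(period_regressions(tab, "R", list(c(95, 99))), "skipped")
})

test_that("BH adjustment reproduces the step-up rule and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(30)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  o <- sample(30)
  expect_equal(bh_fdr(p[o]), adj[o])
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("anteroposterior profiles sum to one and match the generator", {
  ph <- make_hippocampus_phantom(phantom_spec(seed = 1))
  prof <- anteroposterior_profile(list(ph$labels), axis = 2)
  frac <- as.matrix(prof[, c("DG", "CA1", "CA2", "CA3", "SUB")])
  expect_true(all(abs(rowSums(frac) - 1) < 1e-9))
  # single subject: average equals that subject's curve
  prof2 <- anteroposterior_profile(list(ph$labels, ph$labels), axis = 2)
  expect_equal(prof2[, 1:6], prof[, 1:6])
  # generator round-trip: body composition matches the angular partition
  # (DG core area fraction = (r_in/r_out)^2, ring split in four sectors)
  body <- frac[prof$position >= 30 & prof$position <= 70, ]
  dg_expect <- 0.45^2
  expect_lt(abs(mean(body[, "DG"]) - dg_expect), 0.08)
  ring_each <- (1 - dg_expect) / 4
  for (cl in c("CA1", "CA2", "CA3", "SUB"))
    expect_lt(abs(mean(body[, cl]) - ring_each), 0.08)
  expect_error(anteroposterior_profile(list(labelmap(array(0L, c(4, 4, 4))))),
               "no hippocampus")
})

test_that("lifespan_analysis assembles fits, periods and corrected tests", {
  tab <- make_lifespan_cohort(lifespan_spec(n_subjects = 600, seed = 8))
  an <- lifespan_analysis(tab, regions = "CA1", df_range = 2:10)
  expect_true("CA1.F" %in% names(an$fits))
  expect_true(all(an$period_tests$p_adjusted >= an$period_tests$p_value - 1e-15))
  expect_gte(length(an$periods$CA1), 2)
})
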