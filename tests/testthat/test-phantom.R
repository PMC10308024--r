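test_that("noiseless, bias-free phantom renders exact class intensities", {
  sp <- phantom_spec(noise_sd = 0, bias_amplitude = 0)
  ph <- make_hippocampus_phantom(sp)
  for (cls in names(sp$class_intensities)) {
    id <- canonical_classes()[[cls]]
    vox <- ph$volume$data[ph$labels$data == id]
    expect_gt(length(vox), 0)
    expect_equal(unique(vox), unname(sp$class_intensities[[cls]]))
  }
  expect_equal(unique(ph$volume$data[ph$labels$data == 0]),
               sp$bg_intensity)
})

test_that("seed changes only the noise, never the labels", {
  ph1 <- make_hippocampus_phantom(phantom_spec(seed = 1))
  ph2 <- make_hippocampus_phantom(phantom_spec(seed = 2))
  expect_identical(ph1$labels$data, ph2$labels$data)
  expect_false(identical(ph1$volume$data, ph2$volume$data))
  # identical seed => bit-identical output
  ph1b <- make_hippocampus_phantom(phantom_spec(seed = 1))
  expect_identical(ph1$volume$data, ph1b$volume$data)
})

test_that("head/tail phantoms carve seven non-empty classes", {
  ph <- make_hippocampus_phantom(phantom_spec(include_head_tail = TRUE))
  counts <- table(ph$labels$data)
  present <- as.integer(names(counts)[counts > 0])
  expect_setequal(setdiff(present, 0L), 1:7)
})

test_that("a too-small grid errors naming the missing class", {
  expect_error(
    make_hippocampus_phantom(phantom_spec(grid_shape = c(16, 16, 16),
                                          radius = 0.8)),
    "carve class")
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), "grid_shape")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
})

test_that("protocol variants relabel as the rater would have drawn", {
  ph <- make_hippocampus_phantom(phantom_spec())
  lm0 <- ph$labels
  # identity protocol: voxel-for-voxel equal
  expect_identical(make_protocol_variants(lm0, protocol_spec())$data, lm0$data)
  # CA2+CA3 merge: histogram additivity
  pr <- protocol_spec(merge_groups = list(c("CA2", "CA3")))
  merged <- make_protocol_variants(lm0, pr)
  cc <- canonical_classes()
  expect_equal(sum(merged$data == cc[["CA2"]]),
               sum(lm0$data == cc[["CA2"]]) + sum(lm0$data == cc[["CA3"]]))
  expect_true("CA2-CA3" %in% names(merged$schema))
  # head-cap protocol: no subfield label anterior to the head boundary plane
  hp <- make_protocol_variants(lm0, protocol_spec(head_tail = TRUE))
  tst <- attr(lm0, "t_star")
  in_head <- !is.na(tst) & tst < attr(lm0, "cap_masks")$head_boundary_t
  expect_true(all(hp$data[in_head] %in% cc[c("HEAD")]))
  # conservation: total foreground voxel count never changes
  for (v in list(merged, hp))
    expect_equal(sum(v$data > 0), sum(lm0$data > 0))
  # unknown canonical class
  expect_error(protocol_spec(merge_groups = list(c("CA2", "CAX"))), "unknown")
})

test_that("head scenes embed phantoms at recorded poses", {
  sc <- small_scene()
  # left/right ground-truth boxes are disjoint along the left-right axis
  expect_true(sc$boxes$left$hi[1] <= sc$boxes$right$lo[1])
  # identity-pose crop recovers the phantom up to resampling (Dice >= 0.95)
  ph <- make_hippocampus_phantom(phantom_spec(seed = 3))
  pull <- sc$poses$left
  lab_back <- hippseg:::resample_array(sc$labels$data, pull,
                                       dim(ph$labels$data), "nearest", 0)
  expect_gte(dice(ph$labels$data > 0, lab_back > 0), 0.95)
  # pure translation of the pose shifts the ground-truth box exactly
  sh <- affine_transform(diag(3), sc$poses$left$offset + c(5, 0, 0))
  sc2 <- make_head_scene(phantom_spec(seed = 3), pose_left = sh)
  expect_equal(sc2$boxes$left$lo[1], sc$boxes$left$lo[1] + 5L)
  expect_equal(sc2$boxes$left$hi[1], sc$boxes$left$hi[1] + 5L)
  # a pose outside the field of view errors
  expect_error(make_head_scene(phantom_spec(seed = 3),
                               pose_left = affine_transform(diag(3), c(50, 50, 50))),
               "field of view")
})

test_that("scene files round-trip through NIfTI with a JSON pose sidecar", {
  sc <- small_scene()
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  lab <- read_labelmap(file.path(dir, "scene_labels.nii.gz"))
  expect_identical(lab$data, sc$labels$data)
  side <- jsonlite::read_json(file.path(dir, "scene.json"), simplifyVector = TRUE)
  expect_equal(unlist(side$boxes$left$lo), sc$boxes$left$lo)
})

test_that("lifespan cohort follows its generating curves", {
  # noiseless cohort lies exactly on the curve
  sp0 <- lifespan_spec(n_subjects = 40, noise_sd = 0, seed = 2)
  tab0 <- make_lifespan_cohort(sp0)
  for (s in c("F", "M")) {
    sel <- tab0$region == "CA1" & tab0$sex == s
    expect_equal(tab0$volume_mm3[sel],
                 lifespan_curve(sp0, "CA1", s, tab0$age[sel]))
  }
  # decay after the knot: mean volume at 80-90 < mean at 55-65 (Monte-Carlo)
  tab <- make_lifespan_cohort(lifespan_spec(n_subjects = 1000, seed = 5))
  old <- tab$volume_mm3[tab$region == "DG" & tab$age >= 80 & tab$age <= 90]
  mid <- tab$volume_mm3[tab$region == "DG" & tab$age >= 55 & tab$age <= 65]
  expect_lt(mean(old), mean(mid))
  # +5% male plateau offset: pooled male mean > female mean on plateau ages
  plat <- tab[tab$region == "CA1" & tab$age >= 30 & tab$age <= 65, ]
  expect_gt(mean(plat$volume_mm3[plat$sex == "M"]),
            mean(plat$volume_mm3[plat$sex == "F"]))
  # volumes positive; determinism under seed
  expect_true(all(tab$volume_mm3 > 0))
  expect_identical(tab, make_lifespan_cohort(lifespan_spec(n_subjects = 1000,
                                                           seed = 5)))
  expect_error(lifespan_spec(noise_sd = -2), "noise_sd")
  expect_error(lifespan_spec(n_subjects = 5), "n_subjects")
})
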