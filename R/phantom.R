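# Synthetic hippocampus phantom generator.
#
# The phantom is a parametric curved tube (quadratically bent centerline)
# partitioned radially into a DG core surrounded by CA1/CA2/CA3/SUB angular
# sectors, with optional undifferentiated HEAD/TAIL caps along the
# longitudinal (anteroposterior) axis. Intensities follow class means times a
# smooth multiplicative bias field plus additive Gaussian noise. Everything is
# a pure function of (spec, seed).

#' Phantom specification
#'
#' @param grid_shape voxels per axis (each >= 16).
#' @param curvature scalar bend of the tube's centerline (0 = straight).
#' @param class_intensities named mean intensities (arbitrary units) for the
#'   canonical classes to carve; names among DG, CA1, CA2, CA3, SUB.
#' @param bg_intensity background mean intensity.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param bias_amplitude relative amplitude of the smooth multiplicative bias
#'   field (0 = flat).
#' @param include_head_tail carve undifferentiated HEAD/TAIL caps.
#' @param radius outer tube radius in voxels (default `min(grid_shape)/6`).
#' @param spacing voxel size in mm.
#' @param seed integer seed for the noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L), curvature = 0.35,
                         class_intensities = c(DG = 1.0, CA1 = 0.8, CA2 = 0.6,
                                               CA3 = 0.45, SUB = 0.3),
                         bg_intensity = 0.1, noise_sd = 0.05,
                         bias_amplitude = 0.2, include_head_tail = FALSE,
                         radius = NULL, spacing = c(1, 1, 1), seed = 1L) {
  assert_that(all(grid_shape >= 16), "grid_shape must be >= 16 per axis")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  bad <- setdiff(names(class_intensities), subfield_classes())
  if (length(bad) > 0)
    stopf("unknown classes in class_intensities: %s", paste(bad, collapse = ","))
  structure(list(grid_shape = as.integer(grid_shape), curvature = curvature,
                 class_intensities = class_intensities,
                 bg_intensity = bg_intensity, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 include_head_tail = isTRUE(include_head_tail),
                 radius = radius, spacing = spacing, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a hippocampus phantom
#'
#' Carves the curved-tube phantom described by `spec` and renders its
#' intensity volume: `intensity = class mean * bias field + noise`. The label
#' map is independent of the seed; only the noise varies.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume()]) and `labels` (a [labelmap()] with
#'   attributes `cap_masks` — voxel indices of the anatomical head/tail caps —
#'   and `t_star`, the longitudinal coordinate in \[0, 1\] of every foreground
#'   voxel).
#' @export
make_hippocampus_phantom <- function(spec) {
  gs <- spec$grid_shape
  r0 <- spec$radius %||% (min(gs) / 6)
  r_in <- 0.45 * r0
  pad <- max(3, ceiling(r0 * 0.6))
  nvox <- prod(gs)
  g <- voxel_grid(gs)
  X <- g[1, ]; Y <- g[2, ]; Z <- g[3, ]

  # centerline: longitudinal axis = axis 2 (anteroposterior), bend along axis 1
  nt <- 160L
  ts <- seq(0, 1, length.out = nt)
  y0 <- pad; y1 <- gs[2] - 1 - pad
  bend <- spec$curvature * gs[1] / 4
  cx <- gs[1] / 2 - bend * (1 / 3)  # center the bent tube
  px <- cx + bend * ((2 * ts - 1)^2 - 1 / 3)
  py <- y0 + ts * (y1 - y0)
  pz <- rep(gs[3] / 2, nt)

  best_d2 <- rep(Inf, nvox)
  best_i <- rep(1L, nvox)
  for (i in seq_len(nt)) {
    d2 <- (X - px[i])^2 + (Y - py[i])^2 + (Z - pz[i])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_i[upd] <- i
  }

  inside <- best_d2 <= r0^2
  tstar <- ts[best_i]
  # frames: tangent in x-y plane, normal = e_z, binormal = T x N
  txs <- 4 * bend * (2 * ts - 1); tys <- rep(y1 - y0, nt)
  tn <- sqrt(txs^2 + tys^2); txs <- txs / tn; tys <- tys / tn
  # d vector from nearest centerline point
  dx <- X - px[best_i]; dy <- Y - py[best_i]; dz <- Z - pz[best_i]
  # N = (0,0,1); B = T x N = (ty, -tx, 0)
  comp_n <- dz
  comp_b <- dx * tys[best_i] - dy * txs[best_i]
  theta <- atan2(comp_b, comp_n)

  lab <- integer(nvox)
  cc <- canonical_classes()
  core <- inside & best_d2 <= r_in^2
  ring <- inside & !core
  lab[core] <- cc[["DG"]]
  lab[ring & theta >= -pi & theta < -pi / 2] <- cc[["SUB"]]
  lab[ring & theta >= -pi / 2 & theta < 0] <- cc[["CA1"]]
  lab[ring & theta >= 0 & theta < pi / 2] <- cc[["CA2"]]
  lab[ring & theta >= pi / 2] <- cc[["CA3"]]

  head_vox <- which(inside & tstar < 0.15)
  tail_vox <- which(inside & tstar > 0.85)
  if (spec$include_head_tail) {
    lab[head_vox] <- cc[["HEAD"]]
    lab[tail_vox] <- cc[["TAIL"]]
  }

  want <- names(spec$class_intensities)
  if (spec$include_head_tail) want <- c(want, "HEAD", "TAIL")
  for (cls in want)
    if (!any(lab == cc[[cls]]))
      stopf("grid too small to carve class %s", cls)

  means <- c(spec$bg_intensity, rep(0, length(cc)))
  names(means) <- c("BG0", names(cc))
  for (cls in names(spec$class_intensities))
    means[cls] <- spec$class_intensities[[cls]]
  # caps render as the mean of the subfield intensities (mixed tissue)
  cap_mean <- mean(spec$class_intensities)
  means["HEAD"] <- cap_mean; means["TAIL"] <- cap_mean
  lut <- means[c("BG0", names(cc))[match(lab, c(0L, cc)) ]]

  xb <- 2 * X / (gs[1] - 1) - 1; yb <- 2 * Y / (gs[2] - 1) - 1
  zb <- 2 * Z / (gs[3] - 1) - 1
  q <- xb * yb + 0.5 * (xb^2 - zb^2)
  q <- q / max(abs(q))
  bias <- 1 + spec$bias_amplitude * q
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, rnorm(nvox, sd = spec$noise_sd)) else 0
  intens <- as.numeric(lut) * bias + noise

  schema <- cc[c("BG", "DG", "CA1", "CA2", "CA3", "SUB",
                 if (spec$include_head_tail) c("HEAD", "TAIL"))]
  lm <- labelmap(array(lab, dim = gs), spacing = spec$spacing, schema = schema)
  attr(lm, "cap_masks") <- list(head = head_vox, tail = tail_vox,
                                head_boundary_t = 0.15, tail_boundary_t = 0.85)
  attr(lm, "t_star") <- array(ifelse(inside, tstar, NA_real_), dim = gs)
  list(volume = volume(array(intens, dim = gs), spacing = spec$spacing),
       labels = lm)
}

#' Generate a cohort of phantoms with jittered geometry
#'
#' Draws per-subject curvature and radius jitter around the defaults plus
#' fresh noise, emulating anatomical variability across a training or test
#' cohort. Deterministic under the seed.
#'
#' @param n number of phantoms.
#' @param seed integer seed.
#' @param grid_shape voxels per axis.
#' @param include_head_tail carve HEAD/TAIL caps.
#' @return list of `list(volume, labels, spec)`.
#' @export
phantom_cohort <- function(n, seed = 1L, grid_shape = c(32L, 32L, 32L),
                           include_head_tail = FALSE) {
  pars <- with_seed(seed, list(curv = runif(n, 0.25, 0.45),
                               rad = runif(n, 0.9, 1.1) * min(grid_shape) / 6))
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(grid_shape = grid_shape, curvature = pars$curv[i],
                       radius = pars$rad[i],
                       include_head_tail = include_head_tail,
                       seed = seed + 1000L + i)
    c(make_hippocampus_phantom(sp), list(spec = sp))
  })
}

# ---- head scene -------------------------------------------------------------

default_scene_poses <- function(spec, scene_dim) {
  gs <- spec$grid_shape
  off_y <- (scene_dim[2] - gs[2]) %/% 2
  off_z <- (scene_dim[3] - gs[3]) %/% 2
  left <- affine_transform(diag(3), c(2, off_y, off_z))
  # right hippocampus is the mirror image across the mid-sagittal plane
  Mm <- diag(c(-1, 1, 1))
  right <- affine_transform(Mm, c(gs[1] - 1 + (scene_dim[1] - gs[1] - 2),
                                  off_y, off_z))
  list(left = left, right = right)
}

#' Build a synthetic head scene with bilateral phantoms
#'
#' Embeds a left and a (mirrored) right hippocampus phantom into a larger
#' "head" volume at known affine poses, and builds the paired template/atlas
#' scene at canonical pose. Atlas and scene labels encode side: left voxels
#' carry the canonical ids, right voxels the canonical ids + 10.
#'
#' @param spec a [phantom_spec()].
#' @param pose_left,pose_right [affine_transform()]s mapping phantom voxels to
#'   scene voxels; defaults place the phantoms in the two hemifields.
#' @param scene_dim scene grid (default 64^3).
#' @return list with `volume`, `labels`, `template`, `atlas`, `poses`, and the
#'   ground-truth bounding `boxes` per side.
#' @export
make_head_scene <- function(spec, pose_left = NULL, pose_right = NULL,
                            scene_dim = c(64L, 64L, 64L)) {
  poses <- default_scene_poses(spec, scene_dim)
  if (!is.null(pose_left)) poses$left <- pose_left
  if (!is.null(pose_right)) poses$right <- pose_right
  ph <- make_hippocampus_phantom(spec)
  ph0 <- make_hippocampus_phantom(
    phantom_spec(grid_shape = spec$grid_shape, curvature = spec$curvature,
                 class_intensities = spec$class_intensities,
                 bg_intensity = spec$bg_intensity, noise_sd = 0,
                 bias_amplitude = 0, include_head_tail = spec$include_head_tail,
                 radius = spec$radius, spacing = spec$spacing, seed = spec$seed))

  corners <- t(expand.grid(c(0, spec$grid_shape[1] - 1),
                           c(0, spec$grid_shape[2] - 1),
                           c(0, spec$grid_shape[3] - 1)))
  for (side in c("left", "right")) {
    mc <- apply_transform_coords(poses[[side]], corners)
    fg <- label_bounding_box(ph$labels$data, setdiff(ph$labels$schema, 0L))
    fgc <- t(expand.grid(c(fg$lo[1], fg$hi[1] - 1), c(fg$lo[2], fg$hi[2] - 1),
                         c(fg$lo[3], fg$hi[3] - 1)))
    mf <- apply_transform_coords(poses[[side]], fgc)
    if (any(mf < -0.5) || any(mf > scene_dim - 0.5))
      stopf("pose pushes the %s phantom outside the scene field of view", side)
  }

  build_scene <- function(phant, poses, noise_sd, seed_off) {
    sc_int <- head_background(scene_dim)
    sc_lab <- array(0L, dim = scene_dim)
    for (side in c("left", "right")) {
      pull <- invert_transform(poses[[side]])
      labs <- resample_array(phant$labels$data, pull, scene_dim,
                             method = "nearest", fill = 0)
      vals <- resample_array(phant$volume$data, pull, scene_dim,
                             method = "linear", fill = 0)
      sel <- labs > 0
      sc_int[sel] <- vals[sel]
      sc_lab[sel] <- as.integer(labs[sel]) + if (side == "right") 10L else 0L
    }
    if (noise_sd > 0)
      sc_int <- sc_int + with_seed(spec$seed + seed_off,
                                   rnorm(length(sc_int), sd = noise_sd))
    list(int = array(sc_int, dim = scene_dim), lab = sc_lab)
  }

  native <- build_scene(ph, poses, spec$noise_sd, seed_off = 101L)
  canon <- build_scene(ph0, default_scene_poses(spec, scene_dim), 0, 0L)

  schema <- ph$labels$schema
  schema2 <- c(schema, setNames(schema[schema > 0] + 10L,
                                paste0(names(schema[schema > 0]), "_R")))
  boxes <- list(
    left = label_bounding_box(native$lab, schema[schema > 0]),
    right = label_bounding_box(native$lab, schema[schema > 0] + 10L))
  list(volume = volume(native$int, spacing = spec$spacing),
       labels = labelmap(native$lab, spacing = spec$spacing, schema = schema2),
       template = volume(canon$int, spacing = spec$spacing),
       atlas = labelmap(canon$lab, spacing = spec$spacing, schema = schema2),
       poses = poses, boxes = boxes)
}

head_background <- function(scene_dim) {
  g <- voxel_grid(scene_dim)
  xb <- 2 * g[1, ] / (scene_dim[1] - 1) - 1
  yb <- 2 * g[2, ] / (scene_dim[2] - 1) - 1
  zb <- 2 * g[3, ] / (scene_dim[3] - 1) - 1
  r2 <- (xb / 0.92)^2 + (yb / 0.88)^2 + (zb / 0.85)^2
  bg <- ifelse(r2 <= 1, 0.12 + 0.04 * yb + 0.03 * zb, 0)
  array(bg, dim = scene_dim)
}

#' Save a scene to disk
#'
#' Writes NIfTI volume/label pairs plus a JSON sidecar holding the
#' ground-truth poses and boxes.
#'
#' @param scene result of [make_head_scene()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(file.path(dir, "scene.nii.gz"), scene$volume)
  write_labelmap(file.path(dir, "scene_labels.nii.gz"), scene$labels)
  write_volume(file.path(dir, "template.nii.gz"), scene$template)
  write_labelmap(file.path(dir, "atlas.nii.gz"), scene$atlas)
  side <- function(tr) list(M = tr$M, offset = tr$offset)
  jsonlite::write_json(
    list(poses = lapply(scene$poses, side),
         boxes = lapply(scene$boxes, function(b) list(lo = b$lo, hi = b$hi))),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---- protocol variants ------------------------------------------------------

#' Relabel a phantom label map as a given protocol's rater would have drawn it
#'
#' Merge groups collapse to the id of their first canonical member; with a
#' head/tail protocol, every voxel inside the anatomical head/tail caps is
#' relabelled HEAD/TAIL. Total foreground voxel count is conserved.
#'
#' @param lm a [labelmap()] produced by [make_hippocampus_phantom()].
#' @param protocol a [protocol_spec()].
#' @return the relabelled [labelmap()].
#' @export
make_protocol_variants <- function(lm, protocol) {
  cc <- canonical_classes()
  lab <- lm$data
  schema <- lm$schema
  for (grp in protocol$merge_groups) {
    ids <- cc[grp]
    keep <- min(ids)
    lab[lab %in% ids] <- keep
    schema <- schema[!(schema %in% setdiff(ids, keep))]
    names(schema)[schema == keep] <- paste(grp, collapse = "-")
  }
  if (protocol$head_tail) {
    caps <- attr(lm, "cap_masks")
    if (is.null(caps))
      stopf("label map carries no head/tail cap geometry; cannot apply a head/tail protocol")
    lab[caps$head] <- cc[["HEAD"]]
    lab[caps$tail] <- cc[["TAIL"]]
    for (cap in c("HEAD", "TAIL"))
      if (!cap %in% names(schema)) schema <- c(schema, cc[cap])
  }
  out <- labelmap(lab, lm$spacing, lm$affine, schema)
  attr(out, "cap_masks") <- attr(lm, "cap_masks")
  attr(out, "t_star") <- attr(lm, "t_star")
  out
}
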