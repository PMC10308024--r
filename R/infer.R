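# Inference: test-time augmentation, ensemble fusion by voxel-wise plurality
# vote, and the vote-entropy uncertainty map.
#
# Augmented predictions are mapped back to native crop space before voting.
# Flips and affines are inverted exactly; elastic deformations via the
# negated-displacement approximation.

#' Test-time augmentation configuration
#'
#' @param n_versions augmented copies per input (default 21; version 1 is
#'   always the identity).
#' @param flip_prob probability of a horizontal (left-right axis) flip.
#' @param rot_deg maximum rotation per axis, degrees.
#' @param scale_range isotropic scale range.
#' @param elastic_max maximum control-point displacement, voxels (0 disables).
#' @param elastic_grid control grid points per axis.
#' @param seed integer seed.
#' @return a `tta_config` list.
#' @export
tta_config <- function(n_versions = 21L, flip_prob = 0.5, rot_deg = 10,
                       scale_range = c(0.95, 1.05), elastic_max = 2,
                       elastic_grid = 4L, seed = 1L) {
  assert_that(n_versions >= 1, "n_versions must be >= 1")
  assert_that(all(scale_range > 0), "non-invertible transform: scale must be > 0")
  assert_that(elastic_max >= 0 && elastic_grid >= 2,
              "invalid elastic parameters")
  structure(list(n_versions = as.integer(n_versions), flip_prob = flip_prob,
                 rot_deg = rot_deg, scale_range = scale_range,
                 elastic_max = elastic_max, elastic_grid = as.integer(elastic_grid),
                 seed = as.integer(seed)),
            class = "tta_config")
}

identity_tta_record <- function(dims) {
  list(flip = FALSE, affine = NULL, disp = NULL, dims = dims)
}

random_tta_record <- function(dims, cfg) {
  rec <- identity_tta_record(dims)
  rec$flip <- runif(1) < cfg$flip_prob
  ang <- runif(3, -cfg$rot_deg, cfg$rot_deg) * pi / 180
  sc <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
  center <- (dims - 1) / 2
  M <- rotation_matrix(ang) * sc
  rec$affine <- affine_transform(M, center - as.numeric(M %*% center))
  if (cfg$elastic_max > 0) {
    ng <- cfg$elastic_grid
    rec$disp <- lapply(1:3, function(a) {
      ctrl <- array(runif(ng^3, -cfg$elastic_max, cfg$elastic_max),
                    dim = rep(ng, 3))
      scale_tr <- affine_transform(diag((ng - 1) / (dims - 1)), c(0, 0, 0))
      resample_array(ctrl, scale_tr, dims, method = "linear", fill = 0)
    })
  }
  rec
}

flip_coords <- function(coords, dims, flip) {
  if (flip) coords[1, ] <- dims[1] - 1 - coords[1, ]
  coords
}

# Pull map of the augmentation: augmented voxel u -> native crop coordinate.
tta_pull_coords <- function(rec, coords) {
  if (!is.null(rec$disp)) {
    # elastic pull: sample displacement at the augmented voxel itself
    for (a in 1:3)
      coords[a, ] <- coords[a, ] + as.numeric(rec$disp[[a]])
  }
  if (!is.null(rec$affine))
    coords <- apply_transform_coords(invert_transform(rec$affine), coords)
  flip_coords(coords, rec$dims, rec$flip)
}

# Approximate inverse map: native voxel v -> augmented-space coordinate, used
# to realign predictions before voting.
tta_push_coords <- function(rec, coords) {
  coords <- flip_coords(coords, rec$dims, rec$flip)
  if (!is.null(rec$affine))
    coords <- apply_transform_coords(rec$affine, coords)
  if (!is.null(rec$disp)) {
    for (a in 1:3) {
      dv <- cpp_sample_at(as.numeric(rec$disp[[a]]), rec$dims, coords, 1L, 0)
      coords[a, ] <- coords[a, ] - dv
    }
  }
  coords
}

#' Apply a TTA transform to a crop
#'
#' @param x 3D numeric array.
#' @param rec a transform record from [tta_augment()].
#' @param method `"linear"` for intensities, `"nearest"` for labels.
#' @param fill out-of-view fill value.
#' @return transformed array.
#' @export
tta_apply <- function(x, rec, method = c("linear", "nearest"), fill = 0) {
  method <- match.arg(method)
  g <- voxel_grid(dim(x))
  src <- tta_pull_coords(rec, g)
  vals <- cpp_sample_at(as.numeric(x), dim(x), src,
                        if (method == "nearest") 0L else 1L, fill)
  array(vals, dim = dim(x))
}

#' Map an augmented-space label map back to native crop space
#'
#' @param labels integer array in augmented space.
#' @param rec the transform record used to create that version.
#' @param fill label for voxels mapping outside the augmented grid.
#' @return realigned integer array.
#' @export
tta_realign_labels <- function(labels, rec, fill = 0L) {
  g <- voxel_grid(dim(labels))
  src <- tta_push_coords(rec, g)
  vals <- cpp_sample_at(as.numeric(labels), dim(labels), src, 0L, fill)
  array(as.integer(vals), dim = dim(labels))
}

#' Generate the test-time augmentation stack for a crop
#'
#' Produces exactly `n_versions` copies; the first is the identity, the rest
#' draw a random flip, affine and elastic deformation each. Every version
#' carries the record needed to map a prediction back to native space.
#'
#' @param crop 3D numeric array (preprocessed crop).
#' @param cfg a [tta_config()].
#' @return list of `list(data, record)`.
#' @export
tta_augment <- function(crop, cfg = tta_config()) {
  dims <- dim(crop)
  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_versions), function(i) {
      rec <- if (i == 1) identity_tta_record(dims)
             else random_tta_record(dims, cfg)
      data <- if (i == 1) crop else tta_apply(crop, rec)
      list(data = data, record = rec)
    })
  })
}

# ---- vote fusion ------------------------------------------------------------

#' Voxel-wise plurality vote
#'
#' Assigns to every voxel the most frequent class in its vote stack; ties are
#' broken toward the lowest class id.
#'
#' @param votes integer matrix (n_votes x n_voxels) of class labels.
#' @param classes class ids in the ensemble's label space (default: observed).
#' @return integer vector of fused labels (length n_voxels).
#' @export
plurality_vote <- function(votes, classes = sort(unique(as.integer(votes)))) {
  votes <- as.matrix(votes)
  if (nrow(votes) == 0 || ncol(votes) == 0) stopf("empty vote stack")
  classes <- sort(as.integer(classes))
  cnt <- cpp_vote_counts(votes, classes)
  best <- cnt[1, ]
  fused <- rep(classes[1], ncol(votes))
  for (k in seq_along(classes)[-1]) {
    upd <- cnt[k, ] > best
    best[upd] <- cnt[k, upd]
    fused[upd] <- classes[k]
  }
  fused
}

#' Voxel-wise vote entropy (aleatoric uncertainty)
#'
#' `H = -sum_m p_m log(p_m)` where `p_m` is the frequency of the m-th unique
#' voted class at that voxel; 0 under unanimity, at most `log(n_classes)`.
#'
#' @param votes integer matrix (n_votes x n_voxels).
#' @param classes class ids (default: observed).
#' @return numeric vector of entropies (nats).
#' @export
uncertainty_map <- function(votes, classes = sort(unique(as.integer(votes)))) {
  votes <- as.matrix(votes)
  if (nrow(votes) == 0 || ncol(votes) == 0) stopf("empty vote stack")
  cnt <- cpp_vote_counts(votes, sort(as.integer(classes)))
  p <- cnt / nrow(votes)
  pl <- p * log(p)
  pl[p == 0] <- 0
  -.colSums(pl, nrow(pl), ncol(pl))
}

# ---- end-to-end segmentation ------------------------------------------------

#' Segment a preprocessed crop with a model ensemble
#'
#' Runs every ensemble member on every TTA version, realigns the predicted
#' label maps to native crop space, fuses them by plurality vote and computes
#' the vote-entropy map.
#'
#' @param crop 3D numeric array (Z-normalized, padded).
#' @param ensemble an `ensemble` from [train_ensemble()], or list of models.
#' @param tta_cfg a [tta_config()].
#' @return list with `labels` (integer array), `uncertainty` (numeric array),
#'   `votes` (matrix) and `n_votes`.
#' @export
segment_crop <- function(crop, ensemble, tta_cfg = tta_config()) {
  models <- if (inherits(ensemble, "ensemble")) ensemble$members else ensemble
  versions <- tta_augment(crop, tta_cfg)
  n_classes <- models[[1]]$config$n_classes
  classes <- 0:(n_classes - 1)
  votes <- matrix(0L, length(models) * length(versions), length(crop))
  row <- 1L
  for (v in versions) {
    for (m in models) {
      prob <- model_forward(m, v$data)
      pred <- array(max.col(t(matrix(prob, n_classes, length(crop))),
                            ties.method = "first") - 1L, dim = dim(crop))
      realigned <- if (is.null(v$record$affine) && !v$record$flip &&
                       is.null(v$record$disp)) pred
                   else tta_realign_labels(pred, v$record)
      votes[row, ] <- as.integer(realigned)
      row <- row + 1L
    }
  }
  fused <- plurality_vote(votes, classes)
  unc <- uncertainty_map(votes, classes)
  list(labels = array(fused, dim = dim(crop)),
       uncertainty = array(unc, dim = dim(crop)),
       votes = votes, n_votes = nrow(votes))
}

#' Full segmentation pipeline on a native volume
#'
#' Registration, bilateral ROI extraction, per-side TTA-ensemble prediction,
#' and re-embedding of the fused labels and uncertainty into the native grid.
#' Right-side crops can optionally be mirrored to left chirality before
#' prediction (`mirror_right`, default off).
#'
#' @param vol native [volume()].
#' @param ensemble trained ensemble.
#' @param template,atlas template volume and side-coded atlas label map.
#' @param roi_cfg a [roi_config()].
#' @param tta_cfg a [tta_config()].
#' @param mirror_right mirror right crops to left chirality.
#' @return list with `labels` ([labelmap()]; right side offset by 10),
#'   `uncertainty` ([volume()]), `boxes`, `transform`.
#' @export
segment <- function(vol, ensemble, template, atlas, roi_cfg = roi_config(),
                    tta_cfg = tta_config(), mirror_right = FALSE) {
  ext <- extract_hippocampi(vol, template, atlas, roi_cfg)
  seg_full <- array(0L, dim = dim(vol$data))
  unc_full <- array(0, dim = dim(vol$data))
  for (side in c("left", "right")) {
    crop <- ext[[side]]
    x <- crop$data
    if (side == "right" && mirror_right)
      x <- x[dim(x)[1]:1, , , drop = FALSE]
    res <- segment_crop(x, ensemble, tta_cfg)
    lab <- res$labels; unc <- res$uncertainty
    if (side == "right" && mirror_right) {
      lab <- lab[dim(lab)[1]:1, , , drop = FALSE]
      unc <- unc[dim(unc)[1]:1, , , drop = FALSE]
    }
    p <- attr(crop, "pad")
    d <- dim(lab)
    lab <- lab[(p$lo[1] + 1):(d[1] - p$hi[1]), (p$lo[2] + 1):(d[2] - p$hi[2]),
               (p$lo[3] + 1):(d[3] - p$hi[3]), drop = FALSE]
    unc <- unc[(p$lo[1] + 1):(d[1] - p$hi[1]), (p$lo[2] + 1):(d[2] - p$hi[2]),
               (p$lo[3] + 1):(d[3] - p$hi[3]), drop = FALSE]
    box <- attr(crop, "crop_box")
    off <- if (side == "right") 10L else 0L
    sl <- list((box$lo[1] + 1):box$hi[1], (box$lo[2] + 1):box$hi[2],
               (box$lo[3] + 1):box$hi[3])
    sub <- seg_full[sl[[1]], sl[[2]], sl[[3]]]
    sub[lab > 0] <- lab[lab > 0] + off
    seg_full[sl[[1]], sl[[2]], sl[[3]]] <- sub
    unc_full[sl[[1]], sl[[2]], sl[[3]]] <- pmax(
      unc_full[sl[[1]], sl[[2]], sl[[3]]], unc)
  }
  list(labels = labelmap(seg_full, vol$spacing, vol$affine,
                         schema = canonical_classes()),
       uncertainty = volume(unc_full, vol$spacing, vol$affine),
       boxes = ext$boxes, transform = ext$transform)
}
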