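# ROI localization: template-to-native registration, atlas back-projection of
# the hippocampus boxes with a safety margin, and the crop / Z-normalize / pad
# preprocessing chain.

#' ROI extraction configuration
#'
#' @param margin voxels added on every side of the projected atlas hull
#'   (default 16).
#' @param pad_multiple pad crops so each dimension divides this (default 8).
#' @param registration_kind `"rigid"` (translation + rotation) or `"affine"`
#'   (adds per-axis scaling).
#' @return a `roi_config` list.
#' @export
roi_config <- function(margin = 16L, pad_multiple = 8L,
                       registration_kind = c("affine", "rigid")) {
  assert_that(margin >= 0, "margin must be >= 0")
  assert_that(pad_multiple >= 1, "pad_multiple must be >= 1")
  structure(list(margin = as.integer(margin),
                 pad_multiple = as.integer(pad_multiple),
                 registration_kind = match.arg(registration_kind)),
            class = "roi_config")
}

rotation_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1]); cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

params_to_transform <- function(par, kind, center) {
  t <- par[1:3]
  R <- rotation_matrix(par[4:6])
  A <- if (kind == "affine") R %*% diag(exp(par[7:9])) else R
  affine_transform(A, center + t - as.numeric(A %*% center))
}

downsample2 <- function(x) {
  d <- dim(x)
  d2 <- d %/% 2L
  x <- x[seq_len(2 * d2[1]), seq_len(2 * d2[2]), seq_len(2 * d2[3]), drop = FALSE]
  e <- x[seq(1, 2 * d2[1], 2), , , drop = FALSE] + x[seq(2, 2 * d2[1], 2), , , drop = FALSE]
  e <- e[, seq(1, 2 * d2[2], 2), , drop = FALSE] + e[, seq(2, 2 * d2[2], 2), , drop = FALSE]
  e <- e[, , seq(1, 2 * d2[3], 2), drop = FALSE] + e[, , seq(2, 2 * d2[3], 2), drop = FALSE]
  e / 8
}

#' Register a template to a target volume
#'
#' Built-in multi-resolution optimization of the mean-squared intensity
#' difference over rigid or affine parameters, adequate for synthetic scenes;
#' external registration tools can be substituted by supplying any
#' [affine_transform()] downstream.
#'
#' @param template a [volume()] (moving image).
#' @param target a [volume()] (fixed image), same grid geometry family.
#' @param kind `"rigid"` or `"affine"`.
#' @param levels number of pyramid levels (coarse-to-fine).
#' @param maxit optimizer iterations per level.
#' @return an [affine_transform()] mapping template voxels to target voxels,
#'   with attribute `objective` (final mean-squared error).
#' @export
register_affine <- function(template, target, kind = c("affine", "rigid"),
                            levels = 3L, maxit = 300L) {
  kind <- match.arg(kind)
  assert_that(sd(template$data) > 0 && sd(target$data) > 0,
              "volumes must be non-constant")
  np <- if (kind == "affine") 9L else 6L
  par <- numeric(np)
  pyr_t <- list(template$data); pyr_g <- list(target$data)
  for (l in seq_len(levels - 1)) {
    pyr_t[[l + 1]] <- downsample2(pyr_t[[l]])
    pyr_g[[l + 1]] <- downsample2(pyr_g[[l]])
  }
  scales <- c(rep(0.2, 3), rep(0.05, 3), rep(0.05, 3))[seq_len(np)]
  for (l in rev(seq_len(levels))) {
    f <- 2^(l - 1)
    tpl <- pyr_t[[l]]; tgt <- pyr_g[[l]]
    center <- (dim(tgt) - 1) / 2
    grid <- voxel_grid(dim(tgt))
    tgt_v <- as.numeric(tgt)
    obj <- function(p) {
      p_full <- p
      p_full[1:3] <- p[1:3]  # translation expressed at this level
      tr <- params_to_transform(p_full, kind, center)
      src <- apply_transform_coords(invert_transform(tr), grid)
      v <- cpp_sample_at(as.numeric(tpl), dim(tpl), src, 1L, NA_real_)
      ok <- !is.na(v)
      if (mean(ok) < 0.2) return(1e6)
      mean((v[ok] - tgt_v[ok])^2)
    }
    par_l <- par; par_l[1:3] <- par[1:3] / f
    fit <- optim(par_l, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, parscale = pmax(scales, 1e-3)))
    par <- fit$par; par[1:3] <- fit$par[1:3] * f
    final_obj <- fit$value
  }
  if (!is.finite(final_obj))
    stopf("registration failed to converge (objective = %g)", final_obj)
  center <- (dim(target$data) - 1) / 2
  tr <- params_to_transform(par, kind, center)
  attr(tr, "objective") <- final_obj
  attr(tr, "params") <- par
  tr
}

#' Locate the bilateral hippocampus boxes in native space
#'
#' Maps the atlas ROI voxels through the template-to-native transform, takes
#' the axis-aligned hull per side, expands it by the configured margin on
#' every side and clamps it to the native grid. Sides are always returned in
#' fixed (left, right) order.
#'
#' @param atlas a [labelmap()] on the template grid.
#' @param transform [affine_transform()] from [register_affine()].
#' @param roi_labels list with integer vectors `left` and `right`.
#' @param config a [roi_config()].
#' @param grid_dim native image dimensions (for clamping).
#' @return list of [bounding_box()]es `left` and `right`.
#' @export
locate_roi <- function(atlas, transform, roi_labels, config, grid_dim) {
  arr <- atlas$data
  one_side <- function(ids) {
    idx <- which(array(arr %in% ids, dim = dim(arr)), arr.ind = TRUE)
    if (nrow(idx) == 0)
      stopf("empty ROI: atlas has no voxel with labels %s",
            paste(ids, collapse = ","))
    mapped <- apply_transform_coords(transform, t(idx) - 1)
    lo <- floor(apply(mapped, 1, min))
    hi <- floor(apply(mapped, 1, max)) + 1
    expand_box(bounding_box(lo, hi), config$margin, grid_dim)
  }
  list(left = one_side(roi_labels$left), right = one_side(roi_labels$right))
}

#' Extract, normalize and pad both hippocampus crops
#'
#' The full ROI localization chain: register the template to the native
#' volume, back-project the atlas hippocampus labels, crop each side with the
#' safety margin, Z-normalize, and pad to the configured multiple.
#'
#' @param vol native [volume()].
#' @param template template [volume()].
#' @param atlas template-space [labelmap()] (left ids 1-7, right ids 11-17).
#' @param config a [roi_config()].
#' @param roi_labels per-side atlas label ids.
#' @return list with `left`, `right` (preprocessed crops), `boxes`,
#'   `transform`.
#' @export
extract_hippocampi <- function(vol, template, atlas, config = roi_config(),
                               roi_labels = list(left = 1:7, right = 11:17)) {
  tr <- register_affine(template, vol, kind = config$registration_kind)
  boxes <- locate_roi(atlas, tr, roi_labels, config, dim(vol$data))
  prep <- function(box) {
    pad_to_multiple(z_normalize(crop_volume(vol, box)), config$pad_multiple)
  }
  list(left = prep(boxes$left), right = prep(boxes$right),
       boxes = boxes, transform = tr)
}
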