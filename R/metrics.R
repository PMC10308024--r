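# Benchmarking metrics: Dice coefficient, Hausdorff distance, volumetric
# similarity, per label and per segmentation pair.

#' Dice coefficient between two masks
#'
#' `DC = 2|ym intersect yp| / (|ym| + |yp|)`.
#'
#' @param ym,yp logical arrays (or 0/1) on the same grid.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(ym, yp) {
  ym <- as.logical(ym); yp <- as.logical(yp)
  nm <- sum(ym); np <- sum(yp)
  if (nm + np == 0) stopf("undefined DC: both masks are empty")
  2 * sum(ym & yp) / (nm + np)
}

#' Hausdorff distance between two masks
#'
#' Symmetric Hausdorff distance `HD = max(hd(ym, yp), hd(yp, ym))` with
#' `hd(X, Y) = max_x min_y ||x - y||_2`, computed between voxel-center point
#' sets of the full masks (all mask voxels), scaled by the voxel spacing.
#' `surface = TRUE` restricts the point sets to boundary voxels (a labelled
#' extra, off by default).
#'
#' @param ym,yp logical arrays on the same grid.
#' @param spacing mm per voxel per axis (default unit voxels).
#' @param surface use only surface voxels of each mask.
#' @return distance (physical units when spacing given, voxels otherwise).
#' @export
hausdorff <- function(ym, yp, spacing = c(1, 1, 1), surface = FALSE) {
  ym <- array(as.logical(ym), dim = dim(ym) %||% length(ym))
  yp <- array(as.logical(yp), dim = dim(yp) %||% length(yp))
  if (!any(ym) || !any(yp)) stopf("Hausdorff distance needs non-empty masks")
  if (surface) { ym <- surface_mask(ym); yp <- surface_mask(yp) }
  pts <- function(m) {
    ix <- which(m, arr.ind = TRUE)
    if (is.null(dim(ix))) ix <- matrix(ix, ncol = 1)
    sweep(ix - 1, 2, spacing[seq_len(ncol(ix))], `*`)
  }
  max(cpp_hausdorff(pts(ym), pts(yp)))
}

surface_mask <- function(m) {
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  shift_and <- function(acc, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx; src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1), d[ax])
    acc & m[src[[1]], src[[2]], src[[3]]]
  }
  for (ax in seq_along(d)) for (by in c(-1, 1))
    interior <- shift_and(interior, ax, by)
  m & !(interior & m)
}

#' Volumetric similarity between two masks
#'
#' `VS = 1 - ||ym| - |yp|| / (|ym| + |yp|)`: agreement of the two volumes
#' irrespective of overlap, 1 for equal volumes, 0 when one mask is empty.
#'
#' @param ym,yp logical arrays.
#' @return scalar in \[0, 1\].
#' @export
volumetric_similarity <- function(ym, yp) {
  nm <- sum(as.logical(ym)); np <- sum(as.logical(yp))
  if (nm + np == 0) stopf("undefined VS: both masks are empty")
  1 - abs(nm - np) / (nm + np)
}

#' Evaluate a predicted segmentation against a reference
#'
#' Computes DC, HD and VS for every requested label. Labels absent from both
#' maps are reported as `NA`; labels absent from exactly one map get
#' `DC = 0`, `VS = 0` and `HD = NA` (undefined for an empty point set).
#'
#' @param pred,ref [labelmap()]s (or integer arrays) on the same grid.
#' @param labels integer label ids to score.
#' @param spacing mm per voxel (taken from `ref` when it is a labelmap).
#' @return a `data.frame` with one row per label: `label`, `DC`, `HD`, `VS`,
#'   `n_ref`, `n_pred`.
#' @export
evaluate_pair <- function(pred, ref, labels, spacing = NULL) {
  parr <- if (inherits(pred, "volume")) pred$data else pred
  rarr <- if (inherits(ref, "volume")) ref$data else ref
  assert_that(all(dim(parr) == dim(rarr)), "grid mismatch between pred and ref")
  if (is.null(spacing))
    spacing <- if (inherits(ref, "volume")) ref$spacing else c(1, 1, 1)
  rows <- lapply(labels, function(l) {
    mp <- parr == l; mr <- rarr == l
    np <- sum(mp); nr <- sum(mr)
    if (np + nr == 0)
      return(data.frame(label = l, DC = NA_real_, HD = NA_real_,
                        VS = NA_real_, n_ref = 0L, n_pred = 0L))
    data.frame(label = l,
               DC = dice(mr, mp),
               HD = if (np > 0 && nr > 0) hausdorff(mr, mp, spacing) else NA_real_,
               VS = volumetric_similarity(mr, mp),
               n_ref = nr, n_pred = np)
  })
  do.call(rbind, rows)
}
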