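# Core containers: Volume (3D scalar image + spacing + affine), LabelMap
# (integer segmentation + label schema), BoundingBox (0-based, half-open),
# AffineTransform (voxel-to-voxel map), and NIfTI round-trip I/O.

#' Construct a Volume
#'
#' @param data 3D numeric array.
#' @param spacing voxel size in mm per axis (positive).
#' @param affine 4x4 voxel-to-world matrix (RAS+); default built from spacing.
#' @return a `volume` object.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  assert_that(length(dim(data)) == 3, "expected 3D data, got %dD",
              length(dim(data)))
  assert_that(all(spacing > 0), "spacing must be > 0 on all axes")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
  }
  assert_that(abs(det(affine)) > 1e-12, "affine must be invertible")
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "volume")
}

#' Construct a LabelMap
#'
#' @param data 3D integer array of labels.
#' @param spacing voxel size in mm per axis.
#' @param affine 4x4 voxel-to-world matrix.
#' @param schema named integer vector mapping class names to label ids.
#' @return a `labelmap` object.
#' @export
labelmap <- function(data, spacing = c(1, 1, 1), affine = NULL,
                     schema = canonical_classes()) {
  v <- volume(data, spacing, affine)
  v$data <- array(as.integer(v$data), dim = dim(v$data))
  v$schema <- schema
  class(v) <- c("labelmap", "volume")
  v
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

# ---- NIfTI I/O --------------------------------------------------------------

#' Read a 3D NIfTI volume
#'
#' @param path path to a NIfTI-1/2 file (.nii or .nii.gz).
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) { img <- img[, , , 1]; d <- dim(img) }
  assert_that(length(d) == 3, "expected 3D NIfTI payload, got %dD", length(d))
  af <- unclass(RNifti::xform(img))
  attributes(af) <- list(dim = dim(af))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  volume(arr, spacing = as.numeric(RNifti::pixdim(img)[1:3]), affine = af)
}

#' @rdname read_volume
#' @param schema label schema to attach.
#' @export
read_labelmap <- function(path, schema = canonical_classes()) {
  v <- read_volume(path)
  labelmap(round(v$data), v$spacing, v$affine, schema)
}

write_nifti_impl <- function(path, v) {
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::qform(img) <- structure(v$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a volume or label map to NIfTI
#'
#' Round-trip write-then-read preserves data, spacing and affine to float
#' tolerance.
#'
#' @param path destination path (.nii or .nii.gz).
#' @param v a [volume()] or [labelmap()].
#' @return the path, invisibly.
#' @export
write_volume <- function(path, v) write_nifti_impl(path, v)

#' @rdname write_volume
#' @export
write_labelmap <- function(path, v) write_nifti_impl(path, v)

# ---- bounding boxes ---------------------------------------------------------

#' Bounding box (0-based, half-open)
#'
#' @param lo inclusive lower voxel index per axis.
#' @param hi exclusive upper voxel index per axis.
#' @return a `bounding_box` object.
#' @export
bounding_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  assert_that(all(lo < hi), "bounding box must satisfy lo < hi per axis")
  structure(list(lo = lo, hi = hi), class = "bounding_box")
}

expand_box <- function(box, margin, grid_dim) {
  bounding_box(pmax(box$lo - margin, 0L), pmin(box$hi + margin, grid_dim))
}

#' Axis-aligned hull of a label set
#'
#' @param lm a [labelmap()] or integer array.
#' @param labels label ids defining the region.
#' @return a [bounding_box()], or error if the region is empty.
#' @export
label_bounding_box <- function(lm, labels) {
  arr <- if (inherits(lm, "volume")) lm$data else lm
  idx <- which(array(arr %in% labels, dim = dim(arr)), arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("empty ROI: no voxel carries labels %s",
                            paste(labels, collapse = ","))
  bounding_box(apply(idx, 2, min) - 1L, apply(idx, 2, max))
}

#' Crop a volume to a bounding box
#'
#' The crop records its box so it can later be re-embedded in the native grid.
#'
#' @param v a [volume()] or [labelmap()].
#' @param box a [bounding_box()].
#' @return the cropped object, with attribute `crop_box`.
#' @export
crop_volume <- function(v, box) {
  d <- v$data[(box$lo[1] + 1):box$hi[1], (box$lo[2] + 1):box$hi[2],
              (box$lo[3] + 1):box$hi[3], drop = FALSE]
  out <- v
  out$data <- d
  out$affine[1:3, 4] <- (v$affine %*% c(box$lo, 1))[1:3]
  attr(out, "crop_box") <- box
  out
}

# ---- preprocessing ----------------------------------------------------------

#' Z-normalize a crop
#'
#' Rescales intensities to zero mean and unit standard deviation over all
#' voxels of the crop. Invariant to positive affine intensity changes.
#'
#' @param v a [volume()].
#' @return the normalized volume.
#' @export
z_normalize <- function(v) {
  x <- v$data
  assert_that(length(x) > 1, "crop must have more than one voxel")
  s <- sd(x)
  if (s == 0) stopf("degenerate crop: constant intensity")
  v$data <- (x - mean(x)) / s
  v
}

#' Pad a volume so each dimension is a multiple of m
#'
#' Pads with zeros (the post-normalization background value), centering the
#' original data; the pad amounts are recorded for exact inverse cropping.
#' Idempotent.
#'
#' @param v a [volume()] or [labelmap()].
#' @param m the divisor (default 8).
#' @return padded object with attribute `pad` (`lo`/`hi` amounts per axis).
#' @export
pad_to_multiple <- function(v, m = 8L) {
  assert_that(m >= 1, "m must be >= 1")
  d <- dim(v$data)
  target <- ceiling(d / m) * m
  extra <- target - d
  lo <- extra %/% 2L
  hi <- extra - lo
  out <- v
  if (any(extra > 0)) {
    arr <- array(if (inherits(v, "labelmap")) 0L else 0, dim = target)
    arr[(lo[1] + 1):(lo[1] + d[1]), (lo[2] + 1):(lo[2] + d[2]),
        (lo[3] + 1):(lo[3] + d[3])] <- v$data
    out$data <- arr
    out$affine[1:3, 4] <- (v$affine %*% c(-lo, 1))[1:3]
  }
  attr(out, "pad") <- list(lo = as.integer(lo), hi = as.integer(hi))
  attr(out, "crop_box") <- attr(v, "crop_box")
  out
}

#' Undo [pad_to_multiple()]
#'
#' @param v a padded volume carrying a `pad` attribute.
#' @return the original-extent volume.
#' @export
unpad_volume <- function(v) {
  p <- attr(v, "pad")
  assert_that(!is.null(p), "volume has no pad record")
  d <- dim(v$data)
  out <- v
  out$data <- v$data[(p$lo[1] + 1):(d[1] - p$hi[1]),
                     (p$lo[2] + 1):(d[2] - p$hi[2]),
                     (p$lo[3] + 1):(d[3] - p$hi[3]), drop = FALSE]
  out$affine[1:3, 4] <- (v$affine %*% c(p$lo, 1))[1:3]
  attr(out, "pad") <- NULL
  out
}

# ---- affine voxel-space transforms -----------------------------------------

#' Affine voxel-to-voxel transform
#'
#' Maps source voxel coordinates to destination voxel coordinates:
#' `v_dst = M v_src + offset` (0-based coordinates).
#'
#' @param M 3x3 matrix.
#' @param offset length-3 translation.
#' @return an `affine_transform`.
#' @export
affine_transform <- function(M = diag(3), offset = c(0, 0, 0)) {
  assert_that(abs(det(M)) > 1e-12, "transform must be invertible")
  structure(list(M = M, offset = as.numeric(offset)), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\nM:\n"); print(signif(x$M, 5))
  cat("offset:", signif(x$offset, 5), "\n")
  invisible(x)
}

invert_transform <- function(tr) {
  Mi <- solve(tr$M)
  affine_transform(Mi, -as.numeric(Mi %*% tr$offset))
}

compose_transform <- function(a, b) {
  # apply b first, then a
  affine_transform(a$M %*% b$M, as.numeric(a$M %*% b$offset) + a$offset)
}

apply_transform_coords <- function(tr, coords) {
  tr$M %*% coords + tr$offset
}

voxel_grid <- function(dims) {
  D <- dims[1]; H <- dims[2]; W <- dims[3]
  rbind(rep(0:(D - 1), times = H * W),
        rep(rep(0:(H - 1), each = D), times = W),
        rep(0:(W - 1), each = D * H))
}

# Resample `data` (3D array) onto a destination grid of `out_dim`, where the
# destination-to-source voxel map is `pull` (an affine_transform or a function
# on 3xN coordinate matrices).
resample_array <- function(data, pull, out_dim, method = c("linear", "nearest"),
                           fill = 0) {
  method <- match.arg(method)
  g <- voxel_grid(out_dim)
  src <- if (inherits(pull, "affine_transform"))
    apply_transform_coords(pull, g) else pull(g)
  vals <- cpp_sample_at(as.numeric(data), dim(data), src,
                        if (method == "nearest") 0L else 1L, fill)
  array(vals, dim = out_dim)
}
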