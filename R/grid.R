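#' Brain sampling grid
#'
#' A `brain_grid` couples a 3D array shape with a NIfTI s-form affine that
#' maps zero-based voxel offsets to MNI world millimetres.  All public voxel
#' indices in this package are 1-based (R array convention); the affine is
#' applied to `index - 1` internally.  An optional set of reference voxel
#' indices (the "target" voxels of co-activation profiles, typically a
#' gray-matter mask) can be attached.
#'
#' @param shape integer vector of length 3, array dimensions.
#' @param affine 4x4 voxel-to-mm transform (NIfTI s-form convention,
#'   zero-based indices); must be invertible.
#' @param reference_indices optional integer vector of 1-based linear array
#'   indices defining the reference (target) voxels.
#' @return An object of class `brain_grid`.
#' @export
brain_grid <- function(shape, affine, reference_indices = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  g <- structure(list(shape = shape, affine = affine,
                      reference_indices = NULL),
                 class = "brain_grid")
  if (!is.null(reference_indices))
    g$reference_indices <- .check_linear_indices(reference_indices, shape)
  g
}

.check_linear_indices <- function(idx, shape) {
  idx <- as.integer(idx)
  if (anyDuplicated(idx)) stop("reference indices must be unique")
  if (any(idx < 1L) || any(idx > prod(shape)))
    stop("reference indices out of grid bounds")
  idx
}

#' @export
print.brain_grid <- function(x, ...) {
  cat("Brain grid:", paste(x$shape, collapse = " x "), "voxels\n")
  vd <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat("  voxel size (mm):", paste(signif(vd, 4), collapse = " x "), "\n")
  if (!is.null(x$reference_indices))
    cat("  reference voxels:", length(x$reference_indices), "\n")
  invisible(x)
}

# round half away from zero (coordinate snapping must not use banker's
# rounding, or voxels at exact half-mm offsets alternate sides)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert world millimetres to voxel indices and back
#'
#' `mm_to_voxel` maps world-space points to the nearest voxel (rounding half
#' away from zero); `voxel_to_mm` maps 1-based voxel indices to the world
#' coordinates of voxel centers.  Points that fall outside the grid are
#' flagged in the `"in_bounds"` attribute, never clamped.
#'
#' @param points numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @param grid a [brain_grid()].
#' @return `mm_to_voxel`: integer n x 3 matrix of 1-based voxel indices with
#'   a logical attribute `"in_bounds"`; `voxel_to_mm`: numeric n x 3 matrix.
#' @export
mm_to_voxel <- function(points, grid) {
  pts <- .as_point_matrix(points)
  inv <- solve(grid$affine)
  v0 <- cbind(pts, 1) %*% t(inv)             # zero-based continuous indices
  idx <- .round_half_away(v0[, 1:3, drop = FALSE]) + 1
  inb <- idx[, 1] >= 1 & idx[, 1] <= grid$shape[1] &
         idx[, 2] >= 1 & idx[, 2] <= grid$shape[2] &
         idx[, 3] >= 1 & idx[, 3] <= grid$shape[3]
  storage.mode(idx) <- "integer"
  attr(idx, "in_bounds") <- as.logical(inb)
  idx
}

#' @rdname mm_to_voxel
#' @param voxels integer matrix (n x 3) or vector of 1-based voxel indices.
#' @export
voxel_to_mm <- function(voxels, grid) {
  v <- .as_point_matrix(voxels)
  out <- cbind(v - 1, 1) %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

.as_point_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("points must have 3 coordinates")
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("points must be an n x 3 matrix")
  if (!all(is.finite(x))) stop("points must be finite")
  x
}

# linear array index <-> (i,j,k) triplets, 1-based
.ijk_to_linear <- function(ijk, shape) {
  as.integer(ijk[, 1] + (ijk[, 2] - 1L) * shape[1] +
             (ijk[, 3] - 1L) * shape[1] * shape[2])
}

.linear_to_ijk <- function(idx, shape) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% shape[1]
  j <- (idx0 %/% shape[1]) %% shape[2]
  k <- idx0 %/% (shape[1] * shape[2])
  cbind(i, j, k) + 1L
}

# world-mm centers of linear voxel indices
.linear_to_mm <- function(idx, grid) {
  voxel_to_mm(.linear_to_ijk(idx, grid$shape), grid)
}

#' Voxel mask on a brain grid
#'
#' @param grid a [brain_grid()].
#' @param voxels integer vector of 1-based linear array indices.
#' @return An object of class `brain_mask` with sorted unique voxel indices.
#' @export
brain_mask <- function(grid, voxels) {
  stopifnot(inherits(grid, "brain_grid"))
  voxels <- sort(unique(.check_linear_indices(voxels, grid$shape)))
  structure(list(grid = grid, voxels = voxels), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("Brain mask:", length(x$voxels), "voxels on a",
      paste(x$grid$shape, collapse = "x"), "grid\n")
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask a [brain_mask()].
#' @export
mask_size <- function(mask) length(mask$voxels)

.grids_compatible <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$affine, b$affine))
}

#' Read a NIfTI image together with its grid
#'
#' @param path path to a NIfTI-1 file.
#' @return list with `values` (3D array) and `grid` ([brain_grid()]).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img[, , , 1], dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))  # dropped singletons
  if (length(d) != 3L) stop("expected a 3D image, got ", length(d), " dimensions")
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  list(values = array(as.numeric(img), dim = d),
       grid = brain_grid(d, matrix(as.numeric(aff), 4, 4)))
}

#' Write a 3D array as NIfTI with a grid's affine
#'
#' @param values 3D numeric array matching `grid$shape`.
#' @param grid a [brain_grid()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_nifti_volume <- function(values, grid, path) {
  stopifnot(all(dim(values) == grid$shape))
  img <- RNifti::asNifti(values)
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load and binarize a probabilistic mask
#'
#' Thresholds a probabilistic NIfTI map at `threshold` (inclusive: a voxel
#' whose value equals the threshold is kept) and binarizes it.  Values on a
#' 0-100 percent scale are rescaled to 0-1 first.
#'
#' @param path NIfTI file with values in \[0, 1\] (or percent).
#' @param threshold inclusion threshold on the probability scale,
#'   default 0.25.
#' @return A [brain_mask()].
#' @export
load_probabilistic_mask <- function(path, threshold = 0.25) {
  vol <- read_nifti_volume(path)
  vals <- vol$values
  if (any(vals < 0)) stop("probabilistic mask has negative values")
  if (max(vals) > 1) vals <- vals / 100   # percent scale
  if (max(vals) > 1) stop("mask values not interpretable as probabilities")
  keep <- which(vals >= threshold & vals > 0)
  if (length(keep) == 0L) stop("thresholding at ", threshold,
                               " leaves an empty mask")
  brain_mask(vol$grid, keep)
}

#' Split a mask along the sagittal midline
#'
#' Assigns voxels with world x < 0 mm to the left mask and x > 0 mm to the
#' right mask.  Voxels exactly on the midline (x == 0) are excluded from
#' both by default, or assigned to the left mask with `midline = "left"`.
#'
#' @param mask a [brain_mask()].
#' @param midline `"exclude"` (default) or `"left"`.
#' @return list with elements `left` and `right`, both [brain_mask()]s.
#' @export
split_hemispheres <- function(mask, midline = c("exclude", "left")) {
  midline <- match.arg(midline)
  xs <- .linear_to_mm(mask$voxels, mask$grid)[, 1]
  left <- mask$voxels[xs < 0 | (midline == "left" & xs == 0)]
  right <- mask$voxels[xs > 0]
  if (length(left) == 0L) warning("left hemisphere mask is empty")
  if (length(right) == 0L) warning("right hemisphere mask is empty")
  list(left = structure(list(grid = mask$grid, voxels = left),
                        class = "brain_mask"),
       right = structure(list(grid = mask$grid, voxels = right),
                         class = "brain_mask"))
}

#' Integer-labelled atlas image
#'
#' @param grid a [brain_grid()].
#' @param labels 3D integer array (0 = background) matching `grid$shape`,
#'   or a vector of per-voxel labels.
#' @param lookup named character vector mapping label IDs (names) to region
#'   names; every nonzero label must be present.
#' @return An object of class `label_image`.
#' @export
label_image <- function(grid, labels, lookup = NULL) {
  stopifnot(inherits(grid, "brain_grid"))
  labels <- array(as.integer(labels), dim = grid$shape)
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be nonnegative")
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(lookup)) {
    lookup <- stats::setNames(paste0("region_", ids), ids)
  } else {
    missing <- setdiff(as.character(ids), names(lookup))
    if (length(missing) > 0L)
      stop("labels missing from lookup: ", paste(missing, collapse = ", "))
  }
  structure(list(grid = grid, labels = labels, lookup = lookup),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  ids <- sort(unique(x$labels[x$labels > 0L]))
  cat("Label image:", length(ids), "regions on a",
      paste(x$grid$shape, collapse = "x"), "grid\n")
  invisible(x)
}

#' All region IDs present in a label image
#' @param atlas a [label_image()].
#' @export
region_ids <- function(atlas) sort(unique(atlas$labels[atlas$labels > 0L]))

#' Extract one atlas region as a mask
#' @param atlas a [label_image()].
#' @param id integer region label.
#' @export
region_mask <- function(atlas, id) {
  vox <- which(atlas$labels == as.integer(id))
  if (length(vox) == 0L) stop("region ", id, " not present in atlas")
  brain_mask(atlas$grid, vox)
}

#' Read a label atlas and its region lookup table
#'
#' @param path NIfTI file with integer labels.
#' @param lookup_path optional two-column TSV (label ID, region name);
#'   header optional.
#' @return A [label_image()].
#' @export
read_label_image <- function(path, lookup_path = NULL) {
  vol <- read_nifti_volume(path)
  lookup <- NULL
  if (!is.null(lookup_path)) {
    tab <- utils::read.delim(lookup_path, header = FALSE,
                             stringsAsFactors = FALSE)
    if (!is.numeric(type.convert(tab[1, 1], as.is = TRUE)))
      tab <- tab[-1, , drop = FALSE]   # header row
    lookup <- stats::setNames(as.character(tab[[2]]),
                              as.character(as.integer(tab[[1]])))
  }
  label_image(vol$grid, round(vol$values), lookup)
}

#' Write a label image (or mask) to NIfTI
#' @param x a [label_image()] or [brain_mask()].
#' @param path output path.
#' @export
write_label_image <- function(x, path) {
  if (inherits(x, "brain_mask")) {
    vals <- array(0L, dim = x$grid$shape)
    vals[x$voxels] <- 1L
    write_nifti_volume(vals, x$grid, path)
  } else {
    write_nifti_volume(x$labels, x$grid, path)
  }
}
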