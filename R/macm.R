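#' Gaussian spatial-uncertainty kernel for modeled activation
#'
#' Each activation focus is modeled as a discretized isotropic 3D Gaussian
#' probability mass.  In `"sample_size"` mode the full width at half maximum
#' combines a template-registration component with a between-subject
#' component that shrinks with the square root of the number of subjects,
#' `FWHM(n) = sqrt(template_fwhm^2 + subject_fwhm^2 / n)`; experiments
#' without a subject count fall back to the fixed FWHM.  In `"fixed"` mode
#' the fixed FWHM is always used.  The kernel is truncated at
#' `truncate_sd` standard deviations and its mass renormalized to 1 over
#' the truncated support.
#'
#' @param mode `"sample_size"` (default) or `"fixed"`.
#' @param fwhm_mm fixed-mode FWHM in mm (default 12).
#' @param template_fwhm,subject_fwhm components of the sample-size model,
#'   in mm (defaults 5.7 and 11.6).
#' @param truncate_sd truncation radius in standard deviations (default 3.5).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(mode = c("sample_size", "fixed"), fwhm_mm = 12,
                        template_fwhm = 5.7, subject_fwhm = 11.6,
                        truncate_sd = 3.5) {
  mode <- match.arg(mode)
  stopifnot(fwhm_mm > 0, template_fwhm > 0, subject_fwhm > 0,
            truncate_sd > 0)
  structure(list(mode = mode, fwhm_mm = fwhm_mm,
                 template_fwhm = template_fwhm, subject_fwhm = subject_fwhm,
                 truncate_sd = truncate_sd),
            class = "kernel_spec")
}

# FWHM -> sigma: sigma = FWHM / (2 sqrt(2 ln 2))
.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Kernel standard deviation for an experiment
#' @param kernel a [kernel_spec()].
#' @param n_subjects subject count or `NULL`.
#' @return sigma in mm.
#' @export
kernel_sigma <- function(kernel, n_subjects = NULL) {
  fwhm <- if (kernel$mode == "sample_size" && !is.null(n_subjects) &&
              is.finite(n_subjects) && n_subjects > 0) {
    sqrt(kernel$template_fwhm^2 + kernel$subject_fwhm^2 / n_subjects)
  } else {
    kernel$fwhm_mm
  }
  .fwhm_to_sigma(fwhm)
}

#' Bank of nearest-experiment spatial filter sizes
#'
#' The spatial filter associates each seed voxel with its `n` nearest
#' experiments before ALE; profiles are computed over a whole bank of
#' filter sizes.  The default bank, 20 to 200 in steps of 2, has 91 sizes.
#'
#' @param from,to,by filter-size range and step (defaults 20, 200, 2).
#' @return strictly increasing integer vector of filter sizes.
#' @export
filter_bank <- function(from = 20, to = 200, by = 2) {
  sizes <- as.integer(seq(from, to, by = by))
  if (length(sizes) < 1L || any(diff(sizes) <= 0L))
    stop("filter sizes must be strictly increasing")
  sizes
}

#' Minimum focus distance from a voxel to each experiment
#'
#' For a seed voxel (given by its world-mm center) returns, per experiment
#' and in database order, the minimum Euclidean distance (mm) over the
#' experiment's foci.  Experiments with no foci get `Inf` and are flagged
#' in the `"empty"` attribute.
#'
#' @param voxel_mm length-3 world coordinate of the voxel center (mm).
#' @param db a [coord_db()].
#' @return named numeric vector of distances with attribute `"empty"`.
#' @export
experiment_distances <- function(voxel_mm, db) {
  if (n_experiments(db) == 0L) stop("empty database")
  d <- .min_distance_matrix(matrix(voxel_mm, nrow = 1), db)[1, ]
  empty <- focus_counts(db) == 0L
  attr(d, "empty") <- unname(empty)
  d
}

# N_S x N_E matrix of min distances from seed centers (rows) to experiments
.min_distance_matrix <- function(seed_mm, db) {
  ne <- n_experiments(db)
  ns <- nrow(seed_mm)
  D <- matrix(Inf, ns, ne, dimnames = list(NULL, db$ids))
  s2 <- rowSums(seed_mm^2)
  for (e in seq_len(ne)) {
    foci <- db$experiments[[e]]$foci
    if (nrow(foci) == 0L) next
    # |s - f|^2 = |s|^2 - 2 s.f + |f|^2, minimized over foci
    cross <- seed_mm %*% t(foci)
    d2 <- s2 - 2 * cross + rep(rowSums(foci^2), each = ns)
    D[, e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  D
}

#' Select the n experiments nearest to a seed voxel
#'
#' Nearness is the minimum focus distance; ties are broken by ascending
#' experiment ID so selection is stable.
#'
#' @param voxel_mm length-3 world coordinate of the voxel center (mm).
#' @param db a [coord_db()].
#' @param n number of experiments to select.
#' @return character vector of `n` experiment IDs, sorted by distance then ID.
#' @export
select_nearest <- function(voxel_mm, db, n) {
  ne <- n_experiments(db)
  if (n > ne)
    stop("cannot select ", n, " experiments from a database of ", ne)
  d <- experiment_distances(voxel_mm, db)
  db$ids[order(d, db$ids)][seq_len(n)]
}

#' ALE map container
#' @param grid a [brain_grid()].
#' @param values 3D array of per-voxel ALE values in \[0, 1).
#' @return An object of class `ale_map`.
#' @export
ale_map <- function(grid, values) {
  stopifnot(inherits(grid, "brain_grid"), all(dim(values) == grid$shape))
  if (any(values < 0) || any(values >= 1))
    stop("ALE values must lie in [0, 1)")
  structure(list(grid = grid, values = values), class = "ale_map")
}

#' @export
print.ale_map <- function(x, ...) {
  cat("ALE map on a", paste(x$grid$shape, collapse = "x"),
      "grid; max value", signif(max(x$values), 4), "\n")
  invisible(x)
}

# precompute integer offsets and squared-mm distances of the truncation
# ball around a voxel, for one sigma and grid
.kernel_ball <- function(grid, sigma, truncate_sd) {
  vd <- sqrt(colSums(grid$affine[1:3, 1:3]^2))   # per-axis voxel size, mm
  r <- sigma * truncate_sd
  nmax <- ceiling(r / vd)
  off <- as.matrix(expand.grid(i = -nmax[1]:nmax[1],
                               j = -nmax[2]:nmax[2],
                               k = -nmax[3]:nmax[3]))
  off
}

#' Modeled-activation map of one experiment
#'
#' Each focus contributes a discretized isotropic Gaussian probability mass
#' (summing to 1 over its truncated support); foci are combined within the
#' experiment by the voxel-wise maximum, so repeating a focus never inflates
#' the map.  Foci whose support extends beyond the grid are truncated; a
#' focus whose center lies outside the grid triggers a warning.
#'
#' @param experiment one element of `db$experiments` (list with `foci` and
#'   optionally `n_subjects`).
#' @param grid a [brain_grid()].
#' @param kernel a [kernel_spec()].
#' @return An [ale_map()].
#' @export
ma_map <- function(experiment, grid, kernel = kernel_spec()) {
  foci <- experiment$foci
  if (is.null(foci) || nrow(foci) == 0L)
    stop("experiment has no foci")
  sigma <- kernel_sigma(kernel, experiment$n_subjects)
  vals <- array(0, dim = grid$shape)
  ball <- .kernel_ball(grid, sigma, kernel$truncate_sd)
  centers <- mm_to_voxel(foci, grid)
  inb <- attr(centers, "in_bounds")
  if (any(!inb))
    warning(sum(!inb), " focus(es) outside the grid; contribution truncated")
  r2max <- (sigma * kernel$truncate_sd)^2
  for (f in seq_len(nrow(foci))) {
    ijk <- sweep(ball, 2, centers[f, ], "+")
    keep <- ijk[, 1] >= 1 & ijk[, 1] <= grid$shape[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= grid$shape[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= grid$shape[3]
    full_mm2 <- rowSums((voxel_to_mm(sweep(ball, 2, centers[f, ], "+"),
                                     grid) -
                         rep(foci[f, ], each = nrow(ball)))^2)
    inside <- full_mm2 <= r2max
    w_all <- exp(-full_mm2[inside] / (2 * sigma^2))
    w_all <- w_all / sum(w_all)              # mass 1 over truncated support
    sel <- keep[inside]
    if (!any(sel)) next
    idx <- .ijk_to_linear(ijk[inside & keep, , drop = FALSE], grid$shape)
    vals[idx] <- pmax(vals[idx], w_all[sel])
  }
  ale_map(grid, vals)
}

#' Probabilistic union of modeled-activation maps
#'
#' The ALE score at a voxel is `1 - prod_i (1 - MA_i)`, the probability
#' that at least one experiment activates there.  No thresholding is
#' applied.
#'
#' @param ma_maps list of [ale_map()]s on a common grid.
#' @return An [ale_map()].
#' @export
ale_union <- function(ma_maps) {
  if (length(ma_maps) == 0L) stop("need at least one map")
  grid <- ma_maps[[1]]$grid
  for (m in ma_maps)
    if (!.grids_compatible(m$grid, grid)) stop("mismatched grids")
  one_minus <- Reduce(`*`, lapply(ma_maps, function(m) 1 - m$values))
  ale_map(grid, 1 - one_minus)
}

#' Per-filter-size co-activation profiles of a seed mask
#'
#' For each seed voxel the experiments are ranked by minimum focus distance
#' (ties by ID); for each filter size `n` in the bank, the ALE union of the
#' `n` nearest experiments' modeled-activation maps is sampled at the
#' reference voxels, giving an `N_S x N_B` connectivity matrix per filter
#' size.  Matrices are unthresholded.
#'
#' Because the selected experiment sets are nested across filter sizes,
#' each voxel's ALE rows are computed as prefix products of `(1 - MA)` over
#' the distance-ordered experiments, which reproduces the compositional
#' definition exactly.
#'
#' @param seed_mask a [brain_mask()] of seed voxels.
#' @param db a [coord_db()].
#' @param bank integer vector of filter sizes (see [filter_bank()]).
#' @param reference a [brain_mask()] of reference (target) voxels, or a
#'   [brain_grid()] carrying `reference_indices`.
#' @param kernel a [kernel_spec()].
#' @return list of `coactivation_profile` objects (one per filter size),
#'   each with elements `filter_size`, `seed_voxels`, `reference_voxels`
#'   and `matrix` (`N_S x N_B`).
#' @export
coactivation_profiles <- function(seed_mask, db, bank = filter_bank(),
                                  reference, kernel = kernel_spec()) {
  stopifnot(inherits(seed_mask, "brain_mask"))
  if (mask_size(seed_mask) == 0L) stop("empty seed mask")
  if (inherits(reference, "brain_mask")) {
    ref_idx <- reference$voxels
    grid <- reference$grid
  } else {
    grid <- reference
    ref_idx <- grid$reference_indices
  }
  if (is.null(ref_idx) || length(ref_idx) == 0L)
    stop("no reference voxels supplied")
  if (!.grids_compatible(grid, seed_mask$grid))
    stop("seed mask and reference are on different grids")
  ne <- n_experiments(db)
  if (max(bank) > ne)
    stop("largest filter size (", max(bank),
         ") exceeds the number of experiments (", ne, ")")

  # log(1 - MA) at reference voxels, one column per experiment
  nb <- length(ref_idx)
  L <- matrix(0, nb, ne)
  for (e in seq_len(ne)) {
    m <- ma_map(db$experiments[[e]], grid, kernel)
    L[, e] <- log1p(-m$values[ref_idx])
  }

  seed_mm <- .linear_to_mm(seed_mask$voxels, grid)
  D <- .min_distance_matrix(seed_mm, db)
  maxF <- max(bank)
  prefix <- outer(seq_len(maxF), bank, `<=`) * 1   # maxF x n_sizes
  ns <- nrow(seed_mm)
  mats <- lapply(bank, function(s) matrix(0, ns, nb))
  for (i in seq_len(ns)) {
    ord <- order(D[i, ], db$ids)[seq_len(maxF)]
    ale <- 1 - exp(L[, ord, drop = FALSE] %*% prefix)   # nb x n_sizes
    for (s in seq_along(bank)) mats[[s]][i, ] <- ale[, s]
  }
  lapply(seq_along(bank), function(s) {
    structure(list(filter_size = bank[s],
                   seed_voxels = seed_mask$voxels,
                   reference_voxels = ref_idx,
                   grid = grid,
                   matrix = mats[[s]]),
              class = "coactivation_profile")
  })
}

#' @export
print.coactivation_profile <- function(x, ...) {
  cat("Co-activation profile, filter size", x$filter_size, ":",
      nrow(x$matrix), "seed voxels x", ncol(x$matrix),
      "reference voxels\n")
  invisible(x)
}
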