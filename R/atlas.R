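#' Jaccard index between two voxel masks
#'
#' `|A intersect B| / |A union B|` on a shared grid.
#'
#' @param mask_a,mask_b [brain_mask()]s on the same grid.
#' @return real in \[0, 1\]; both masks empty is an error.
#' @export
jaccard <- function(mask_a, mask_b) {
  if (!.grids_compatible(mask_a$grid, mask_b$grid))
    stop("masks are on different grids")
  a <- mask_a$voxels; b <- mask_b$voxels
  uni <- length(union(a, b))
  if (uni == 0L) stop("both masks are empty")
  length(intersect(a, b)) / uni
}

# nearest-neighbour resample of an atlas onto another grid: each target
# voxel takes the label of the atlas voxel containing its world center
.resample_atlas <- function(atlas, grid) {
  if (.grids_compatible(atlas$grid, grid)) return(atlas)
  n <- prod(grid$shape)
  mm <- .linear_to_mm(seq_len(n), grid)
  idx <- mm_to_voxel(mm, atlas$grid)
  inb <- attr(idx, "in_bounds")
  lab <- integer(n)
  lab[inb] <- atlas$labels[.ijk_to_linear(idx[inb, , drop = FALSE],
                                          atlas$grid$shape)]
  label_image(grid, lab, atlas$lookup)
}

#' Jaccard overlap table between a parcellation and an atlas
#'
#' One row per parcel, one column per atlas region, entries the Jaccard
#' index of the two voxel sets.  If the grids differ the atlas is resampled
#' to the parcellation grid by nearest neighbour.
#'
#' @param parcellation a [consensus_parcellation()] result carrying a grid
#'   and seed voxels.
#' @param atlas a [label_image()].
#' @return matrix of Jaccard indices with a `"best_match"` attribute naming
#'   the best-matching atlas label per parcel.
#' @export
overlap_table <- function(parcellation, atlas) {
  if (is.null(parcellation$grid)) stop("parcellation carries no grid")
  atlas <- .resample_atlas(atlas, parcellation$grid)
  ids <- region_ids(atlas)
  tab <- matrix(0, parcellation$k, length(ids),
                dimnames = list(paste0("parcel_", seq_len(parcellation$k)),
                                as.character(ids)))
  for (c in seq_len(parcellation$k)) {
    pv <- parcellation$seed_voxels[parcellation$labels == c]
    if (length(pv) == 0L) {
      warning("parcel ", c, " is empty")
      next
    }
    for (j in seq_along(ids)) {
      av <- which(atlas$labels == ids[j])
      tab[c, j] <- length(intersect(pv, av)) /
        length(union(pv, av))
    }
  }
  attr(tab, "best_match") <- colnames(tab)[apply(tab, 1, which.max)]
  tab
}

#' Select atlas regions by coverage of a binary map
#'
#' A region is selected iff the fraction of its voxels covered by the map
#' is at least `frac` (inclusive).  With `frac = 0` every region that has
#' at least one voxel is selected.
#'
#' @param binary_map a [brain_mask()] (e.g. a thresholded connectivity map).
#' @param atlas a [label_image()] on the same grid (resampled otherwise).
#' @param frac coverage threshold in \[0, 1\], default 0.8.
#' @return data.frame with columns `region_id`, `name`, `coverage`,
#'   `selected`.
#' @export
coverage_select <- function(binary_map, atlas, frac = 0.8) {
  atlas <- .resample_atlas(atlas, binary_map$grid)
  ids <- region_ids(atlas)
  cov <- vapply(ids, function(id) {
    rv <- which(atlas$labels == id)
    if (length(rv) == 0L) {
      warning("region ", id, " has no voxels; skipped")
      return(NA_real_)
    }
    mean(rv %in% binary_map$voxels)
  }, 0)
  out <- data.frame(region_id = ids,
                    name = unname(atlas$lookup[as.character(ids)]),
                    coverage = cov,
                    selected = !is.na(cov) & cov >= frac)
  out[!is.na(out$coverage), , drop = FALSE]
}
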