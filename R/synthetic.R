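#' Configuration of the synthetic foci-database generator
#'
#' The generator emulates a coordinate database with planted structure at
#' desk scale: a box-shaped seed region whose `k_true` sub-blocks co-activate
#' with cluster-specific cortical targets (so connectivity-based
#' parcellation can recover the blocks), and per-cluster term annotations
#' whose frequencies are enriched in experiments sampling that cluster's
#' system (so decoding can recover the planted term-systems).
#'
#' Each planted system consists of `n_hit_regions` "hit" cortical targets
#' that every system experiment activates (these carry the parcellation
#' signal and are captured by the cortical-only quasi-null decoding) and
#' `regions_per_cluster - n_hit_regions` "joint" regions that are
#' functionally connected but receive foci only with probability
#' `joint_hit_prob` (0 by default: their term association exists only
#' jointly with the seed cluster, which is what the systems-level set
#' difference isolates).
#'
#' @param grid_dim grid dimensions (default `c(24, 28, 24)`).
#' @param voxel_mm isotropic voxel size in mm (default 4).
#' @param k_true number of planted seed clusters (default 3).
#' @param n_experiments database size (default 600).
#' @param foci_range min/max foci per experiment (default `c(5, 12)`).
#' @param jitter_sd spatial jitter of emitted foci, mm (default 2).
#' @param regions_per_cluster connected cortical regions per planted system
#'   (default 6).
#' @param n_hit_regions always-activated targets per system (default 2).
#' @param joint_hit_prob per-experiment probability that a joint region
#'   receives a focus (default 0).
#' @param seed_signal if `FALSE`, system experiments emit no seed-region
#'   foci (cortical-only negative control).
#' @param enrich_prob probability that a system experiment carries its
#'   planted term (default 0.6).
#' @param base_rate background probability of any term (default 0.05).
#' @param null_frac fraction of unstructured null experiments (default 0.2).
#' @param n_background_terms background vocabulary size (default 15).
#' @param shell_radii inner/outer radius of the cortical shell, mm
#'   (default `c(36, 44)`).
#' @param seed RNG seed (default 1).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid_dim = c(24, 28, 24), voxel_mm = 4,
                         k_true = 3, n_experiments = 600,
                         foci_range = c(5, 12), jitter_sd = 2,
                         regions_per_cluster = 6, n_hit_regions = 2,
                         joint_hit_prob = 0, seed_signal = TRUE,
                         enrich_prob = 0.6, base_rate = 0.05,
                         null_frac = 0.2, n_background_terms = 15,
                         shell_radii = c(36, 44), seed = 1L) {
  stopifnot(k_true >= 2, jitter_sd > 0, n_experiments >= 1,
            foci_range[1] >= 1, foci_range[2] >= foci_range[1],
            enrich_prob >= 0, enrich_prob <= 1,
            base_rate >= 0, base_rate <= 1,
            null_frac >= 0, null_frac < 1,
            n_hit_regions >= 1, regions_per_cluster >= n_hit_regions,
            shell_radii[1] < shell_radii[2])
  structure(as.list(environment()), class = "synth_config")
}

# grid whose voxel centers are symmetric about the world origin
.synth_grid <- function(grid_dim, voxel_mm) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -(grid_dim - 1) / 2 * voxel_mm
  brain_grid(grid_dim, aff)
}

#' Toy cortical-shell atlas with contiguous regions
#'
#' Tiles a spherical shell of the grid into `n_regions` contiguous,
#' non-overlapping regions (Voronoi cells of a k-means partition of the
#' shell voxel coordinates, relabelled deterministically by centroid
#' position).
#'
#' @param grid a [brain_grid()].
#' @param n_regions number of regions (>= 1).
#' @param seed RNG seed.
#' @param shell_radii inner/outer shell radius in mm.
#' @return A [label_image()].
#' @export
make_toy_atlas <- function(grid, n_regions, seed = 1L,
                           shell_radii = c(36, 44)) {
  if (n_regions < 1L) stop("n_regions must be at least 1")
  mm <- .linear_to_mm(seq_len(prod(grid$shape)), grid)
  r <- sqrt(rowSums(mm^2))
  shell <- which(r >= shell_radii[1] & r <= shell_radii[2])
  if (n_regions > length(shell))
    stop("n_regions exceeds the number of shell voxels")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lab_vec <- if (n_regions == 1L) rep(1L, length(shell)) else
    as.integer(stats::kmeans(mm[shell, ], centers = n_regions,
                             nstart = 5, iter.max = 100)$cluster)
  # deterministic region ids: order centroids lexicographically
  cent <- t(vapply(seq_len(n_regions), function(c)
    colMeans(mm[shell[lab_vec == c], , drop = FALSE]), numeric(3)))
  ord <- order(cent[, 1], cent[, 2], cent[, 3])
  relabel <- integer(n_regions); relabel[ord] <- seq_len(n_regions)
  lab <- array(0L, dim = grid$shape)
  lab[shell] <- relabel[lab_vec]
  label_image(grid, lab,
              stats::setNames(sprintf("shell_region_%02d", 1:n_regions),
                              1:n_regions))
}

# seed box geometry: central box split into k_true azimuthal wedges in the
# x-y plane.  Wedges keep the planted clusters mutually adjacent and
# geometrically symmetric, so no particular merge of two clusters is
# preferred and stability criteria can discriminate the true k.
.synth_seed_layout <- function(grid, k_true) {
  dm <- grid$shape
  xs <- seq(floor(dm[1] / 2) - 2, floor(dm[1] / 2) + 3)
  ys <- seq(floor(dm[2] / 2) - 2, floor(dm[2] / 2) + 3)
  zs <- seq(floor(dm[3] / 2) - 2, floor(dm[3] / 2) + 2)
  if (max(xs) > dm[1] || max(ys) > dm[2] || max(zs) > dm[3] ||
      min(c(xs, ys, zs)) < 1)
    stop("seed geometry does not fit the grid")
  ijk <- as.matrix(expand.grid(i = xs, j = ys, k = zs))
  idx <- .ijk_to_linear(ijk, dm)
  theta <- atan2(ijk[, 2] - mean(ys), ijk[, 1] - mean(xs))
  # rank-based angular split: exactly balanced, angularly contiguous wedges
  block <- ceiling(rank(theta, ties.method = "first") *
                   k_true / length(theta))
  list(voxels = idx, labels = as.integer(block))
}

#' Generate a synthetic foci database with planted structure
#'
#' See [synth_config()] for what is planted.  Deterministic given the
#' config seed.
#'
#' @param config a [synth_config()].
#' @return list with `db` (annotated [coord_db()]), `truth` (planted voxel
#'   labels, per-experiment latent cluster, planted systems), `grid`,
#'   `seed_mask`, `reference_mask` and `atlas`.
#' @export
make_synthetic_db <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  grid <- .synth_grid(config$grid_dim, config$voxel_mm)
  n_regions <- config$k_true * config$regions_per_cluster
  atlas <- make_toy_atlas(grid, n_regions, seed = config$seed,
                          shell_radii = config$shell_radii)
  layout <- .synth_seed_layout(grid, config$k_true)
  seed_mask <- brain_mask(grid, layout$voxels)
  seed_labels <- layout$labels[match(seed_mask$voxels, layout$voxels)]

  # reference voxels: checkerboard-thinned shell plus the whole seed box
  shell <- which(atlas$labels > 0L)
  ijk <- .linear_to_ijk(shell, grid$shape)
  thin <- shell[(ijk[, 1] + ijk[, 2] + ijk[, 3]) %% 2L == 0L]
  reference_mask <- brain_mask(grid, union(thin, seed_mask$voxels))

  # planted systems: block of regions per cluster, first n_hit always hit
  rpc <- config$regions_per_cluster
  systems <- lapply(seq_len(config$k_true), function(c) {
    regs <- ((c - 1) * rpc + 1):(c * rpc)
    list(cluster = c, term = paste0("system_", c),
         hit_regions = regs[seq_len(config$n_hit_regions)],
         joint_regions = regs[-seq_len(config$n_hit_regions)],
         connected_regions = regs)
  })
  centroids <- t(vapply(seq_len(n_regions), function(id) {
    colMeans(.linear_to_mm(which(atlas$labels == id), grid))
  }, numeric(3)))

  world_lo <- apply(.linear_to_mm(c(1L, prod(grid$shape)), grid), 2, min)
  world_hi <- apply(.linear_to_mm(c(1L, prod(grid$shape)), grid), 2, max)
  clamp <- function(x) pmin(pmax(x, rep(world_lo, each = nrow(x))),
                            rep(world_hi, each = nrow(x)))
  jitter3 <- function(n) matrix(stats::rnorm(3 * n, 0, config$jitter_sd),
                                n, 3)
  ref_mm <- .linear_to_mm(reference_mask$voxels, grid)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  vocab <- c(paste0("system_", seq_len(config$k_true)),
             sprintf("background_%02d", seq_len(config$n_background_terms)))
  ne <- config$n_experiments
  experiments <- vector("list", ne)
  ann <- matrix(0, ne, length(vocab), dimnames = list(NULL, vocab))
  latent <- integer(ne)
  for (e in seq_len(ne)) {
    is_null <- stats::runif(1) < config$null_frac
    z <- if (is_null) 0L else sample.int(config$k_true, 1L)
    latent[e] <- z
    n_f <- sample(seq(config$foci_range[1], config$foci_range[2]), 1L)
    foci <- NULL
    if (z > 0L) {
      sys <- systems[[z]]
      if (config$seed_signal) {
        sv <- sample(which(seed_labels == z), 3L, replace = TRUE)
        foci <- rbind(foci, .linear_to_mm(seed_mask$voxels[sv], grid) +
                              jitter3(3L))
      }
      hits <- rep(sys$hit_regions, 2L)   # two foci per hit target
      joint_on <- sys$joint_regions[
        stats::runif(length(sys$joint_regions)) < config$joint_hit_prob]
      targets <- c(hits, joint_on)
      if (length(targets) > 0L)
        foci <- rbind(foci, centroids[targets, , drop = FALSE] +
                              jitter3(length(targets)))
    }
    n_bg <- max(n_f - NROW(foci), 0L)
    if (n_bg > 0L) {
      bg <- ref_mm[sample.int(nrow(ref_mm), n_bg, replace = TRUE), ,
                   drop = FALSE]
      foci <- rbind(foci, bg + jitter3(n_bg))
    }
    foci <- clamp(foci)
    experiments[[e]] <- list(id = sprintf("exp_%04d", e), foci = foci,
                             n_subjects = sample(10:30, 1L))
    p_term <- rep(config$base_rate, length(vocab))
    if (z > 0L) p_term[z] <- config$enrich_prob
    present <- stats::runif(length(vocab)) < p_term
    ann[e, present] <- stats::runif(sum(present), 0.005, 0.05)
  }
  db <- coord_db(experiments, annotations = ann)
  truth <- list(voxel_labels = stats::setNames(seed_labels,
                                               seed_mask$voxels),
                experiment_cluster = stats::setNames(latent, db$ids),
                systems = systems)
  list(db = db, truth = truth, grid = grid, seed_mask = seed_mask,
       reference_mask = reference_mask, atlas = atlas)
}

#' Permute a database's annotations across experiments
#'
#' Null model for decoder calibration: the rows of the term-frequency
#' table are permuted across experiments while foci stay untouched, so
#' marginal term frequencies are preserved exactly but any
#' activation-term association is destroyed.
#'
#' @param db an annotated [coord_db()].
#' @param seed RNG seed.
#' @return The database with permuted annotations.
#' @export
permute_annotations <- function(db, seed = 1L) {
  if (is.null(db$annotations)) stop("database has no annotations")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(nrow(db$annotations))
  ann <- db$annotations[perm, , drop = FALSE]
  rownames(ann) <- db$ids
  db$annotations <- ann
  db
}

#' Write a synthetic study to the on-disk formats the pipeline consumes
#'
#' Emits the foci text file, the annotation TSV, NIfTI images for the seed
#' mask, reference mask and toy atlas, the atlas lookup TSV, and a truth
#' sidecar TSV with the planted voxel labels.
#'
#' @param sim result of [make_synthetic_db()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(foci = file.path(dir, "foci.txt"),
             annotations = file.path(dir, "annotations.tsv"),
             seed_mask = file.path(dir, "seed_mask.nii.gz"),
             reference = file.path(dir, "reference_mask.nii.gz"),
             atlas = file.path(dir, "atlas.nii.gz"),
             lookup = file.path(dir, "atlas_lookup.tsv"),
             truth = file.path(dir, "truth_voxel_labels.tsv"))
  write_foci_file(sim$db, paths["foci"])
  write_annotations(sim$db, paths["annotations"])
  write_label_image(sim$seed_mask, paths["seed_mask"])
  write_label_image(sim$reference_mask, paths["reference"])
  write_label_image(sim$atlas, paths["atlas"])
  utils::write.table(
    data.frame(id = names(sim$atlas$lookup), name = sim$atlas$lookup),
    paths["lookup"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(
    data.frame(voxel = names(sim$truth$voxel_labels),
               cluster = sim$truth$voxel_labels),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
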