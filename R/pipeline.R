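# deterministic sub-seed derivation: one config seed governs every
# stochastic stage; kept below 2^31
.sub_seed <- function(seed, k, f) {
  as.integer((as.double(seed) * 7919 + k * 104729 + f * 101) %% 2147483647)
}

#' Meta-analytic connectivity-based parcellation of a seed region
#'
#' End-to-end parcellation workflow: co-activation profiles over a bank of
#' nearest-experiment filter sizes, k-means clustering for each candidate
#' k, label alignment across filter sizes, selection of the contiguous
#' filter range with fewest deviants (aggregated over k), stability
#' metrics per k restricted to that range (deviants, variation of
#' information between consecutive filter sizes, silhouette,
#' inter/intra-cluster distance ratio, hierarchy index), rank-vote
#' selection of the optimal k, and a consensus parcellation over the
#' selected range.  Optionally quantifies Jaccard overlap with a
#' reference atlas.
#'
#' @param db a [coord_db()].
#' @param seed_mask [brain_mask()] of the seed region.
#' @param reference [brain_mask()] of reference (target) voxels.
#' @param bank filter sizes (see [filter_bank()]).
#' @param k_range candidate cluster numbers (default `2:8`).
#' @param filter_window width of the selected filter range, in number of
#'   sizes (default 25, capped at the bank length).
#' @param kernel a [kernel_spec()].
#' @param seed integer RNG seed governing all k-means restarts.
#' @param restarts k-means restarts (default 50).
#' @param atlas optional [label_image()] for overlap quantification.
#' @param row_norm if `TRUE`, profile rows are scaled to unit Euclidean
#'   norm before clustering; default `FALSE` (raw unthresholded profiles).
#' @return An object of class `macm_parcellation`.
#' @export
run_parcellate <- function(db, seed_mask, reference, bank = filter_bank(),
                           k_range = 2:8, filter_window = 25,
                           kernel = kernel_spec(), seed = 1L,
                           restarts = 50L, atlas = NULL, row_norm = FALSE) {
  k_range <- sort(as.integer(k_range))
  profiles <- coactivation_profiles(seed_mask, db, bank, reference, kernel)
  mats <- lapply(profiles, function(p) {
    m <- p$matrix
    if (row_norm) {
      nr <- sqrt(rowSums(m^2)); nr[nr == 0] <- 1
      m <- m / nr
    }
    m
  })
  nf <- length(bank)

  stacks <- list(); dev_kf <- matrix(0, length(k_range), nf,
                                     dimnames = list(k_range, bank))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    labs <- lapply(seq_len(nf), function(f)
      kmeans_labels(mats[[f]], k, seed = .sub_seed(seed, k, f),
                    restarts = restarts))
    stacks[[ki]] <- .align_stack(labs)
    dev_kf[ki, ] <- .deviants_per_filter(stacks[[ki]])
  }

  width <- min(filter_window, nf)
  sel <- select_filter_range(colSums(dev_kf), bank, width)
  rows <- match(sel, bank)

  dists <- lapply(rows, function(f) stats::dist(mats[[f]]))
  metrics <- do.call(rbind, lapply(seq_along(k_range), function(ki) {
    st <- stacks[[ki]][rows, , drop = FALSE]
    vi <- if (length(rows) > 1)
      mean(vapply(seq_len(length(rows) - 1), function(i)
        variation_of_information(st[i, ], st[i + 1, ]), 0)) else 0
    sil <- mean(vapply(seq_along(rows), function(i)
      silhouette_score(dists[[i]], stacks[[ki]][rows[i], ]), 0))
    rat <- mean(vapply(seq_along(rows), function(i)
      separation_ratio(mats[[rows[i]]], stacks[[ki]][rows[i], ]), 0))
    data.frame(k = k_range[ki], deviants = deviant_fraction(st),
               vi = vi, silhouette = sil, ratio = rat)
  }))
  cons <- lapply(seq_along(k_range), function(ki)
    consensus_parcellation(stacks[[ki]], bank, sel, grid = seed_mask$grid,
                           seed_voxels = seed_mask$voxels,
                           provenance = list(seed = seed,
                                             restarts = restarts)))
  # hierarchy has no parent solution at the smallest candidate k -> NA
  metrics$hierarchy <- vapply(seq_along(k_range), function(ki) {
    if (ki == 1) return(NA_real_)
    hierarchy_index(cons[[ki]]$labels, cons[[ki - 1]]$labels)
  }, 0)

  k_star <- select_k(metrics)
  final <- cons[[match(as.integer(k_star), k_range)]]
  overlap <- if (!is.null(atlas)) overlap_table(final, atlas)
  structure(list(parcellation = final, k_selected = as.integer(k_star),
                 k_rank_table = attr(k_star, "ranks"),
                 metrics = metrics, filter_range = sel,
                 deviants_per_filter = dev_kf, bank = bank,
                 k_range = k_range, overlap = overlap,
                 provenance = list(seed = seed, restarts = restarts,
                                   filter_window = width,
                                   kernel = kernel, row_norm = row_norm)),
            class = "macm_parcellation")
}

#' @export
print.macm_parcellation <- function(x, ...) {
  cat("MACM connectivity-based parcellation\n")
  cat("  selected k:", x$k_selected, "(candidates ",
      paste(range(x$k_range), collapse = "-"), ")\n")
  cat("  selected filter range:", min(x$filter_range), "-",
      max(x$filter_range), "experiments\n")
  cat("  cluster sizes:",
      paste(tabulate(x$parcellation$labels, x$k_selected), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.macm_parcellation <- function(object, ...) {
  cat("Stability metrics per candidate k (computed over filter sizes ",
      min(object$filter_range), "-", max(object$filter_range), "):\n",
      sep = "")
  print(object$metrics, digits = 4, row.names = FALSE)
  cat("\nRank table (lower mean rank is better):\n")
  print(object$k_rank_table, digits = 3)
  if (!is.null(object$overlap)) {
    cat("\nJaccard overlap with reference atlas (best matches):\n")
    print(attr(object$overlap, "best_match"))
  }
  invisible(object)
}

#' Systems-level decoding of a parcellation
#'
#' For every seed cluster and its functionally connected cortical regions:
#' decodes all cluster-region pair masks, decodes the regions alone
#' (quasi-null), intersects the term sets, takes the region-ID set
#' difference to isolate associations unique to the pairing, and
#' summarizes each term-system by its region percentage and mean Bayes
#' factor; the lenient supplementary term set and (optionally) a topic
#' aggregation are reported per cluster.
#'
#' @param db an annotated [coord_db()].
#' @param parcellation a [consensus_parcellation()] result carrying grid
#'   and seed voxels (e.g. from [run_parcellate()]`$parcellation`), or a
#'   named list of cluster [brain_mask()]s.
#' @param atlas a [label_image()] of cortical regions.
#' @param connected named list: for each cluster ID, the integer region
#'   IDs functionally connected with that cluster (e.g. from
#'   [coverage_select()]).
#' @param config a [decoder_config()].
#' @param topic_table optional data.frame with columns `term`, `topic`.
#' @return An object of class `systems_decoding`: per-cluster results and
#'   a combined `summary` data.frame.
#' @export
run_systems_decode <- function(db, parcellation, atlas, connected,
                               config = decoder_config(),
                               topic_table = NULL) {
  cluster_masks <- if (inherits(parcellation, "parcellation")) {
    stats::setNames(lapply(seq_len(parcellation$k), function(c)
      parcel_mask(parcellation, c)), seq_len(parcellation$k))
  } else parcellation
  per_cluster <- list()
  for (cid in names(cluster_masks)) {
    regs <- connected[[cid]]
    if (is.null(regs) || length(regs) == 0L) {
      warning("cluster ", cid, " has no connected regions; skipped")
      next
    }
    region_masks <- stats::setNames(
      lapply(regs, function(r) region_mask(atlas, r)), regs)
    res <- decode_system(db, cluster_masks[[cid]], region_masks, config,
                         cluster_id = as.integer(cid))
    # reconciliation: common and lenient sets partition the pair terms
    stopifnot(length(.term_set(res$pair_terms)) ==
              length(res$common_terms) + length(res$lenient_terms))
    if (!is.null(topic_table))
      res$topics <- aggregate_topics(unique(res$survivors$term), topic_table)
    per_cluster[[cid]] <- res
  }
  summary <- do.call(rbind, c(lapply(per_cluster, `[[`, "summary"),
                              make.row.names = FALSE))
  structure(list(clusters = per_cluster, summary = summary,
                 config = config), class = "systems_decoding")
}

#' @export
print.systems_decoding <- function(x, ...) {
  cat("Systems-level decoding of", length(x$clusters), "cluster(s)\n")
  for (cid in names(x$clusters)) {
    res <- x$clusters[[cid]]
    cat("  cluster ", cid, ": ", nrow(res$survivors),
        " surviving region-term association(s), ",
        length(res$lenient_terms), " lenient term(s)\n", sep = "")
  }
  if (!is.null(x$summary) && nrow(x$summary) > 0) {
    cat("\nTop term-systems:\n")
    print(utils::head(x$summary, 10), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.systems_decoding <- function(object, ...) {
  print(object)
  invisible(object)
}
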