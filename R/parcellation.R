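#' k-means labels of co-activation profile rows
#'
#' Best-of-restarts k-means (squared-Euclidean objective, Hartigan-Wong)
#' on the rows of a profile matrix.  Deterministic given `seed`.
#'
#' @param x numeric matrix, one row per seed voxel.
#' @param k number of clusters (>= 2).
#' @param seed integer RNG seed.
#' @param restarts number of random restarts (default 50).
#' @return integer vector of cluster labels in `1..k` with the within-cluster
#'   sum of squares in the `"objective"` attribute.
#' @export
kmeans_labels <- function(x, k, seed = 1L, restarts = 50L) {
  x <- as.matrix(x)
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(x)) stop("k (", k, ") exceeds the number of rows (", nrow(x), ")")
  nu <- nrow(unique(x))
  if (nu < k) {
    warning("only ", nu, " distinct rows; returning ", nu,
            " effective cluster(s)")
    lab <- match(apply(x, 1, paste, collapse = "\r"),
                 unique(apply(x, 1, paste, collapse = "\r")))
    attr(lab, "objective") <- 0
    return(lab)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fit <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100L))
  lab <- as.integer(fit$cluster)
  attr(lab, "objective") <- fit$tot.withinss
  lab
}

# all permutations of 1..k (k <= 8 in practice)
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Align cluster labels to a reference labeling
#'
#' Finds the permutation of label IDs maximizing agreement with the
#' reference (exhaustive search over the k x k confusion matrix; exact for
#' the small k used in parcellation).
#'
#' @param reference_labels,labels integer label vectors of equal length
#'   using the same number of clusters.
#' @return relabeled `labels`, with the applied permutation in the
#'   `"permutation"` attribute (`perm[old] = new`).
#' @export
align_labels <- function(reference_labels, labels) {
  if (length(reference_labels) != length(labels))
    stop("label vectors differ in length")
  k1 <- max(reference_labels); k2 <- max(labels)
  if (k1 != k2) stop("labelings use different k (", k1, " vs ", k2, ")")
  k <- k1
  conf <- table(factor(labels, levels = 1:k),
                factor(reference_labels, levels = 1:k))
  best <- NULL; best_agree <- -1L
  for (p in .permutations(k)) {
    agree <- sum(conf[cbind(1:k, p)])
    if (agree > best_agree) { best_agree <- agree; best <- p }
  }
  out <- best[labels]
  attr(out, "permutation") <- best
  out
}

# align a list of labelings into a filters x voxels matrix: first pass
# aligns everything to the first labeling, second pass re-aligns to the
# modal labeling so "deviance" is measured against the consensus
.align_stack <- function(label_list) {
  stack <- do.call(rbind, lapply(label_list, as.integer))
  if (nrow(stack) > 1L)
    for (f in 2:nrow(stack))
      stack[f, ] <- align_labels(stack[1, ], stack[f, ])
  mode1 <- .modal_labels(stack)
  for (f in seq_len(nrow(stack)))
    stack[f, ] <- align_labels(mode1, stack[f, ])
  stack
}

# per-voxel modal label of a filters x voxels stack; ties -> smallest label
.modal_labels <- function(stack) {
  apply(stack, 2, function(col) {
    tab <- tabulate(col)
    which.max(tab)
  })
}

#' Fraction of deviant (voxel, filter) assignments
#'
#' A deviant is a (voxel, filter-size) entry whose aligned cluster label
#' differs from the voxel's modal label across filter sizes — the
#' stability criterion used both for filter-range selection and for
#' choosing k.
#'
#' @param label_stack aligned integer matrix, filter sizes x voxels.
#' @return fraction in \[0, 1\].
#' @export
deviant_fraction <- function(label_stack) {
  label_stack <- as.matrix(label_stack)
  if (nrow(label_stack) == 1L) {
    warning("single filter size: deviant fraction is 0 by definition")
    return(0)
  }
  mode_lab <- .modal_labels(label_stack)
  mean(sweep(label_stack, 2, mode_lab, `!=`))
}

# per-filter deviant fractions (columns of the stack compared per filter)
.deviants_per_filter <- function(label_stack) {
  mode_lab <- .modal_labels(label_stack)
  rowMeans(sweep(label_stack, 2, mode_lab, `!=`))
}

#' Select the contiguous filter range with fewest deviants
#'
#' @param deviant_per_filter numeric vector of per-filter-size deviant
#'   counts or fractions (already aggregated over k).
#' @param sizes integer vector of filter sizes, same length.
#' @param width window width in number of sizes (>= 2).
#' @return integer vector: the selected contiguous filter sizes, with the
#'   window start index in attribute `"start"`.  Ties go to the window
#'   with the smaller starting size.
#' @export
select_filter_range <- function(deviant_per_filter, sizes, width) {
  n <- length(sizes)
  stopifnot(length(deviant_per_filter) == n)
  if (width < 2L) stop("window width must be at least 2")
  if (width > n) stop("window width exceeds the number of filter sizes")
  sums <- vapply(seq_len(n - width + 1L), function(s)
    sum(deviant_per_filter[s:(s + width - 1L)]), 0)
  start <- which.min(sums)   # which.min takes the first (smallest start) tie
  out <- sizes[start:(start + width - 1L)]
  attr(out, "start") <- start
  out
}

#' Variation of information between two partitions
#'
#' `VI = H(p1) + H(p2) - 2 I(p1, p2)` in nats; zero iff the partitions are
#' identical up to relabeling, symmetric, and a metric on partitions.
#'
#' @param p1,p2 integer label vectors of equal length.
#' @return nonnegative real (nats).
#' @export
variation_of_information <- function(p1, p2) {
  if (length(p1) == 0L || length(p2) == 0L) stop("empty partitions")
  if (length(p1) != length(p2)) stop("partitions differ in length")
  n <- length(p1)
  joint <- table(p1, p2) / n
  px <- rowSums(joint); py <- colSums(joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pj <- joint[joint > 0]
  mi <- sum(pj * log(pj / (px[row(joint)][joint > 0] *
                           py[col(joint)][joint > 0])))
  max(h(px) + h(py) - 2 * mi, 0)
}

#' Mean silhouette width of a clustering
#'
#' Standard silhouette with Euclidean distances; singleton clusters get
#' width 0 (with a warning).
#'
#' @param x profile matrix (rows clustered) or a `dist` object.
#' @param labels integer cluster labels.
#' @return mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(x, labels) {
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  d <- if (inherits(x, "dist")) x else stats::dist(as.matrix(x))
  if (any(tabulate(labels) == 1L))
    warning("singleton cluster(s): silhouette set to 0 for those points")
  sil <- cluster::silhouette(as.integer(labels), d)
  mean(sil[, "sil_width"])
}

#' Inter- to intra-cluster distance ratio
#'
#' Mean pairwise between-centroid distance divided by the mean
#' point-to-own-centroid distance.
#'
#' @param x profile matrix.
#' @param labels integer cluster labels.
#' @return positive real; `Inf` (with a warning) if all points coincide
#'   with their centroids.
#' @export
separation_ratio <- function(x, labels) {
  x <- as.matrix(x)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) stop("need at least 2 clusters")
  cent <- t(vapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]),
                   numeric(ncol(x))))
  dc <- stats::dist(cent)
  within <- sqrt(rowSums((x - cent[match(labels, ks), , drop = FALSE])^2))
  if (mean(within) == 0) {
    warning("zero within-cluster distance; ratio is infinite")
    return(Inf)
  }
  mean(dc) / mean(within)
}

#' Hierarchy index between consecutive clustering solutions
#'
#' For each cluster of the finer (k) solution, its dominant parent is the
#' coarser (k-1) cluster holding the plurality of its voxels; the index is
#' the fraction of voxels whose coarse label is not their cluster's
#' dominant parent.  Zero for perfectly nested solutions.
#'
#' @param labels_k finer labeling (k clusters).
#' @param labels_km1 coarser labeling (fewer clusters).
#' @return fraction in \[0, 1\].
#' @export
hierarchy_index <- function(labels_k, labels_km1) {
  if (length(labels_k) != length(labels_km1))
    stop("labelings differ in length")
  ks <- sort(unique(labels_k))
  parent <- vapply(ks, function(c) {
    tab <- tabulate(labels_km1[labels_k == c])
    best <- which(tab == max(tab))
    if (length(best) > 1L)
      warning("plurality tie for parent of cluster ", c,
              "; taking the lower parent id")
    best[1]
  }, 0L)
  mean(labels_km1 != parent[match(labels_k, ks)])
}

#' Consensus parcellation over a filter range
#'
#' The final label of each voxel is its modal label across the selected
#' filter sizes of the aligned stack; modal ties take the label at the
#' median filter size (with a warning).  The number of consistent voxels
#' per cluster (voxels labelled identically at every selected filter size)
#' is reported.
#'
#' @param label_stack aligned integer matrix, filter sizes x voxels.
#' @param sizes filter sizes corresponding to the stack rows.
#' @param filter_range filter sizes to use (must be a subset of `sizes`).
#' @param grid optional [brain_grid()] for the provenance record.
#' @param seed_voxels optional linear voxel indices of the stack columns.
#' @param provenance optional list recorded verbatim (seed, restarts, ...).
#' @return An object of class `parcellation` with elements `labels`, `k`,
#'   `filter_range`, `consistent_voxels`, `seed_voxels`, `grid`,
#'   `provenance`.
#' @export
consensus_parcellation <- function(label_stack, sizes,
                                   filter_range = sizes, grid = NULL,
                                   seed_voxels = NULL, provenance = list()) {
  label_stack <- as.matrix(label_stack)
  stopifnot(length(sizes) == nrow(label_stack))
  rows <- match(filter_range, sizes)
  if (anyNA(rows)) stop("filter_range must be a subset of the stack sizes")
  sub <- label_stack[rows, , drop = FALSE]
  med_row <- rows[ceiling(length(rows) / 2)]   # median filter size
  nv <- ncol(sub)
  labels <- integer(nv)
  tied <- 0L
  for (v in seq_len(nv)) {
    tab <- tabulate(sub[, v])
    top <- which(tab == max(tab))
    if (length(top) > 1L) {
      tied <- tied + 1L
      labels[v] <- label_stack[med_row, v]
    } else labels[v] <- top[1]
  }
  if (tied > 0L)
    warning(tied, " voxel(s) with modal ties; took the label at the ",
            "median filter size")
  k <- max(labels)
  consistent <- vapply(seq_len(k), function(c) {
    sum(labels == c & apply(sub, 2, function(col) all(col == col[1])))
  }, 0L)
  structure(list(labels = labels, k = k,
                 filter_range = as.integer(filter_range),
                 consistent_voxels = consistent,
                 seed_voxels = seed_voxels, grid = grid,
                 provenance = provenance),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("Parcellation into", x$k, "clusters of", length(x$labels),
      "seed voxels\n")
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "),
      "\n")
  cat("  filter range:", min(x$filter_range), "-", max(x$filter_range), "\n")
  cat("  consistent voxels per cluster:",
      paste(x$consistent_voxels, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one parcel as a mask
#' @param parcellation a [consensus_parcellation()] result carrying a grid.
#' @param cluster integer cluster label.
#' @export
parcel_mask <- function(parcellation, cluster) {
  if (is.null(parcellation$grid) || is.null(parcellation$seed_voxels))
    stop("parcellation carries no grid/voxel information")
  brain_mask(parcellation$grid,
             parcellation$seed_voxels[parcellation$labels == cluster])
}

#' Select the optimal number of clusters by rank voting
#'
#' Each stability criterion ranks the candidate k values (lower deviants,
#' lower variation of information, higher silhouette, higher separation
#' ratio, lower hierarchy index are better); the selected k has the best
#' (lowest) mean rank (Borda count), with ties resolved toward the
#' smaller k.
#'
#' A criterion may be undefined (NA) for some k — the hierarchy index has
#' no parent solution at the smallest candidate k.  Such a criterion is
#' ranked over the k values where it is defined, and each k's mean rank is
#' taken over its available criteria; this avoids the degenerate
#' alternative of scoring an undefined criterion as perfect, which would
#' bias selection toward the smallest k regardless of the data.  A
#' criterion missing for every k is dropped with a warning.
#'
#' @param metrics data.frame with column `k` and criterion columns
#'   `deviants`, `vi`, `silhouette`, `ratio`, `hierarchy` (any subset).
#' @return the selected k, with the rank matrix in attribute `"ranks"`.
#' @export
select_k <- function(metrics) {
  stopifnot(is.data.frame(metrics), "k" %in% names(metrics))
  lower_better <- c(deviants = TRUE, vi = TRUE, silhouette = FALSE,
                    ratio = FALSE, hierarchy = TRUE)
  crit <- intersect(names(lower_better), names(metrics))
  if (length(crit) == 0L) stop("no criterion columns found")
  ranks <- sapply(crit, function(cn) {
    v <- metrics[[cn]]
    out <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    if (any(ok))
      out[ok] <- if (lower_better[[cn]]) rank(v[ok], ties.method = "average")
                 else rank(-v[ok], ties.method = "average")
    out
  })
  ranks <- matrix(ranks, nrow = nrow(metrics),
                  dimnames = list(NULL, crit))
  all_missing <- colnames(ranks)[colSums(!is.na(ranks)) == 0L]
  if (length(all_missing) > 0L) {
    warning("criterion dropped (missing for every k): ",
            paste(all_missing, collapse = ", "))
    ranks <- ranks[, setdiff(colnames(ranks), all_missing), drop = FALSE]
  }
  if (ncol(ranks) == 0L) stop("all criteria missing")
  agg <- rowMeans(ranks, na.rm = TRUE)
  best <- metrics$k[agg == min(agg)]
  out <- min(best)
  attr(out, "ranks") <- cbind(k = metrics$k, ranks, mean_rank = agg)
  out
}
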