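#' Union mask of a seed cluster and a cortical region
#'
#' @param cluster_mask,region_mask [brain_mask()]s on a shared grid; both
#'   nonempty.
#' @return A [brain_mask()] of the voxel union.
#' @export
pair_mask <- function(cluster_mask, region_mask) {
  if (mask_size(cluster_mask) == 0L || mask_size(region_mask) == 0L)
    stop("pair masks must both be nonempty")
  if (!.grids_compatible(cluster_mask$grid, region_mask$grid))
    stop("masks are on different grids")
  brain_mask(cluster_mask$grid,
             union(cluster_mask$voxels, region_mask$voxels))
}

.empty_tagged <- function() {
  data.frame(term = character(0), region_id = integer(0),
             cluster_id = integer(0), posterior = numeric(0),
             bayes_factor = numeric(0), q_fdr = numeric(0),
             stringsAsFactors = FALSE)
}

.tag_decoding <- function(dec, region_id, cluster_id) {
  if (nrow(dec) == 0L) return(.empty_tagged())
  data.frame(term = dec$term, region_id = region_id,
             cluster_id = if (is.null(cluster_id)) NA_integer_ else cluster_id,
             posterior = dec$posterior, bayes_factor = dec$bayes_factor,
             q_fdr = dec$q_fdr, stringsAsFactors = FALSE)
}

#' Decode all seed-cluster/cortical-region pair masks
#'
#' For every cortical region, decodes the union of the cluster mask and the
#' region mask, keeps the top-10 (or `config$top_k`) terms by posterior,
#' drops terms failing the FDR correction (applied within each pair), and
#' tags every surviving term with the region's atlas ID.
#'
#' @param db an annotated [coord_db()].
#' @param cluster_mask [brain_mask()] of the seed cluster.
#' @param region_masks named list of [brain_mask()]s keyed by region ID.
#' @param config a [decoder_config()].
#' @param cluster_id integer identifier stored with each tag.
#' @return data.frame of tagged terms: `term`, `region_id`, `cluster_id`,
#'   `posterior`, `bayes_factor`, `q_fdr`.
#' @export
decode_pairs <- function(db, cluster_mask, region_masks,
                         config = decoder_config(), cluster_id = 1L) {
  out <- lapply(names(region_masks), function(rid) {
    pm <- pair_mask(cluster_mask, region_masks[[rid]])
    dec <- decode_roi(db, pm, config,
                      roi_id = paste0("cluster", cluster_id, "+region", rid))
    .tag_decoding(dec, as.integer(rid), as.integer(cluster_id))
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_tagged()
  rownames(res) <- NULL
  res
}

#' Decode cortical regions alone (quasi-null model)
#'
#' Repeats the pair decoding without the seed-cluster mask: each connected
#' cortical region is decoded on its own (FDR within each region), which
#' captures term associations explained by the cortex alone.
#'
#' @inheritParams decode_pairs
#' @return data.frame of tagged terms as in [decode_pairs()], with
#'   `cluster_id` NA.
#' @export
decode_regions <- function(db, region_masks, config = decoder_config()) {
  out <- lapply(names(region_masks), function(rid) {
    dec <- decode_roi(db, region_masks[[rid]], config,
                      roi_id = paste0("region", rid))
    .tag_decoding(dec, as.integer(rid), NULL)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_tagged()
  rownames(res) <- NULL
  res
}

.term_set <- function(x) {
  if (is.data.frame(x)) unique(x$term) else unique(as.character(x))
}

#' Terms common to the pair and cortical-only decodings
#'
#' Logical-AND conjunction of the two term sets (region tags ignored;
#' no repetitions).
#'
#' @param pair_terms,cortical_terms tagged-term data.frames (or character
#'   vectors of terms).
#' @return character vector of distinct common terms.
#' @export
term_intersection <- function(pair_terms, cortical_terms) {
  sort(intersect(.term_set(pair_terms), .term_set(cortical_terms)))
}

#' Region-tagged terms unique to the seed-cortical pairing
#'
#' For each common term, keeps the pair entries (term, region) whose
#' region-ID tag does not appear with that term in the cortical-only
#' decoding — the region's association with the term exists only jointly
#' with the seed cluster.
#'
#' @param pair_terms,cortical_terms tagged-term data.frames.
#' @param common_terms character vector from [term_intersection()].
#' @return data.frame of surviving tagged pair entries.
#' @export
unique_region_terms <- function(pair_terms, cortical_terms, common_terms) {
  keep <- pair_terms$term %in% common_terms
  key_pair <- paste(pair_terms$term, pair_terms$region_id, sep = "\r")
  key_cort <- paste(cortical_terms$term, cortical_terms$region_id, sep = "\r")
  out <- pair_terms[keep & !(key_pair %in% key_cort), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of a system's regions associated with a term
#'
#' @param n_surviving number of surviving region-term associations.
#' @param denominator total number of regions in the functionally connected
#'   system.
#' @return real in \[0, 100\].
#' @export
system_percentage <- function(n_surviving, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  100 * n_surviving / denominator
}

#' Mean Bayes factor of a term-system's surviving entries
#'
#' @param surviving_entries tagged-term data.frame (nonempty) or numeric
#'   vector of Bayes factors.
#' @return arithmetic mean Bayes factor.
#' @export
system_mean_bf <- function(surviving_entries) {
  bf <- if (is.data.frame(surviving_entries)) surviving_entries$bayes_factor
        else as.numeric(surviving_entries)
  if (length(bf) == 0L) stop("no surviving entries")
  mean(bf)
}

#' Lenient term-set difference (supplementary variant)
#'
#' Distinct terms found in the pair decoding but absent from the
#' cortical-only decoding.  Together with the strict common-term set this
#' partitions the pair-term vocabulary.
#'
#' @inheritParams term_intersection
#' @return character vector of terms.
#' @export
lenient_term_difference <- function(pair_terms, cortical_terms) {
  sort(setdiff(.term_set(pair_terms), .term_set(cortical_terms)))
}

#' Label image of the system associated with one term
#'
#' Marks each surviving region with its atlas label and the seed cluster
#' with the reserved label `max(atlas labels) + 1`.
#'
#' @param surviving_region_ids integer region IDs (must exist in the atlas).
#' @param atlas a [label_image()].
#' @param cluster_mask [brain_mask()] of the seed cluster.
#' @return A [label_image()].
#' @export
term_system_map <- function(surviving_region_ids, atlas, cluster_mask) {
  ids <- unique(as.integer(surviving_region_ids))
  unknown <- setdiff(ids, region_ids(atlas))
  if (length(unknown) > 0L)
    stop("unknown region id(s): ", paste(unknown, collapse = ", "))
  lab <- array(0L, dim = atlas$grid$shape)
  keep <- atlas$labels %in% ids
  lab[keep] <- atlas$labels[keep]
  cluster_code <- max(region_ids(atlas)) + 1L
  lab[cluster_mask$voxels] <- cluster_code
  lookup <- c(atlas$lookup[as.character(ids)],
              stats::setNames("seed_cluster", cluster_code))
  label_image(atlas$grid, lab, lookup)
}

#' Aggregate surviving terms into broader topics
#'
#' Joins terms against a user-supplied term-to-topic table (e.g. an
#' LDA-derived topic mapping) and counts surviving terms per topic.
#'
#' @param terms character vector of terms.
#' @param topic_table data.frame with columns `term` and `topic`.
#' @return list with `counts` (named integer vector per topic) and
#'   `unmapped` (terms absent from the table).
#' @export
aggregate_topics <- function(terms, topic_table) {
  terms <- unique(as.character(terms))
  if (is.null(topic_table) || nrow(topic_table) == 0L) {
    warning("empty topic mapping: all terms unmapped")
    return(list(counts = integer(0), unmapped = terms))
  }
  stopifnot(all(c("term", "topic") %in% names(topic_table)))
  m <- match(terms, topic_table$term)
  mapped <- !is.na(m)
  counts <- table(topic_table$topic[m[mapped]])
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       unmapped = terms[!mapped])
}

#' Systems-level decoding of one seed cluster
#'
#' Runs the full set-algebraic pipeline for one seed cluster and its
#' functionally connected cortical regions: pair decoding, quasi-null
#' cortical decoding, term intersection, region-ID set difference,
#' per-term system percentages (denominator: the number of connected
#' regions in the cluster's system; raw counts are also reported so any
#' other denominator can be recomputed) and mean Bayes factors, plus the
#' lenient supplementary term set.
#'
#' @param db an annotated [coord_db()].
#' @param cluster_mask [brain_mask()] of the seed cluster.
#' @param region_masks named list of [brain_mask()]s keyed by region ID
#'   (the cluster's functionally connected regions).
#' @param config a [decoder_config()].
#' @param cluster_id integer identifier.
#' @return list with `pair_terms`, `cortical_terms`, `common_terms`,
#'   `survivors`, `summary` (data.frame: `cluster_id`, `term`,
#'   `n_regions`, `region_ids`, `percentage`, `mean_bf`), `lenient_terms`,
#'   `n_connected`.
#' @export
decode_system <- function(db, cluster_mask, region_masks,
                          config = decoder_config(), cluster_id = 1L) {
  pair <- decode_pairs(db, cluster_mask, region_masks, config, cluster_id)
  cort <- decode_regions(db, region_masks, config)
  common <- term_intersection(pair, cort)
  surv <- unique_region_terms(pair, cort, common)
  lenient <- lenient_term_difference(pair, cort)

  # hard invariants of the set algebra, asserted on every run
  stopifnot(all(surv$term %in% .term_set(pair)))
  stopifnot(!any(paste(surv$term, surv$region_id) %in%
                 paste(cort$term, cort$region_id)))
  stopifnot(length(intersect(lenient, common)) == 0L)

  n_conn <- length(region_masks)
  terms <- unique(surv$term)
  summary <- do.call(rbind, lapply(terms, function(tm) {
    ent <- surv[surv$term == tm, , drop = FALSE]
    data.frame(cluster_id = cluster_id, term = tm,
               n_regions = nrow(ent),
               region_ids = paste(sort(ent$region_id), collapse = ","),
               percentage = system_percentage(nrow(ent), n_conn),
               mean_bf = system_mean_bf(ent),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary))
    summary <- data.frame(cluster_id = integer(0), term = character(0),
                          n_regions = integer(0), region_ids = character(0),
                          percentage = numeric(0), mean_bf = numeric(0))
  summary <- summary[order(-summary$percentage, summary$term), , drop = FALSE]
  rownames(summary) <- NULL
  list(pair_terms = pair, cortical_terms = cort, common_terms = common,
       survivors = surv, summary = summary, lenient_terms = lenient,
       n_connected = n_conn)
}
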