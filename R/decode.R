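#' Configuration for Bayesian reverse-inference decoding
#'
#' @param prior prior probability of a term-related brain state, in (0, 1);
#'   default 0.5 (equates base-rate differences between terms).
#' @param term_freq_threshold a study carries a term iff its frequency is
#'   strictly greater than this (default 0.001).
#' @param activation_radius_mm a study activates a mask iff any focus lies
#'   within this distance of a mask voxel center; 0 means the focus must
#'   map into the mask (default 10).
#' @param top_k number of highest-posterior terms retained (default 10).
#' @param alpha FDR significance level (default 0.05).
#' @param exclusion_list terms dropped from results (e.g. anatomical or
#'   scanner-technical terms); empty by default.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(prior = 0.5, term_freq_threshold = 0.001,
                           activation_radius_mm = 10, top_k = 10L,
                           alpha = 0.05, exclusion_list = character(0)) {
  stopifnot(prior > 0, prior < 1, term_freq_threshold >= 0,
            activation_radius_mm >= 0, top_k >= 1L, alpha > 0, alpha < 1)
  structure(list(prior = prior,
                 term_freq_threshold = term_freq_threshold,
                 activation_radius_mm = activation_radius_mm,
                 top_k = as.integer(top_k), alpha = alpha,
                 exclusion_list = as.character(exclusion_list)),
            class = "decoder_config")
}

#' Binary study-by-term indicator matrix
#'
#' Entry is 1 iff the study's term frequency strictly exceeds the
#' threshold.
#'
#' @param db an annotated [coord_db()].
#' @param threshold frequency threshold (strict `>`).
#' @return binary matrix, studies x terms, with all-zero terms flagged in
#'   the `"never_present"` attribute.
#' @export
term_indicator <- function(db, threshold = 0.001) {
  if (is.null(db$annotations)) stop("database has no annotations")
  ind <- (db$annotations > threshold) * 1L
  attr(ind, "never_present") <- colnames(ind)[colSums(ind) == 0]
  ind
}

#' Binary activation indicator of studies for a mask
#'
#' A study is marked active iff any of its foci lies within `radius_mm` of
#' any mask voxel center; with radius 0 a focus must map into the mask.
#'
#' @param db a [coord_db()].
#' @param mask a [brain_mask()].
#' @param radius_mm activation radius in mm.
#' @return named binary integer vector over studies.
#' @export
activation_indicator <- function(db, mask, radius_mm = 10) {
  if (mask_size(mask) == 0L) stop("empty mask")
  grid <- mask$grid
  out <- integer(n_experiments(db))
  if (radius_mm == 0) {
    in_mask <- logical(prod(grid$shape))
    in_mask[mask$voxels] <- TRUE
    for (e in seq_along(db$experiments)) {
      foci <- db$experiments[[e]]$foci
      if (nrow(foci) == 0L) next
      idx <- mm_to_voxel(foci, grid)
      inb <- attr(idx, "in_bounds")
      if (any(inb) &&
          any(in_mask[.ijk_to_linear(idx[inb, , drop = FALSE], grid$shape)]))
        out[e] <- 1L
    }
  } else {
    centers <- .linear_to_mm(mask$voxels, grid)
    c2 <- rowSums(centers^2)
    r2 <- radius_mm^2
    for (e in seq_along(db$experiments)) {
      foci <- db$experiments[[e]]$foci
      if (nrow(foci) == 0L) next
      # squared distances foci x mask-centers, early exit on first hit
      d2 <- outer(rowSums(foci^2), c2, `+`) - 2 * foci %*% t(centers)
      if (min(d2) <= r2 + 1e-9) out[e] <- 1L
    }
  }
  if (all(out == 0L)) warning("no study activates the mask")
  stats::setNames(out, db$ids)
}

#' Two-by-two activation/term contingency table
#'
#' @param activation,term binary indicator vectors over the same studies.
#' @return An object of class `decode_table`: counts `n11` (active & term),
#'   `n10`, `n01`, `n00` and the conditional probabilities
#'   `p_act_term` = P(activation | term) and
#'   `p_act_noterm` = P(activation | no term) (NA on zero margins).
#' @export
contingency_table <- function(activation, term) {
  stopifnot(length(activation) == length(term))
  a <- activation > 0; t <- term > 0
  n11 <- sum(a & t); n10 <- sum(a & !t)
  n01 <- sum(!a & t); n00 <- sum(!a & !t)
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 p_act_term = if (n11 + n01 > 0) n11 / (n11 + n01) else NA,
                 p_act_noterm = if (n10 + n00 > 0) n10 / (n10 + n00) else NA),
            class = "decode_table")
}

#' Forward inference probability P(activation | term, p)
#'
#' The prior-weighted convex combination
#' `p * P(activation | term) + (1 - p) * P(activation | no term)`.
#'
#' @param table a [contingency_table()].
#' @param p prior probability in (0, 1).
#' @return real in \[0, 1\].
#' @export
forward_prob <- function(table, p = 0.5) {
  if (is.na(table$p_act_term)) stop("undefined P(activation|term): term margin is zero")
  if (is.na(table$p_act_noterm)) stop("undefined P(activation|no term): complement margin is zero")
  p * table$p_act_term + (1 - p) * table$p_act_noterm
}

#' Reverse inference posterior P(term | activation, p)
#'
#' `p * P(activation | term) / P(activation | term, p)`.
#'
#' @inheritParams forward_prob
#' @return posterior probability in \[0, 1\].
#' @export
reverse_posterior <- function(table, p = 0.5) {
  fwd <- forward_prob(table, p)
  if (fwd == 0) stop("forward probability is zero; posterior undefined")
  p * table$p_act_term / fwd
}

#' Pearson chi-square test of activation-term independence
#'
#' Two-way chi-square without continuity correction, df = 1.  All margins
#' must be positive.
#'
#' @param table a [contingency_table()].
#' @return list with `statistic` and `p_value`.
#' @export
chisq_independence <- function(table) {
  m <- matrix(c(table$n11, table$n10, table$n01, table$n00), 2, 2,
              byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: chi-square undefined")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up procedure, applied within one region's term list.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param alpha significance level (default 0.05).
#' @return list with `q_values` and logical `reject`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(list(q_values = numeric(0), reject = logical(0)))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = q <= alpha)
}

#' Bayes factor from a reverse-inference posterior
#'
#' Posterior odds divided by prior odds:
#' `(posterior / (1 - posterior)) / (p / (1 - p))`.
#'
#' @param posterior posterior probability strictly between 0 and 1.
#' @param p prior probability strictly between 0 and 1 (default 0.5).
#' @return positive real.
#' @export
bayes_factor <- function(posterior, p = 0.5) {
  if (any(posterior <= 0) || any(posterior >= 1))
    stop("posterior must lie strictly between 0 and 1 (odds are infinite otherwise)")
  stopifnot(p > 0, p < 1)
  (posterior / (1 - posterior)) / (p / (1 - p))
}

#' Bayesian reverse-inference decoding of a region of interest
#'
#' For every vocabulary term, builds the activation/term contingency table,
#' computes the reverse posterior, forward probability, chi-square test and
#' Bayes factor, applies Benjamini-Hochberg FDR within this region's term
#' list, ranks terms by posterior (descending, ties broken alphabetically),
#' keeps the `top_k` highest, then drops terms failing the FDR threshold
#' post hoc and terms on the exclusion list.
#'
#' @param db an annotated [coord_db()].
#' @param mask a [brain_mask()] region of interest.
#' @param config a [decoder_config()].
#' @param roi_id optional identifier recorded in the result.
#' @param activation optional precomputed [activation_indicator()] vector
#'   (saves recomputation when decoding the same mask repeatedly).
#' @return An object of class `roi_decoding`: a data.frame with columns
#'   `term`, `posterior`, `forward`, `chi2`, `p_value`, `q_fdr`,
#'   `bayes_factor`, `significant`, at most `top_k` rows sorted by
#'   posterior; the full unfiltered table is in attribute `"all_terms"`.
#' @export
decode_roi <- function(db, mask, config = decoder_config(), roi_id = NULL,
                       activation = NULL) {
  if (is.null(db$annotations)) stop("database has no annotations")
  if (is.null(activation))
    activation <- activation_indicator(db, mask, config$activation_radius_mm)
  term_ind <- term_indicator(db, config$term_freq_threshold)
  terms <- sort(colnames(term_ind))   # order-invariance: canonical order
  rows <- lapply(terms, function(tm) {
    tab <- contingency_table(activation, term_ind[, tm])
    if (is.na(tab$p_act_term) || is.na(tab$p_act_noterm) ||
        (tab$n11 + tab$n10) == 0L || (tab$n01 + tab$n00) == 0L)
      return(NULL)                     # zero margin: term skipped
    fwd <- forward_prob(tab, config$prior)
    if (fwd == 0) return(NULL)
    post <- reverse_posterior(tab, config$prior)
    cs <- chisq_independence(tab)
    bf <- if (post > 0 && post < 1) bayes_factor(post, config$prior) else NA
    data.frame(term = tm, posterior = post, forward = fwd,
               chi2 = cs$statistic, p_value = cs$p_value,
               bayes_factor = bf, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) {
    res <- data.frame(term = character(0), posterior = numeric(0),
                      forward = numeric(0), chi2 = numeric(0),
                      p_value = numeric(0), q_fdr = numeric(0),
                      bayes_factor = numeric(0), significant = logical(0))
    return(structure(res, roi_id = roi_id, all_terms = res,
                     class = c("roi_decoding", "data.frame")))
  }
  fdr <- bh_fdr(res$p_value, config$alpha)
  res$q_fdr <- fdr$q_values
  res$significant <- fdr$reject
  res <- res[, c("term", "posterior", "forward", "chi2", "p_value",
                 "q_fdr", "bayes_factor", "significant")]
  full <- res[order(-res$posterior, res$term), , drop = FALSE]
  rownames(full) <- NULL
  top <- utils::head(full, config$top_k)
  top <- top[top$significant, , drop = FALSE]                 # post hoc
  top <- top[!(top$term %in% config$exclusion_list), , drop = FALSE]
  rownames(top) <- NULL
  structure(top, roi_id = roi_id, all_terms = full,
            class = c("roi_decoding", "data.frame"))
}

#' @export
print.roi_decoding <- function(x, ...) {
  id <- attr(x, "roi_id")
  cat("Reverse-inference decoding", if (!is.null(id)) paste0("of '", id, "'"),
      ":", nrow(x), "significant term(s)\n")
  if (nrow(x) > 0) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
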