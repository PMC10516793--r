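test_that("pair masks are voxel unions", {
  g <- tiny_grid(c(10, 10, 1))
  a <- brain_mask(g, 1:10)
  b <- brain_mask(g, 21:40)
  expect_equal(mask_size(pair_mask(a, b)), 30L)
  expect_equal(pair_mask(a, a)$voxels, a$voxels)       # idempotent
  c <- brain_mask(g, 5:14)
  expect_equal(mask_size(pair_mask(a, c)), 10 + 10 - 6)
  expect_error(pair_mask(a, brain_mask(g, integer(0))), "nonempty")
})

tagged <- function(terms, regions, bf = 2) {
  data.frame(term = terms, region_id = regions, cluster_id = 1L,
             posterior = 0.7, bayes_factor = bf, q_fdr = 0.01,
             stringsAsFactors = FALSE)
}

test_that("term intersection and set differences follow the set algebra", {
  pair <- tagged(c("A", "B", "C"), c(1L, 1L, 2L))
  cort <- tagged(c("B", "C", "D"), c(1L, 3L, 3L))
  expect_equal(term_intersection(pair, cort), c("B", "C"))
  expect_equal(term_intersection(pair, tagged("Z", 9L)), character(0))
  expect_equal(term_intersection(pair, pair), c("A", "B", "C"))
  # (C,2) survives: C is common but region 2 is untagged cortically
  surv <- unique_region_terms(pair, cort, term_intersection(pair, cort))
  expect_equal(surv$term, "C")
  expect_equal(surv$region_id, 2L)
  expect_equal(nrow(unique_region_terms(pair, pair,
                                        term_intersection(pair, pair))), 0L)
  expect_equal(lenient_term_difference(pair, cort), "A")
  expect_equal(lenient_term_difference(pair, pair), character(0))
})

test_that("strict and lenient sets partition the pair vocabulary", {
  set.seed(5)
  for (i in 1:20) {
    pair <- tagged(sample(LETTERS[1:6], 8, TRUE), sample(1:4, 8, TRUE))
    cort <- tagged(sample(LETTERS[1:6], 8, TRUE), sample(1:4, 8, TRUE))
    common <- term_intersection(pair, cort)
    lenient <- lenient_term_difference(pair, cort)
    expect_length(intersect(common, lenient), 0)
    expect_setequal(c(common, lenient), unique(pair$term))
    surv <- unique_region_terms(pair, cort, common)
    expect_true(all(surv$term %in% pair$term))
    expect_false(any(paste(surv$term, surv$region_id) %in%
                       paste(cort$term, cort$region_id)))
    expect_length(intersect(surv$term, lenient), 0)
  }
})

test_that("system percentages reproduce the worked fractions", {
  expect_equal(system_percentage(9, 15), 60)
  expect_equal(round(system_percentage(2, 3), 1), 66.7)
  expect_equal(system_percentage(0, 7), 0)
  expect_error(system_percentage(1, 0), "positive")
})

test_that("mean Bayes factors average the surviving entries", {
  expect_equal(system_mean_bf(tagged("A", 1L, bf = 2)), 2)
  expect_equal(system_mean_bf(tagged(c("A", "A"), c(1L, 2L),
                                     bf = c(2, 4))), 3)
  expect_equal(system_mean_bf(c(2, 4)), 3)
  # matches Bayes factors recomputed from posteriors
  posts <- c(0.7, 0.75, 0.8)
  ent <- data.frame(term = "A", region_id = 1:3, cluster_id = 1L,
                    posterior = posts,
                    bayes_factor = bayes_factor(posts, 0.5), q_fdr = 0.01)
  expect_equal(system_mean_bf(ent), mean(posts / (1 - posts)))
  expect_error(system_mean_bf(numeric(0)), "no surviving")
})

test_that("term-system maps mark surviving regions plus the seed cluster", {
  g <- tiny_grid(c(10, 1, 1))
  atlas <- label_image(g, c(1, 1, 2, 2, 3, 3, 0, 0, 0, 0))
  cl <- brain_mask(g, 9:10)
  m <- term_system_map(c(1L, 3L), atlas, cl)
  expect_equal(sum(m$labels == 1L), 2L)
  expect_equal(sum(m$labels == 3L), 2L)
  expect_equal(sum(m$labels == 2L), 0L)             # non-survivor absent
  expect_equal(sum(m$labels == 4L), 2L)             # cluster code
  expect_equal(sum(m$labels > 0L), 6L)              # region sizes + cluster
  expect_error(term_system_map(9L, atlas, cl), "unknown region",
               ignore.case = TRUE)
})

test_that("topic aggregation joins and conserves term counts", {
  tt <- data.frame(term = c("A", "B", "C"), topic = c("T1", "T1", "T2"))
  agg <- aggregate_topics(c("A", "B", "X"), tt)
  expect_equal(agg$counts[["T1"]], 2L)
  expect_equal(agg$unmapped, "X")
  expect_equal(sum(agg$counts), 2L)                 # = number mapped
  agg2 <- aggregate_topics(c("Y", "Z"), tt)
  expect_length(agg2$counts, 0)
  expect_warning(aggregate_topics("A", data.frame(term = character(0),
                                                  topic = character(0))),
                 "empty")
})

test_that("pair and quasi-null decodings recover a planted system", {
  sim <- small_sim(seed = 6)
  tr <- sim$truth
  cfg <- decoder_config(activation_radius_mm = 5)
  sys1 <- tr$systems[[1]]
  cl1 <- brain_mask(sim$grid, sim$seed_mask$voxels[tr$voxel_labels == 1])
  rmasks <- stats::setNames(lapply(sys1$connected_regions, function(r)
    region_mask(sim$atlas, r)), sys1$connected_regions)
  res <- suppressWarnings(decode_system(sim$db, cl1, rmasks, cfg,
                                        cluster_id = 1L))
  # pair decoding tags the planted term at every connected region
  expect_lte(nrow(res$pair_terms),
             cfg$top_k * length(rmasks))            # <= 10 per pair
  expect_true(all(res$pair_terms$region_id %in% sys1$connected_regions))
  # survivors: exactly the joint (never-hit) regions of the planted system
  surv1 <- res$survivors[res$survivors$term == "system_1", ]
  expect_setequal(surv1$region_id, sys1$joint_regions)
  # the hit regions are explained by the quasi-null and excluded
  expect_true(all(sys1$hit_regions %in%
                    res$cortical_terms$region_id[
                      res$cortical_terms$term == "system_1"]))
  # summary arithmetic
  row1 <- res$summary[res$summary$term == "system_1", ]
  expect_equal(row1$percentage,
               100 * length(sys1$joint_regions) /
                 length(sys1$connected_regions))
  expect_equal(row1$mean_bf, mean(surv1$bayes_factor))
})
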