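test_that("term indicators threshold strictly and flag dead terms", {
  db <- random_db(seed = 2)
  db$annotations[1, 1] <- 0.002
  db$annotations[2, 1] <- 0.001
  ind <- term_indicator(db, threshold = 0.001)
  expect_equal(ind[1, 1], 1L)
  expect_equal(ind[2, 1], 0L)            # equality fails the strict >
  ind0 <- term_indicator(db, threshold = 0)
  expect_equal(unname(ind0), unname((db$annotations > 0) * 1L),
               ignore_attr = TRUE)
  db$annotations[, 2] <- 0
  expect_true("term02" %in%
                attr(term_indicator(db, 0.001), "never_present"))
})

test_that("activation indicators match an exhaustive distance scan", {
  g <- tiny_grid(c(20, 20, 20))
  mask <- brain_mask(g, metaparc:::.ijk_to_linear(
    as.matrix(expand.grid(9:11, 9:11, 10)), g$shape))
  db <- coord_db(list(
    list(id = "in", foci = rbind(c(9, 9, 9))),       # inside the mask
    list(id = "near", foci = rbind(c(9, 9, 14))),    # 5 mm away
    list(id = "far", foci = rbind(c(1, 1, 1)))))
  expect_equal(unname(activation_indicator(db, mask, 0)), c(1L, 0L, 0L))
  expect_equal(unname(activation_indicator(db, mask, 6)), c(1L, 1L, 0L))
  expect_equal(unname(activation_indicator(db, mask, 4)), c(1L, 0L, 0L))
  # brute-force oracle on a random database
  rdb <- random_db(n_exp = 40, seed = 9, extent = 20)
  centers <- metaparc:::.linear_to_mm(mask$voxels, g)
  for (r in c(3, 8)) {
    oracle <- vapply(rdb$experiments, function(e) {
      dmin <- min(apply(e$foci, 1, function(f)
        min(sqrt(colSums((t(centers) - f)^2)))))
      as.integer(dmin <= r)
    }, 0L)
    expect_equal(unname(activation_indicator(rdb, mask, r)), oracle)
  }
})

test_that("forward and reverse probabilities follow the stated equations", {
  t1 <- tab4(40, 10, 10, 40)   # P(a|t)=0.8, P(a|not t)=0.2
  expect_equal(forward_prob(t1, 0.5), 0.5)
  expect_equal(reverse_posterior(t1, 0.5), 0.8)      # 0.4 / 0.5
  expect_equal(forward_prob(t1, 1), 0.8)             # boundary p = 1
  t2 <- tab4(30, 30, 20, 20)   # P(a|t) = P(a|not t) = 0.6
  for (p in c(0.2, 0.5, 0.9)) {
    expect_equal(forward_prob(t2, p), 0.6)
    expect_equal(reverse_posterior(t2, p), p)   # information-free term
  }
  t3 <- tab4(10, 0, 10, 40)    # P(a|not t) = 0
  expect_equal(reverse_posterior(t3, 0.5), 1)
  t0 <- tab4(0, 10, 0, 10)     # zero term margin
  expect_error(forward_prob(t0, 0.5), "margin")
})

test_that("Bayes' identity holds on random contingency tables", {
  set.seed(4)
  for (i in 1:30) {
    tb <- tab4(sample(1:30, 1), sample(1:30, 1),
               sample(1:30, 1), sample(1:30, 1))
    p <- runif(1, 0.1, 0.9)
    expect_equal(reverse_posterior(tb, p) * forward_prob(tb, p),
                 p * tb$p_act_term, tolerance = 1e-12)
  }
})

test_that("chi-square equals the definitional (O-E)^2/E oracle", {
  even <- tab4(10, 10, 10, 10)
  cs <- chisq_independence(even)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p_value, 1)
  # closed form n(ad - bc)^2 / (r1 r2 c1 c2)
  cs2 <- chisq_independence(tab4(30, 10, 10, 30))
  expect_equal(cs2$statistic, 20)
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:40, 4, replace = TRUE)
    tb <- tab4(n[1], n[2], n[3], n[4])
    o <- matrix(c(tb$n11, tb$n10, tb$n01, tb$n00), 2, 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    expect_equal(chisq_independence(tb)$statistic, sum((o - e)^2 / e),
                 tolerance = 1e-10)
  }
  expect_error(chisq_independence(tab4(0, 0, 5, 5)), "margin")
})

test_that("BH step-up matches hand-computed rejections", {
  r1 <- bh_fdr(rep(0.01, 10), alpha = 0.05)
  expect_true(all(r1$reject))
  # p_(i) <= i/4 * 0.05 holds at i = 4 (0.04 <= 0.05) so all reject
  r2 <- bh_fdr(c(0.001, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r2$reject))
  expect_equal(r2$q_values, c(0.004, 0.04, 0.04, 0.04))
  r3 <- bh_fdr(c(0.001, 0.04, 0.9), alpha = 0.05)
  expect_equal(r3$reject, c(TRUE, FALSE, FALSE))   # 0.04 > 2/3 * 0.05
  # q monotone in sorted p order
  set.seed(3)
  p <- sort(runif(25))
  expect_true(all(diff(bh_fdr(p)$q_values) >= 0))
  expect_true(all(bh_fdr(p)$q_values >= p))
  expect_length(bh_fdr(numeric(0))$q_values, 0)
})

test_that("Bayes factors are posterior odds over prior odds", {
  expect_equal(bayes_factor(0.5, 0.5), 1)
  expect_equal(round(bayes_factor(0.726, 0.5), 2), 2.65)
  expect_equal(round(bayes_factor(0.799, 0.5), 2), 3.98)
  expect_equal(bayes_factor(0.8, 0.2), (0.8 / 0.2) / (0.2 / 0.8))
  expect_error(bayes_factor(1, 0.5), "strictly")
  expect_error(bayes_factor(0, 0.5), "strictly")
})

test_that("ROI decoding recovers a planted term and respects its contract", {
  sim <- small_sim(seed = 2)
  cfg <- decoder_config(activation_radius_mm = 5)
  cl1 <- brain_mask(sim$grid,
                    sim$seed_mask$voxels[sim$truth$voxel_labels == 1])
  dec <- decode_roi(sim$db, cl1, cfg, roi_id = "cluster1")
  expect_s3_class(dec, "roi_decoding")
  expect_lte(nrow(dec), cfg$top_k)
  expect_equal(dec$term[1], "system_1")             # planted term ranks first
  expect_true(dec$significant[1])
  expect_true(all(diff(dec$posterior) <= 0))        # sorted by posterior
  expect_true(all(dec$q_fdr >= dec$p_value))
  # Bayes factors recompute from the posteriors
  expect_equal(dec$bayes_factor, bayes_factor(dec$posterior, cfg$prior))
  # exclusion list removes terms post hoc
  cfg2 <- decoder_config(activation_radius_mm = 5,
                         exclusion_list = "system_1")
  expect_false("system_1" %in% decode_roi(sim$db, cl1, cfg2)$term)
})

test_that("ROI decoding is invariant to study and term order", {
  sim <- small_sim(seed = 3)
  cfg <- decoder_config(activation_radius_mm = 5)
  cl <- brain_mask(sim$grid,
                   sim$seed_mask$voxels[sim$truth$voxel_labels == 2])
  base <- decode_roi(sim$db, cl, cfg)
  set.seed(1)
  perm <- sample(n_experiments(sim$db))
  db2 <- coord_db(sim$db$experiments[perm],
                  annotations = sim$db$annotations[perm, rev(seq_len(
                    ncol(sim$db$annotations)))])
  dec2 <- decode_roi(db2, cl, cfg)
  expect_equal(as.data.frame(dec2), as.data.frame(base))
})

test_that("permuted annotations decode to an empty or chance-level list", {
  sim <- small_sim(seed = 4)
  cfg <- decoder_config(activation_radius_mm = 5)
  cl <- brain_mask(sim$grid,
                   sim$seed_mask$voxels[sim$truth$voxel_labels == 1])
  act <- activation_indicator(sim$db, cl, cfg$activation_radius_mm)
  hits <- 0L
  for (i in 1:30) {
    dbp <- permute_annotations(sim$db, seed = i)
    dec <- suppressWarnings(decode_roi(dbp, cl, cfg, activation = act))
    hits <- hits + (nrow(dec) > 0L)
  }
  expect_lte(hits, 5L)   # any-rejection rate controlled near alpha
})
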