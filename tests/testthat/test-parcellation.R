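make_blobs <- function(n_per = 20, k = 2, sep = 10, d = 5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(k), function(c)
    matrix(rnorm(n_per * d, mean = c * sep), n_per, d)))
}

test_that("k-means recovers well-separated blobs deterministically", {
  x <- make_blobs()
  truth <- rep(1:2, each = 20)
  lab <- kmeans_labels(x, 2, seed = 4, restarts = 10)
  expect_equal(align_labels(truth, lab), truth, ignore_attr = TRUE)
  expect_identical(kmeans_labels(x, 2, seed = 4, restarts = 10),
                   kmeans_labels(x, 2, seed = 4, restarts = 10))
  # objective beats 100 random assignments
  obj <- attr(kmeans_labels(x, 3, seed = 1, restarts = 10), "objective")
  set.seed(9)
  rand_obj <- replicate(100, {
    l <- sample(1:3, nrow(x), replace = TRUE)
    sum(vapply(1:3, function(c) {
      xi <- x[l == c, , drop = FALSE]
      if (nrow(xi) == 0) 0 else sum(sweep(xi, 2, colMeans(xi))^2)
    }, 0))
  })
  expect_true(all(obj <= rand_obj))
  expect_error(kmeans_labels(x, nrow(x) + 1, 1), "exceeds")
  expect_warning(kmeans_labels(matrix(1, 5, 3), 2, 1), "distinct")
})

test_that("label alignment finds the optimal permutation", {
  ref <- c(1, 1, 2, 2, 3, 3)
  swapped <- c(3, 3, 1, 1, 2, 2)
  expect_equal(align_labels(ref, swapped), ref, ignore_attr = TRUE)
  # never decreases agreement, matches exhaustive search at k = 3
  set.seed(2)
  for (i in 1:20) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    al <- align_labels(a, b)
    expect_gte(sum(al == a), sum(b == a))
    perms <- metaparc:::.permutations(3)
    best <- max(vapply(perms, function(p) sum(p[b] == a), 0))
    expect_equal(sum(al == a), best)
  }
  expect_error(align_labels(c(1, 2), c(1, 2, 3)), "length")
  expect_error(align_labels(c(1, 2, 2), c(1, 2, 3)), "different k")
})

test_that("deviant fractions count disagreement with the modal label", {
  stack <- rbind(c(1, 2, 1, 2), c(1, 2, 1, 2), c(1, 2, 1, 2))
  expect_equal(deviant_fraction(stack), 0)
  stack[2, 4] <- 1                       # one discordant entry of 12
  expect_equal(deviant_fraction(stack), 1 / 12)
  expect_warning(deviant_fraction(stack[1, , drop = FALSE]), "single")
  # random stacks: agree with a direct count against the per-voxel mode
  set.seed(5)
  for (i in 1:10) {
    st <- matrix(sample(1:2, 5 * 40, replace = TRUE), 5, 40)
    mode_lab <- apply(st, 2, function(cl) which.max(tabulate(cl)))
    expect_equal(deviant_fraction(st),
                 mean(st != matrix(mode_lab, 5, 40, byrow = TRUE)))
  }
})

test_that("filter-range selection minimizes windowed deviants, earliest tie", {
  sizes <- seq(20, 38, 2)
  dev <- c(5, 4, 1, 1, 1, 4, 5, 6, 7, 8)
  sel <- select_filter_range(dev, sizes, 3)
  expect_equal(as.integer(sel), c(24, 26, 28))
  expect_equal(as.integer(select_filter_range(dev, sizes, 10)), sizes)
  dev2 <- c(2, 1, 1, 2, 1, 1, 2, 2, 2, 2)  # windows tied: earlier wins
  expect_equal(attr(select_filter_range(dev2, sizes, 2), "start"), 2L)
  expect_error(select_filter_range(dev, sizes, 1), "at least 2")
})

test_that("variation of information obeys its axioms", {
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               2 * log(2))
  set.seed(6)
  for (i in 1:15) {
    p1 <- sample(1:3, 25, replace = TRUE)
    p2 <- sample(1:4, 25, replace = TRUE)
    p3 <- sample(1:2, 25, replace = TRUE)
    expect_equal(variation_of_information(p1, p2),
                 variation_of_information(p2, p1))
    expect_gte(variation_of_information(p1, p2), 0)
    # triangle inequality
    expect_lte(variation_of_information(p1, p3),
               variation_of_information(p1, p2) +
                 variation_of_information(p2, p3) + 1e-12)
    # invariant to label permutation
    expect_equal(variation_of_information(p1, p2),
                 variation_of_information(p1, c(4, 1, 3, 2)[p2]))
  }
  expect_error(variation_of_information(integer(0), integer(0)), "empty")
})

test_that("VI agrees with an established implementation", {
  skip_if_not_installed("igraph")
  set.seed(8)
  for (i in 1:5) {
    p1 <- sample(1:3, 40, replace = TRUE)
    p2 <- sample(1:3, 40, replace = TRUE)
    expect_equal(variation_of_information(p1, p2),
                 igraph::compare(p1, p2, method = "vi"), tolerance = 1e-12)
  }
})

test_that("silhouette equals the brute-force definition", {
  x <- make_blobs(n_per = 15, sep = 20)
  lab <- rep(1:2, each = 15)
  expect_gt(silhouette_score(x, lab), 0.9)
  set.seed(7)
  for (i in 1:5) {
    xi <- matrix(rnorm(60), 20, 3)
    li <- sample(1:3, 20, replace = TRUE)
    if (length(unique(li)) < 2) next
    expect_equal(silhouette_score(xi, li), silhouette_bruteforce(xi, li),
                 tolerance = 1e-10)
  }
  # random labels on structureless data: near zero
  set.seed(11)
  xr <- matrix(rnorm(300), 100, 3)
  sils <- replicate(20, silhouette_score(xr, sample(1:2, 100, TRUE)))
  expect_lt(abs(mean(sils)), 0.05)
})

test_that("separation ratio matches hand-computed centroid arithmetic", {
  x <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  lab <- c(1, 1, 2, 2)
  # centroids (0,1) and (10,1): between = 10; within = 1 for every point
  expect_equal(separation_ratio(x, lab), 10)
  expect_gt(separation_ratio(make_blobs(sep = 20), rep(1:2, each = 20)), 5)
  expect_warning(
    r <- separation_ratio(rbind(c(0, 0), c(1, 1)), c(1, 2)), "infinite")
  expect_true(is.infinite(r))
})

test_that("hierarchy index measures nestedness into the coarser solution", {
  km1 <- c(1, 1, 1, 1, 2, 2, 2, 2)
  k_nested <- c(1, 1, 3, 3, 2, 2, 2, 2)     # cluster 1 split cleanly
  expect_equal(hierarchy_index(k_nested, km1), 0)
  k_cross <- c(1, 1, 3, 3, 2, 2, 2, 3)      # one of 8 voxels crosses
  expect_equal(hierarchy_index(k_cross, km1), 1 / 8)
  # random coarse labels, k = 2 vs 2: expected minority mass
  set.seed(3)
  fracs <- replicate(200, {
    fine <- rep(1:2, each = 25)
    coarse <- sample(1:2, 50, replace = TRUE)
    hierarchy_index(fine, coarse)
  })
  # per cluster the index is the minority fraction of a Binomial(25, 1/2):
  # E[min(X, 25 - X)] / 25 computed exactly as the oracle
  expected <- sum(stats::dbinom(0:25, 25, 0.5) * pmin(0:25, 25 - 0:25)) / 25
  expect_equal(mean(fracs), expected, tolerance = 0.02)
  expect_true(all(fracs >= 0 & fracs <= 0.5))
})

test_that("consensus takes the modal label with median-filter tie-breaks", {
  stack <- rbind(c(1, 1, 2), c(1, 2, 2), c(1, 2, 2))
  sizes <- c(20, 30, 40)
  cons <- consensus_parcellation(stack, sizes)
  expect_equal(cons$labels, c(1L, 2L, 2L))       # majority per voxel
  expect_equal(cons$consistent_voxels, c(1L, 1L))
  # identical stack reproduces itself
  st2 <- rbind(c(1, 2, 2), c(1, 2, 2))
  expect_equal(consensus_parcellation(st2, c(1, 2))$labels, c(1L, 2L, 2L))
  # 2-filter tie: label at the median (first) filter size
  st3 <- rbind(c(1, 1), c(2, 1))
  expect_warning(c3 <- consensus_parcellation(st3, c(1, 2)), "tie")
  expect_equal(c3$labels[1], 1L)
  # consensus agreement with the stack is at least any single filter's
  set.seed(10)
  st <- matrix(sample(1:3, 6 * 30, replace = TRUE), 6, 30)
  cons <- suppressWarnings(consensus_parcellation(st, 1:6))
  agree_cons <- sum(sweep(st, 2, cons$labels, `==`))
  for (f in 1:6)
    expect_gte(agree_cons, sum(sweep(st, 2, st[f, ], `==`)))
})

test_that("select_k picks the best mean rank with ties to smaller k", {
  m <- data.frame(k = 2:4,
                  deviants = c(0.3, 0.1, 0.4), vi = c(0.5, 0.2, 0.6),
                  silhouette = c(0.2, 0.6, 0.3), ratio = c(1.1, 2, 1.4),
                  hierarchy = c(NA, 0.02, 0.1))
  expect_equal(as.integer(select_k(m)), 3L)
  # unanimity tie between k = 3 and k = 4 resolves to 3
  m2 <- data.frame(k = 2:4, deviants = c(0.5, 0.1, 0.1),
                   silhouette = c(0.1, 0.5, 0.5))
  expect_equal(as.integer(select_k(m2)), 3L)
  m3 <- data.frame(k = 2:4, deviants = c(0.5, 0.1, 0.2),
                   vi = c(NA_real_, NA_real_, NA_real_))
  expect_warning(k3 <- select_k(m3), "dropped")
  expect_equal(as.integer(k3), 3L)
})

test_that("stability metrics are invariant to label permutation", {
  x <- make_blobs(n_per = 10, k = 3, sep = 6)
  lab <- rep(1:3, each = 10)
  perm <- c(2L, 3L, 1L)[lab]
  expect_equal(silhouette_score(x, lab), silhouette_score(x, perm))
  expect_equal(separation_ratio(x, lab), separation_ratio(x, perm))
  expect_equal(variation_of_information(lab, perm), 0)
  expect_equal(hierarchy_index(lab, rep(1:3, each = 10)),
               hierarchy_index(perm, rep(1:3, each = 10)))
})
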