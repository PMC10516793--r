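# small in-code fixtures shared across tests

# identity-affine grid (1 mm voxels, origin at voxel (1,1,1))
tiny_grid <- function(shape = c(12, 12, 12)) {
  brain_grid(shape, diag(4))
}

# database of hand-placed experiments on a tiny grid
tiny_db <- function() {
  coord_db(list(
    list(id = "a", foci = rbind(c(2, 2, 2), c(8, 8, 8)), n_subjects = 12),
    list(id = "b", foci = rbind(c(5, 5, 5))),
    list(id = "c", foci = rbind(c(2, 3, 2), c(9, 2, 4), c(4, 4, 4)))
  ))
}

# random database with annotations, deterministic given seed
random_db <- function(n_exp = 30, n_terms = 4, seed = 1, extent = 20) {
  set.seed(seed)
  exps <- lapply(seq_len(n_exp), function(i) {
    nf <- sample(1:5, 1)
    list(id = sprintf("e%03d", i),
         foci = matrix(runif(3 * nf, 1, extent - 1), nf, 3),
         n_subjects = sample(8:30, 1))
  })
  ann <- matrix(rbinom(n_exp * n_terms, 1, 0.3) * runif(n_exp * n_terms,
                                                        0.002, 0.05),
                n_exp, n_terms,
                dimnames = list(NULL, sprintf("term%02d", seq_len(n_terms))))
  coord_db(exps, annotations = ann)
}

# deterministic contingency table from four counts
tab4 <- function(n11, n10, n01, n00) {
  contingency_table(rep(c(1, 1, 0, 0), c(n11, n10, n01, n00)),
                    rep(c(1, 0, 1, 0), c(n11, n10, n01, n00)))
}

# brute-force mean silhouette from the definition
silhouette_bruteforce <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(c)
      mean(d[i, labels == c]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small synthetic study used by several pipeline tests (cheap settings)
small_sim <- function(seed = 1) {
  make_synthetic_db(synth_config(n_experiments = 200, seed = seed))
}
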