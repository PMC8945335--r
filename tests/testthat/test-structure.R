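test_that("Hamming distances equal brute-force XOR counts", {
  m <- random_matrix(n_ind = 6, n_loci = 12, n_pops = 2, seed = 21)
  d <- hamming_distances(m)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(d[i, j], sum(m$bands[i, ] != m$bands[j, ]))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_equal(unclass(d) / n_loci(m),
               unclass(hamming_distances(m, normalize = TRUE)),
               ignore_attr = TRUE)
  # identical and complementary individuals
  b <- rbind(a = rep(1L, 10), b = rep(1L, 10), c = rep(0L, 10))
  m2 <- marker_matrix(b, populations = c("x", "x", "y"))
  d2 <- hamming_distances(m2)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 10)
})

test_that("MSN tree edges match exhaustive spanning-tree search", {
  set.seed(33)
  for (rep in 1:3) {
    n <- sample(4:6, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- sample(100, n * (n - 1) / 2)  # unique weights
    d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    net <- minimum_spanning_network(d)
    tree <- net$edges[net$edges$in_tree, ]
    ex <- exhaustive_mst(d)
    expect_equal(sum(tree$weight), ex$weight)
    got <- apply(cbind(tree$from, tree$to), 1,
                 function(e) paste(sort(e), collapse = "-"))
    want <- apply(ex$edges, 1, function(e)
      paste(sort(rownames(d)[e]), collapse = "-"))
    expect_setequal(got, want)
    # with unique weights no tied edges are added
    expect_equal(nrow(net$edges), n - 1)
  }
})

test_that("MSN retains tied alternative edges (network, not tree)", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  dimnames(d) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- minimum_spanning_network(d)
  expect_equal(nrow(net$edges), 3)  # 3-cycle of equidistant nodes
  # two nodes: a single edge
  d2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(nrow(minimum_spanning_network(d2)$edges), 1)
})

test_that("PCA: variance accounting, sign convention, reconstruction", {
  # one variable locus -> first component carries all the variance
  b <- cbind(c(0L, 0L, 1L, 1L), 1L, 0L)
  m1 <- marker_matrix(b, populations = rep("z", 4))
  p1 <- marker_pca(m1)
  expect_equal(p1$pct_variance[1], 100)
  # eigenvalues match an independent symmetric eigendecomposition
  m <- random_matrix(n_ind = 8, n_loci = 5, n_pops = 2, seed = 3)
  p <- marker_pca(m)
  ev_ref <- eigen(cov(m$bands), symmetric = TRUE)$values
  expect_equal(p$eigenvalues[1:5], ev_ref, tolerance = 1e-9)
  expect_true(all(p$pct_variance >= 0))
  expect_lte(sum(p$pct_variance), 100 + 1e-9)
  # retaining all components reproduces the centered matrix
  centered <- scale(m$bands, center = TRUE, scale = FALSE)
  rec <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(rec - centered)), 1e-8)
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_along(p$eigenvalues))
    if (p$eigenvalues[k] > 1e-9)
      expect_gte(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  # constant matrix reports zero eigenvalues without crashing
  mc <- marker_matrix(matrix(1L, 4, 3), populations = rep("z", 4))
  expect_equal(sum(marker_pca(mc)$eigenvalues), 0)
})

test_that("DAPC recovers two separated clusters and handles k = 1", {
  hits <- 0
  for (s in 1:20) {
    d <- sim_design(n_pops = 2, n_per_pop = 15, n_loci = 60, k_ancestral = 2,
                    pop_to_cluster = c(1, 2), fst_target = 0.6,
                    seed = 400 + s)
    m <- simulate_markers(d)$matrix
    r <- suppressWarnings(dapc_markers(m, k_max = 6, seed = s))
    if (r$k == 2) hits <- hits + 1
  }
  expect_gte(hits, 18)
  m1 <- simulate_markers(sim_design(n_pops = 1, n_per_pop = 12, n_loci = 20,
                                    fst_target = 0.2, seed = 2))$matrix
  r1 <- dapc_markers(m1, k = 1)
  expect_equal(r1$k, 1)
  expect_equal(ncol(r1$scores), 0)
  expect_true(all(r1$assignments == 1))
  expect_error(dapc_markers(m1, k = 50), "exceed")
  # discriminant function count <= k - 1
  sim <- simulate_markers(study_preset())
  r6 <- dapc_markers(sim$matrix, k = 3, seed = 1)
  expect_lte(ncol(r6$scores), 2)
})

test_that("admixture sampler: Q rows sum to 1, K = 1 degenerate, determinism", {
  m <- simulate_markers(sim_design(n_pops = 2, n_per_pop = 10, n_loci = 20,
                                   k_ancestral = 2, pop_to_cluster = c(1, 2),
                                   fst_target = 0.4, seed = 6))$matrix
  r1 <- admixture_mcmc(m, K = 1, n_burnin = 50, n_sample = 100, seed = 1)
  expect_true(all(r1$Q == 1))
  r3 <- admixture_mcmc(m, K = 3, n_burnin = 200, n_sample = 300, seed = 2)
  expect_true(all(abs(rowSums(r3$Q) - 1) < 1e-9))
  r3b <- admixture_mcmc(m, K = 3, n_burnin = 200, n_sample = 300, seed = 2)
  expect_identical(r3$Q, r3b$Q)
  expect_identical(r3$loglik, r3b$loglik)
  expect_error(admixture_mcmc(m, K = 50, n_burnin = 10, n_sample = 10),
               "exceed")
})

test_that("admixture posterior concentrates for fixed opposite populations", {
  b <- rbind(matrix(rep(c(1L, 0L), each = 15), 6, 30, byrow = TRUE),
             matrix(rep(c(0L, 1L), each = 15), 6, 30, byrow = TRUE))
  m <- marker_matrix(b, populations = rep(c("A", "B"), each = 6))
  r <- admixture_mcmc(m, K = 2, n_burnin = 500, n_sample = 1000, seed = 9)
  self1 <- colMeans(r$Q[1:6, ])
  self2 <- colMeans(r$Q[7:12, ])
  k1 <- which.max(self1)
  expect_gt(self1[k1], 0.95)
  expect_gt(self2[-k1][1], 0.95)
})

test_that("Evanno table matches the arithmetic oracle and flat L gives 0", {
  mk_run <- function(K, l) structure(list(K = K, loglik = l),
                                     class = "admixture_run")
  mus <- c(-1000, -600, -580, -575)
  runs <- unlist(lapply(1:4, function(k)
    list(mk_run(k, mus[k] - 1), mk_run(k, mus[k] + 1))), recursive = FALSE)
  ev <- evanno(runs)
  # frozen: L' = (400, 20, 5); |L''| = (380, 15); sd = sqrt(2)
  expect_equal(ev$delta_k[2], 268.700576850888, tolerance = 1e-10)
  expect_equal(ev$delta_k[3], 10.6066017177982, tolerance = 1e-10)
  expect_equal(attr(ev, "best_k"), 2)
  # L exactly linear in K: all interior Delta K = 0
  lin <- unlist(lapply(1:4, function(k)
    list(mk_run(k, -100 * k - 1), mk_run(k, -100 * k + 1))),
    recursive = FALSE)
  ev2 <- evanno(lin)
  expect_equal(ev2$delta_k[2:3], c(0, 0))
  # zero replicate spread -> Inf with a warning
  degen <- unlist(lapply(1:3, function(k)
    list(mk_run(k, -10 * k^2), mk_run(k, -10 * k^2))), recursive = FALSE)
  expect_warning(ev3 <- evanno(degen), "Inf")
  expect_true(is.infinite(ev3$delta_k[2]))
  expect_error(evanno(runs[1:4]), "consecutive")
})
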