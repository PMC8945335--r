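test_that("Gst closed forms: identical populations and fixed opposites", {
  # identical allele frequencies in both populations -> Gst = 0
  f_same <- structure(list(
    x = matrix(0.25, 2, 2), q = matrix(0.5, 2, 2), p = matrix(0.5, 2, 2),
    n = c(a = 50, b = 50), populations = c("a", "b"), loci = c("L1", "L2")),
    class = "locus_freqs")
  expect_equal(nei_gst(f_same)$gst, 0)
  # fixed for opposite states: Hs = 0, Ht = 0.5, Gst = 1
  f_opp <- structure(list(
    x = matrix(c(0, 1), 2, 1), q = matrix(c(0, 1), 2, 1),
    p = matrix(c(1, 0), 2, 1), n = c(a = 50, b = 50),
    populations = c("a", "b"), loci = "L1"), class = "locus_freqs")
  r <- nei_gst(f_opp)
  expect_equal(r$gst, 1)
  expect_equal(r$ht, 0.5)
  expect_equal(r$hs, 0)
  expect_lte(r$hs, r$ht)
  # all-monomorphic matrix has no defined Gst
  mono <- marker_matrix(matrix(1L, 4, 3), populations = c("a", "a", "b", "b"))
  expect_error(nei_gst(mono), "monomorphic")
})

test_that("Crow-Aoki gene flow matches direct arithmetic", {
  r <- gene_flow_crow_aoki(0.25, n_pops = 6)
  expect_equal(r$alpha, 1.44)
  expect_equal(r$nm, 0.520833333333333, tolerance = 1e-12)
  expect_equal(gene_flow_crow_aoki(1, n_pops = 4)$nm, 0)
  expect_error(gene_flow_crow_aoki(0, n_pops = 4), "infinite")
})

test_that("AMOVA components equal the brute-force sums-of-squares oracle", {
  m <- toy_matrix()
  a <- amova_binary(m, n_perm = 0)
  # frozen values from an explicit double-loop computation on this fixture
  expect_equal(unname(a$ss["total"]), 5.375)
  expect_equal(unname(a$ss["among"]), 1.125)
  expect_equal(unname(a$ss["within"]), 4.25)
  expect_equal(unname(a$ms["within"]), 0.708333333333333, tolerance = 1e-12)
  expect_equal(unname(a$sigma2["among"]), 0.104166666666667, tolerance = 1e-12)
  expect_equal(a$phi_st, 0.128205128205128, tolerance = 1e-12)
  # and against the independent oracle run here
  o <- brute_amova(m$bands, m$pop)
  expect_equal(unname(a$ss["among"]), o$ss_among)
  expect_equal(unname(a$sigma2["among"]), o$sigma2_among)
  expect_equal(a$phi_st, o$phi)
  # percentages sum to 100 exactly before rounding
  expect_equal(unname(sum(a$pct)), 100)
})

test_that("AMOVA under an exchangeable null: Phi near 0, large p", {
  set.seed(8)
  base <- matrix(rbinom(400, 1, 0.5), 20, 20)
  b <- rbind(base, base)   # two copies of the same multiset of genotypes
  m <- marker_matrix(b, populations = rep(c("A", "B"), each = 20))
  a <- amova_binary(m, n_perm = 199, seed = 3)
  expect_lt(abs(a$phi_st), 0.1)
  expect_gt(a$p_value, 0.5)
  expect_error(amova_binary(marker_matrix(matrix(c(1L, 0L, 1L), 3, 1),
                                          populations = c("a", "b", "b")),
                            n_perm = 0), "single individual")
})

test_that("AMOVA permutation p is reproducible under a seed", {
  sim <- simulate_markers(study_preset())
  p1 <- amova_binary(sim$matrix, n_perm = 99, seed = 7)$p_value
  p2 <- amova_binary(sim$matrix, n_perm = 99, seed = 7)$p_value
  expect_identical(p1, p2)
})

test_that("pairwise Phi_st agrees with per-pair AMOVA and linearizes", {
  t3 <- toy3_matrix()
  pw <- pairwise_fst(t3)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    sub <- subset_markers(t3, keep_populations = pair)
    expect_equal(pw$phi_st[pair[1], pair[2]],
                 amova_binary(sub, n_perm = 0)$phi_st)
  }
  expect_equal(pw$phi_st, t(pw$phi_st))
  expect_equal(unname(diag(pw$phi_st)), rep(0, 3))
  expect_equal(unname(diag(pw$linearized)), rep(0, 3))
  # linearization closed form
  expect_equal(pw$linearized["A", "B"],
               pw$phi_st["A", "B"] / (1 - pw$phi_st["A", "B"]))
  # duplicated populations give ~0 on both scales
  set.seed(9)
  base <- matrix(rbinom(400, 1, 0.5), 20, 20)
  dup <- marker_matrix(rbind(base, base), populations = rep(c("X", "Y"), each = 20))
  pwd <- pairwise_fst(dup)
  expect_lt(abs(pwd$phi_st["X", "Y"]), 0.1)
})

test_that("Mantel r is exact for a monotone relation and p matches enumeration", {
  g <- population_geo(c("A", "B", "C", "D"),
                      x = c(0, 3, 7, 13), y = c(0, 0, 0, 0))
  dg <- geo_distances(g)
  gen <- log10(dg) * 2 + 1   # perfect linear function of log distance
  diag(gen) <- 0
  r <- mantel_ibd(gen, g, n_perm = 999, seed = 2, n_boot = 0)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$spearman_rho, 1)
  # exhaustive null over all 4! = 24 relabelings (independent enumeration)
  ut <- upper.tri(gen)
  xv <- log10(dg)[ut]
  r_all <- vapply(all_perms(4), function(o) cor(xv, gen[o, o][ut]), 0)
  p_exh <- mean(r_all >= r$r - 1e-12)
  se_mc <- sqrt(p_exh * (1 - p_exh) / r$n_perm)
  expect_lt(abs(r$p - p_exh), 2 * se_mc + 1 / (r$n_perm + 1))
  # a noisy genetic matrix: Monte-Carlo p still tracks the exhaustive p
  set.seed(5)
  noise <- matrix(0, 4, 4); noise[ut] <- runif(6); noise <- noise + t(noise)
  gen2 <- gen + 3 * noise
  r2 <- mantel_ibd(gen2, g, n_perm = 4999, seed = 11, n_boot = 200)
  r2_all <- vapply(all_perms(4), function(o) cor(xv, gen2[o, o][ut]), 0)
  p2_exh <- mean(r2_all >= r2$r - 1e-12)
  se2 <- sqrt(p2_exh * (1 - p2_exh) / r2$n_perm)
  expect_lt(abs(r2$p - p2_exh), 2 * se2 + 1 / (r2$n_perm + 1))
  expect_true(r2$ci95[1] <= r2$r && r2$r <= r2$ci95[2])
  # zero distances are rejected (log undefined)
  dg0 <- dg; dg0["A", "B"] <- dg0["B", "A"] <- 0
  expect_error(mantel_ibd(gen, dg0, n_perm = 9), "zero geographic")
  expect_error(mantel_ibd(gen[1:3, 1:3], dg[1:3, 1:3], n_perm = 9), ">= 4")
})

test_that("Mantel agrees with an established implementation", {
  skip_if_not_installed("vegan")
  sim <- simulate_markers(study_preset())
  pw <- pairwise_fst(sim$matrix)
  geo <- study_preset()$geo
  dg <- geo_distances(geo)[rownames(pw$linearized), rownames(pw$linearized)]
  ours <- mantel_ibd(pw$linearized, dg, n_perm = 999, seed = 3, n_boot = 0)
  ref <- vegan::mantel(as.dist(log10(dg)), as.dist(pw$linearized),
                       permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})
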