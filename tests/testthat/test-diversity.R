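test_that("Lynch-Milligan estimator matches direct arithmetic and boundaries", {
  # population of 20: 15 with band (x = 0.25), oracle value from the
  # closed-form expression sqrt(x) / (1 - (x(1-x)/n) / (8 x^2))
  b <- matrix(0L, 40, 1, dimnames = list(sprintf("i%02d", 1:40), "L1"))
  b[1:15, 1] <- 1L          # pop1: x = 0.25
  b[21:40, 1] <- 1L         # pop2: x = 0 -> q = 0
  m <- marker_matrix(b, populations = rep(c("pop1", "pop2"), each = 20))
  f <- estimate_frequencies(m)
  expect_equal(f$q["pop1", "L1"], 0.509554140127389, tolerance = 1e-12)
  expect_equal(f$p["pop1", "L1"] + f$q["pop1", "L1"], 1)
  expect_equal(f$q["pop2", "L1"], 0)
  expect_equal(f$p["pop2", "L1"], 1)
  # x = 1: no individual shows the band -> q clamps to 1
  b2 <- matrix(0L, 4, 1); b2[1:2] <- 1L
  m2 <- marker_matrix(b2, populations = c("a", "a", "b", "b"))
  expect_equal(estimate_frequencies(m2)$q[2, 1], 1)
  # bias term needs n >= 2
  m3 <- marker_matrix(matrix(c(1L, 0L), 2, 1), populations = c("a", "b"))
  expect_error(estimate_frequencies(m3), ">= 2 individuals")
})

test_that("frequency estimates converge to generator truth (property)", {
  d <- sim_design(n_pops = 2, n_per_pop = 500, n_loci = 40, fst_target = 0.3,
                  seed = 12)
  sim <- simulate_markers(d)
  f <- estimate_frequencies(sim$matrix)
  bias <- mean(abs(f$q - (1 - sim$truth$p_pop)))
  expect_lt(bias, 0.02)
})

test_that("allele counts: states, private alleles, effective number", {
  t3 <- toy3_matrix()
  ac <- allele_counts(t3)
  rownames(ac) <- ac$population
  # hand census: A is polymorphic at L1,L2 (2 states) and monomorphic at
  # L3,L4,L5,L6 (1 state) -> 8; same logic for B and C
  expect_equal(ac["A", "na"], 8)
  expect_equal(ac["B", "na"], 9)
  expect_equal(ac["C", "na"], 8)
  expect_equal(ac$private, c(2, 1, 1))  # L1+L2 -> A, L3 -> B, L6 -> C
  # monomorphic population: na = L, ne = 1
  mono <- marker_matrix(matrix(1L, 3, 4), populations = rep("z", 3))
  acm <- allele_counts(mono)
  expect_equal(acm$na, 4)
  expect_equal(acm$ne, 1)
  expect_true(all(ac$private <= ac$na))
})

test_that("synthetic private bands are tallied in exactly one population", {
  sim <- simulate_markers(study_preset())
  ac <- allele_counts(sim$matrix)
  rownames(ac) <- ac$population
  expect_gte(ac["Presa Cebolletas", "private"], 4)
  expect_gte(ac["Puente Cuates", "private"], 1)
})

test_that("He, Shannon I and %P behave as closed forms dictate", {
  mono <- marker_matrix(matrix(1L, 4, 5), populations = rep("z", 4))
  h <- heterozygosity(estimate_frequencies(mono))
  expect_equal(h$he, 0)
  expect_equal(h$i, 0)
  expect_equal(h$pct_p, 0)
  # p = q = 0.5 exactly: He = 0.5, I = ln 2
  f <- structure(list(x = matrix(0.25, 1, 1), q = matrix(0.5, 1, 1),
                      p = matrix(0.5, 1, 1), n = c(a = 100),
                      populations = "a", loci = "L1"),
                 class = "locus_freqs")
  h2 <- heterozygosity(f)
  expect_equal(h2$he, 0.5)
  expect_equal(h2$i, log(2))
  expect_equal(h2$pct_p, 100)
})

test_that("diversity invariants: He range, relabeling invariance, %P monotone", {
  sim <- simulate_markers(study_preset())
  div <- diversity_summary(sim$matrix)
  expect_true(all(div$he >= 0 & div$he <= 0.5))
  expect_true(all(div$pct_p >= 0 & div$pct_p <= 100))
  # shuffling individuals leaves He and I untouched
  m <- sim$matrix
  set.seed(1); o <- sample(nrow(m$bands))
  m2 <- marker_matrix(m$bands[o, ], populations = m$pop[o])
  div2 <- diversity_summary(m2)
  expect_equal(div2[order(div2$population), c("he", "i")],
               div[order(div$population), c("he", "i")], ignore_attr = TRUE)
  # replacing a polymorphic locus with a monomorphic one cannot raise %P
  b <- toy3_matrix()$bands
  b2 <- b; b2[, "L5"] <- 1L
  p_before <- heterozygosity(estimate_frequencies(toy3_matrix()))$pct_p
  p_after <- heterozygosity(estimate_frequencies(
    marker_matrix(b2, populations = rep(c("A", "B", "C"), each = 3))))$pct_p
  expect_true(all(p_after <= p_before))
})

test_that("exact differentiation test matches hypergeometric enumeration", {
  # pop A: 9 band / 1 none; pop B: 1 band / 9 none
  b <- matrix(0L, 20, 1)
  b[c(1:9, 11), 1] <- 1L
  m <- marker_matrix(b, populations = rep(c("A", "B"), each = 10))
  res <- exact_differentiation_test(m)
  expect_equal(unname(res$p_locus[1]), fisher_enum_p(9, 1, 1, 9),
               tolerance = 1e-9)
  # identical band counts in every population -> p = 1 at every locus
  b2 <- cbind(rep(c(1L, 0L), 10), rep(1L, 20))
  m2 <- marker_matrix(b2, populations = rep(c("A", "B"), each = 10))
  res2 <- exact_differentiation_test(m2)
  expect_true(all(res2$p_locus == 1))
  expect_gt(res2$p_combined, 0.99)
  # > 2 populations goes through the seeded Monte-Carlo path, reproducibly
  t3 <- toy3_matrix()
  r1 <- exact_differentiation_test(t3, b = 2000, seed = 4)
  r2 <- exact_differentiation_test(t3, b = 2000, seed = 4)
  expect_identical(r1$p_locus, r2$p_locus)
  expect_error(exact_differentiation_test(
    marker_matrix(matrix(1L, 3, 2), populations = rep("A", 3))),
    ">= 2 populations")
})
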