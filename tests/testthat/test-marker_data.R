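test_that("construction validates binary cells, labels and populations", {
  b <- rbind(a = c(1, 0, 1, 1), b = c(0, 0, 1, 0), c = c(1, 1, 1, 0))
  m <- marker_matrix(b, populations = c("P1", "P1", "P2"))
  expect_equal(n_individuals(m), 3)
  expect_equal(n_loci(m), 4)
  expect_equal(populations(m), c("P1", "P2"))

  b2 <- b; b2[2, 3] <- 2
  expect_error(marker_matrix(b2, populations = c("P1", "P1", "P2")),
               "non-binary cell.*'b'.*", perl = TRUE)
  b3 <- b; rownames(b3) <- c("a", "a", "c")
  expect_error(marker_matrix(b3, populations = c("P1", "P1", "P2")),
               "duplicate individual")
  expect_error(marker_matrix(b, populations = c("P1", NA, "P2")),
               "without a population")
})

test_that("missing sentinel is stored but rejected by statistics (fail fast)", {
  b <- rbind(a = c(1, NA, 1), b = c(0, 0, 1), c = c(1, 1, 1), d = c(0, 1, 0))
  m <- marker_matrix(b, populations = c("P1", "P1", "P2", "P2"))
  expect_s3_class(m, "marker_matrix")
  expect_error(estimate_frequencies(m), "missing")
  expect_error(amova_binary(m, n_perm = 0), "missing")
})

test_that("all three dialects round-trip through write/read", {
  m <- random_matrix(n_ind = 9, n_loci = 5, n_pops = 3, seed = 42)
  for (dialect in c("csv", "genalex", "structure")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_marker_matrix(m, path, dialect)
    m2 <- read_marker_matrix(path, dialect)
    expect_identical(unname(m2$bands), unname(m$bands), label = dialect)
    expect_identical(rownames(m2$bands), rownames(m$bands), label = dialect)
    if (dialect != "structure") {
      expect_identical(m2$pop, m$pop, label = dialect)
    } else {
      # structure integer-recodes population labels; the partition survives
      expect_identical(as.integer(m2$pop), as.integer(m$pop))
    }
  }
})

test_that("round-trip identity holds on random matrices (property)", {
  for (seed in 1:5) {
    m <- random_matrix(n_ind = 6 + seed, n_loci = 4 + seed, n_pops = 2, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_marker_matrix(m, path, "csv")
    expect_identical(read_marker_matrix(path, "csv"), m)
  }
})

test_that("single-individual matrices are writable and readable", {
  m <- marker_matrix(matrix(c(1L, 0L), 1, 2, dimnames = list("x", c("L1", "L2"))),
                     populations = "P1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_matrix(m, path, "csv")
  expect_identical(read_marker_matrix(path, "csv"), m)
})

test_that("reader rejects non-binary cells with the cell position", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,population,L1,L2", "a,P1,0,1", "b,P1,2,0",
               "c,P2,1,1"), path)
  expect_error(read_marker_matrix(path, "csv"), "'b'.*'L1'", perl = TRUE)
})

test_that("subset keeps requested units, never invents bands, and composes", {
  m <- random_matrix(n_ind = 12, n_loci = 6, n_pops = 3, seed = 7)
  expect_identical(subset_markers(m, individuals = rownames(m$bands))$bands,
                   m$bands)
  keep2 <- setdiff(populations(m), "P3")
  s <- subset_markers(m, keep_populations = keep2)
  expect_setequal(populations(s), keep2)
  expect_equal(n_loci(s), n_loci(m))
  expect_lte(total_bands(s), total_bands(m))
  # brute-force band census agreement on the toy matrix
  t3 <- toy3_matrix()
  sub <- subset_markers(t3, keep_populations = c("A", "B"))
  expect_equal(total_bands(sub), sum(colSums(t3$bands[1:6, ]) > 0))
  # idempotence and commutation on disjoint removals
  s1 <- subset_markers(subset_markers(m, keep_populations = keep2),
                       keep_populations = keep2)
  expect_identical(s1, s)
  ab <- subset_markers(subset_markers(m, keep_populations = c("P1", "P2")),
                       keep_populations = "P1")
  ba <- subset_markers(m, keep_populations = "P1")
  expect_identical(ab, ba)
  expect_error(subset_markers(m, keep_populations = "nope"), "unknown population")
  expect_error(subset_markers(m, individuals = character(0)), "no individuals")
})

test_that("population coordinates project and validate", {
  g <- population_geo(c("A", "B", "C"), x = c(0, 3, 6), y = c(0, 4, 0))
  d <- geo_distances(g)
  expect_equal(d["A", "B"], 5)
  expect_equal(d, t(d))
  expect_error(population_geo(c("A", "A"), x = c(0, 1), y = c(0, 1)),
               "one coordinate pair")
  expect_error(population_geo(c("A", "B"), x = c(1, 1), y = c(2, 2)),
               "distance > 0")
  # lon/lat projection: ~1 degree latitude is ~110.6 km
  g2 <- population_geo(c("A", "B"), x = c(-102.5, -102.5), y = c(22, 23),
                       lonlat = TRUE)
  expect_equal(geo_distances(g2)["A", "B"], 110.57, tolerance = 1e-6)
})
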