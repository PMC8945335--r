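# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (enumeration, explicit arithmetic) and never call the
# package functions they check.

toy_matrix <- function() {
  b <- rbind(i1 = c(0, 0, 0), i2 = c(0, 1, 0), i3 = c(1, 0, 0),
             i4 = c(1, 1, 1), i5 = c(1, 1, 1), i6 = c(1, 1, 1),
             i7 = c(0, 1, 1), i8 = c(1, 1, 0))
  colnames(b) <- c("L1", "L2", "L3")
  marker_matrix(b, populations = rep(c("A", "B"), each = 4))
}

# 3-population matrix with hand-countable private bands:
#  L1, L2 private to A; L3 private to B; L4 shared by B and C only;
#  L5 everywhere; L6 private to C.
toy3_matrix <- function() {
  b <- rbind(
    a1 = c(1, 1, 0, 0, 1, 0), a2 = c(1, 0, 0, 0, 1, 0), a3 = c(0, 1, 0, 0, 1, 0),
    b1 = c(0, 0, 1, 1, 1, 0), b2 = c(0, 0, 1, 0, 1, 0), b3 = c(0, 0, 0, 1, 0, 0),
    c1 = c(0, 0, 0, 1, 1, 1), c2 = c(0, 0, 0, 1, 0, 1), c3 = c(0, 0, 0, 0, 1, 1))
  colnames(b) <- paste0("L", 1:6)
  marker_matrix(b, populations = rep(c("A", "B", "C"), each = 3))
}

random_matrix <- function(n_ind = 10, n_loci = 8, n_pops = 2, seed = 1) {
  set.seed(seed)
  b <- matrix(rbinom(n_ind * n_loci, 1, runif(n_loci, 0.2, 0.8)[
    rep(seq_len(n_loci), each = n_ind)]), n_ind, n_loci)
  pops <- sample(sprintf("P%d", seq_len(n_pops)), n_ind, replace = TRUE)
  # guarantee every population is represented
  pops[seq_len(n_pops)] <- sprintf("P%d", seq_len(n_pops))
  marker_matrix(b, populations = pops)
}

# All permutations of 1..n (recursive; for exhaustive Mantel nulls)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

# Exhaustive minimum spanning tree weight and edge sets via Pruefer sequences
# (all n^(n-2) labelled trees).
prufer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, 0, 2)
  for (s in seq) {
    leaf <- which(degree == 1L)[1]
    edges <- rbind(edges, c(leaf, s))
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  rbind(edges, last)
}

exhaustive_mst <- function(d) {
  n <- nrow(d)
  seqs <- if (n == 2) list(integer(0)) else {
    grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
    lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  }
  best_w <- Inf; best_edges <- NULL
  for (s in seqs) {
    e <- prufer_to_edges(s, n)
    w <- sum(d[e])
    if (w < best_w - 1e-12) { best_w <- w; best_edges <- e }
  }
  list(weight = best_w, edges = best_edges)
}

# Brute-force AMOVA pieces from a band matrix (explicit double loops).
brute_amova <- function(bands, pop) {
  n <- nrow(bands)
  pop <- as.character(pop)
  d2 <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d2[i, j] <- sum(bands[i, ] != bands[j, ])
  sstot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sstot <- sstot + d2[i, j]
  sstot <- sstot / n
  ssw <- 0
  for (g in unique(pop)) {
    idx <- which(pop == g); s <- 0
    for (a in idx) for (cc in idx) if (a < cc) s <- s + d2[a, cc]
    ssw <- ssw + s / length(idx)
  }
  G <- length(unique(pop))
  msa <- (sstot - ssw) / (G - 1); msw <- ssw / (n - G)
  n0 <- (n - sum(table(pop)^2) / n) / (G - 1)
  s2a <- (msa - msw) / n0
  list(ss_total = sstot, ss_among = sstot - ssw, ss_within = ssw,
       ms_among = msa, ms_within = msw, sigma2_among = s2a,
       phi = s2a / (s2a + msw))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
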