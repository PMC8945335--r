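#' Hamming distances between individuals
#'
#' Number of loci at which two individuals differ in band state (optionally
#' normalized by the locus count).
#'
#' @param m a `marker_matrix`.
#' @param normalize divide by the number of loci.
#' @return symmetric matrix (class `hamming_dist`) with zero diagonal; the
#'   population of each individual is kept in the `"populations"` attribute.
#' @export
hamming_distances <- function(m, normalize = FALSE) {
  validate_marker_matrix(m, allow_missing = FALSE)
  d <- as.matrix(dist(m$bands, method = "manhattan"))
  if (normalize) d <- d / ncol(m$bands)
  structure(d, class = c("hamming_dist", "matrix"),
            populations = setNames(as.character(m$pop), rownames(m$bands)),
            normalized = normalize)
}

#' Minimum spanning network
#'
#' Builds a minimum spanning tree by greedy (Kruskal) edge insertion with a
#' deterministic tie-break on label order, then retains ties: every non-tree
#' edge whose weight equals the maximum edge weight on the tree path between
#' its endpoints (the path bottleneck) is added back, which turns tied
#' alternative connections into cycles — the usual population-genetics network
#' convention.
#'
#' @param d a `hamming_dist` or symmetric distance matrix with labels.
#' @return an `msn` list: `nodes` (data frame id, population), `edges`
#'   (data frame from, to, weight, in_tree), `is_spanning`.
#' @export
minimum_spanning_network <- function(d) {
  dm <- as.matrix(unclass(d))
  n <- nrow(dm)
  if (n < 2L) stop("need >= 2 nodes")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- sprintf("n%d", seq_len(n))
  eps <- 1e-9
  ii <- which(upper.tri(dm), arr.ind = TRUE)
  edges <- data.frame(i = ii[, 1], j = ii[, 2], w = dm[upper.tri(dm)])
  edges <- edges[order(edges$w, edges$i, edges$j), ]
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  in_tree <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges$i[e]); rb <- find(edges$j[e])
    if (ra != rb) { parent[ra] <- rb; in_tree[e] <- TRUE }
  }
  # path bottleneck between all node pairs on the tree, by DFS from each node
  adj <- vector("list", n)
  te <- edges[in_tree, ]
  for (e in seq_len(nrow(te))) {
    adj[[te$i[e]]] <- rbind(adj[[te$i[e]]], c(te$j[e], te$w[e]))
    adj[[te$j[e]]] <- rbind(adj[[te$j[e]]], c(te$i[e], te$w[e]))
  }
  bottleneck <- matrix(0, n, n)
  for (s in seq_len(n)) {
    seen <- logical(n); seen[s] <- TRUE
    stack <- list(c(s, 0))
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- cur[1]; bmax <- cur[2]
      nb <- adj[[v]]
      if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (!seen[u]) {
          seen[u] <- TRUE
          b2 <- max(bmax, nb[r, 2])
          bottleneck[s, u] <- b2
          stack[[length(stack) + 1]] <- c(u, b2)
        }
      }
    }
  }
  keep <- in_tree | (edges$w <= bottleneck[cbind(edges$i, edges$j)] + eps)
  pops <- attr(d, "populations")
  nodes <- data.frame(id = labs,
                      population = if (is.null(pops)) NA_character_ else unname(pops[labs]),
                      stringsAsFactors = FALSE)
  out_edges <- data.frame(from = labs[edges$i[keep]], to = labs[edges$j[keep]],
                          weight = edges$w[keep], in_tree = in_tree[keep],
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = out_edges, is_spanning = TRUE),
            class = "msn")
}

#' @export
print.msn <- function(x, ...) {
  cat(sprintf("minimum spanning network: %d nodes, %d edges (%d tree, %d tied)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$in_tree),
              sum(!x$edges$in_tree)))
  invisible(x)
}

#' Principal component analysis of band data
#'
#' Covariance-matrix PCA (column-centred, unscaled) of the 0/1 band matrix.
#' Component signs follow the convention that the largest-magnitude loading of
#' each component is positive, making the output deterministic.
#'
#' @param m a `marker_matrix`.
#' @return a `marker_pca` list: `scores`, `eigenvalues`, `pct_variance`,
#'   `loadings`, `populations`.
#' @export
marker_pca <- function(m) {
  validate_marker_matrix(m, allow_missing = FALSE)
  if (nrow(m$bands) < 2L) stop("need >= 2 individuals")
  pc <- prcomp(m$bands, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  pct <- if (tot > 0) 100 * ev / tot else rep(0, length(ev))
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  structure(list(scores = scores, eigenvalues = ev, pct_variance = pct,
                 loadings = loadings, center = pc$center,
                 populations = setNames(as.character(m$pop), rownames(m$bands))),
            class = "marker_pca")
}

#' @export
print.marker_pca <- function(x, ...) {
  k <- min(5, length(x$pct_variance))
  cat("PCA of band matrix; leading components (% variance): ",
      paste(sprintf("%.2f", x$pct_variance[1:k]), collapse = ", "), "\n")
  invisible(x)
}

bic_kmeans <- function(scores, k_max, seed = NULL, n_start = 25) {
  n <- nrow(scores)
  if (!is.null(seed)) set.seed(seed)
  wss_tot <- sum(scale(scores, scale = FALSE)^2)
  fits <- vector("list", k_max)
  bic <- numeric(k_max)
  for (k in seq_len(k_max)) {
    if (k == 1) {
      wss <- wss_tot
      fits[[k]] <- list(cluster = rep(1L, n))
    } else {
      km <- kmeans(scores, centers = k, nstart = n_start, iter.max = 200)
      wss <- km$tot.withinss
      fits[[k]] <- km
    }
    bic[k] <- n * log(wss / n) + k * log(n)
  }
  list(bic = bic, k = which.min(bic), fits = fits)
}

#' Discriminant analysis of principal components
#'
#' Reduces the band matrix by covariance PCA, finds groups by seeded k-means
#' over `k = 1..k_max` choosing k by BIC (`n log(WSS/n) + k log(n)`), then
#' fits a linear discriminant analysis of the retained principal components
#' against the groups. The k-means screen runs on all non-degenerate
#' components (group finding wants the full variance, as DAPC practice
#' recommends); the discriminant step uses `n_pcs` components — when not
#' given, the smallest number explaining >= 80% of the variance.
#'
#' @param m a `marker_matrix`.
#' @param k number of groups; inferred by k-means + BIC when `NULL`.
#' @param n_pcs number of principal components to retain.
#' @param k_max largest k screened (default `min(10, n - 1)`).
#' @param seed optional RNG seed for the k-means restarts.
#' @param n_start k-means restarts per k.
#' @return a `dapc_result` list: `k`, `bic_by_k`, `n_pcs`, `scores`
#'   (discriminant functions, `<= k - 1` columns), `assignments`,
#'   `pct_variance_retained`.
#' @export
dapc_markers <- function(m, k = NULL, n_pcs = NULL, k_max = NULL, seed = NULL,
                         n_start = 25) {
  validate_marker_matrix(m, allow_missing = FALSE)
  n <- nrow(m$bands)
  if (n < 2L) stop("need >= 2 individuals")
  if (!is.null(k) && k > n) stop("k cannot exceed the number of individuals")
  pca <- marker_pca(m)
  nz <- which(pca$eigenvalues > 1e-12)
  if (length(nz) == 0L) stop("constant band matrix: no variation to analyse")
  if (is.null(n_pcs)) {
    cum <- cumsum(pca$pct_variance)
    n_pcs <- which(cum >= 80)[1]
    if (is.na(n_pcs)) n_pcs <- length(nz)
  }
  n_pcs <- min(n_pcs, length(nz))
  scores <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  all_scores <- pca$scores[, nz, drop = FALSE]
  if (is.null(k_max)) k_max <- min(10L, n - 1L)
  bic_by_k <- NULL
  if (is.null(k)) {
    sel <- bic_kmeans(all_scores, k_max, seed = seed, n_start = n_start)
    k <- sel$k
    grp <- sel$fits[[k]]$cluster
    bic_by_k <- data.frame(k = seq_len(k_max), bic = sel$bic)
  } else if (k == 1) {
    grp <- rep(1L, n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    grp <- kmeans(all_scores, centers = k, nstart = n_start,
                  iter.max = 200)$cluster
  }
  ld_scores <- matrix(numeric(0), n, 0)
  if (k >= 2) {
    fit <- NULL
    np <- n_pcs
    repeat {
      fit <- tryCatch(
        MASS::lda(scores[, seq_len(np), drop = FALSE], grouping = factor(grp)),
        error = function(e) NULL)
      if (!is.null(fit) || np == 1L) break
      np <- max(1L, np %/% 2L)
    }
    if (is.null(fit)) stop("linear discriminant analysis failed")
    ld_scores <- stats::predict(fit, scores[, seq_len(np), drop = FALSE])$x
  }
  structure(list(k = k, bic_by_k = bic_by_k, n_pcs = n_pcs,
                 scores = ld_scores, assignments = setNames(grp, rownames(m$bands)),
                 pct_variance_retained = sum(pca$pct_variance[seq_len(n_pcs)])),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("DAPC: k = %d groups, %d PCs retained (%.1f%% variance), %d discriminant function(s)\n",
              x$k, x$n_pcs, x$pct_variance_retained, ncol(x$scores)))
  invisible(x)
}

#' Bayesian admixture clustering of binary band phenotypes
#'
#' A Gibbs sampler for a finite mixture with admixture: cluster-by-locus band
#' frequencies `theta_kl ~ Beta(1, 1)`, per-individual admixture proportions
#' `q_i ~ Dirichlet(1, ..., 1)`, per individual-and-locus allocations
#' `z_il ~ Categorical(q_i)` and `band_il ~ Bernoulli(theta[z_il, l])`.
#' Band phenotypes are modelled directly as Bernoulli draws — a deliberate
#' simplification of genotype-based admixture models for dominant data that
#' retains their cluster-recovery behaviour at a fraction of the cost.
#' `L(K)` is the posterior mean of the data log-likelihood over post-burn-in
#' sweeps; `Q` is the posterior mean admixture with label switching resolved
#' by greedy matching of `theta` to a reference sample.
#'
#' @param m a `marker_matrix`.
#' @param K number of clusters (1 <= K <= individuals).
#' @param n_burnin,n_sample burn-in and retained Gibbs sweeps.
#' @param seed optional RNG seed (R's RNG drives the sampler).
#' @return an `admixture_run` list: `K`, `loglik` (L(K)), `Q`
#'   (individuals x K, rows sum to 1), `theta` (posterior mean cluster band
#'   frequencies), `seed`.
#' @export
admixture_mcmc <- function(m, K, n_burnin = 2000, n_sample = 5000, seed = NULL) {
  validate_marker_matrix(m, allow_missing = FALSE)
  stopifnot(K >= 1, n_burnin >= 1, n_sample >= 1)
  if (K > nrow(m$bands)) stop("K cannot exceed the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  res <- admixture_gibbs_cpp(m$bands, as.integer(K), as.integer(n_burnin),
                             as.integer(n_sample))
  rownames(res$Q) <- rownames(m$bands)
  structure(list(K = as.integer(K), loglik = res$loglik, Q = res$Q,
                 theta = res$theta, seed = seed,
                 populations = setNames(as.character(m$pop), rownames(m$bands))),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat(sprintf("admixture run: K = %d, mean log-likelihood = %.2f\n",
              x$K, x$loglik))
  invisible(x)
}

#' Replicated admixture runs over a range of K
#'
#' Convenience driver producing the replicate runs that [evanno()] consumes.
#' Replicate seeds are derived from `seed` as `seed + 1000 K + rep`.
#'
#' @param m a `marker_matrix`.
#' @param k_range integer vector of K values (must be consecutive for the
#'   Evanno statistics).
#' @param n_reps replicate runs per K.
#' @param n_burnin,n_sample sweeps per run.
#' @param seed base seed.
#' @return list of `admixture_run` objects.
#' @export
admixture_scan <- function(m, k_range = 1:5, n_reps = 4, n_burnin = 2000,
                           n_sample = 5000, seed = 1L) {
  runs <- list()
  for (K in k_range) for (r in seq_len(n_reps)) {
    runs[[length(runs) + 1L]] <- admixture_mcmc(
      m, K, n_burnin = n_burnin, n_sample = n_sample,
      seed = as.integer(seed) + 1000L * K + r)
  }
  runs
}

#' Evanno delta-K table from replicated admixture runs
#'
#' Given replicate runs grouped by K, computes `L'(K) = mean L(K) - mean
#' L(K-1)`, `|L''(K)| = |L'(K+1) - L'(K)|` and `Delta K = |L''(K)| / sd(L(K))`,
#' and reports the interior K with maximal Delta K as `best_k`. A zero
#' standard deviation yields an infinite Delta K with a warning.
#'
#' @param runs list of `admixture_run` objects covering >= 3 consecutive K
#'   values with >= 2 replicates each.
#' @return data frame (class `evanno_table`) with columns `k`, `n_reps`,
#'   `mean_l`, `sd_l`, `l_prime`, `l_doubleprime_abs`, `delta_k`; the chosen
#'   K is the `"best_k"` attribute.
#' @export
evanno <- function(runs) {
  ks <- vapply(runs, function(r) r$K, 0L)
  ls <- vapply(runs, function(r) r$loglik, 0)
  kk <- sort(unique(ks))
  if (length(kk) < 3L || !all(diff(kk) == 1L))
    stop("need >= 3 consecutive K values")
  reps <- table(factor(ks, levels = kk))
  if (any(reps < 2L)) stop("need >= 2 replicate runs per K")
  mu <- vapply(kk, function(k) mean(ls[ks == k]), 0)
  sdl <- vapply(kk, function(k) sd(ls[ks == k]), 0)
  nk <- length(kk)
  lp <- c(NA, diff(mu))                       # L'(K), defined from the 2nd K
  lpp <- c(NA, abs(diff(lp[-1])), NA)         # |L''(K)| for interior K
  dk <- lpp / sdl
  if (any(sdl[!is.na(lpp)] == 0)) {
    warning("sd(L(K)) = 0 for some K; Delta K reported as Inf")
    dk[!is.na(lpp) & sdl == 0] <- Inf
  }
  interior <- which(!is.na(dk))
  best <- kk[interior[which.max(dk[interior])]]
  out <- data.frame(k = kk, n_reps = as.integer(reps), mean_l = mu, sd_l = sdl,
                    l_prime = lp, l_doubleprime_abs = lpp, delta_k = dk)
  attr(out, "best_k") <- best
  class(out) <- c("evanno_table", "data.frame")
  out
}

#' @export
print.evanno_table <- function(x, ...) {
  print.data.frame(x, digits = 4, ...)
  cat(sprintf("best-supported K (max Delta K): %d\n", attr(x, "best_k")))
  invisible(x)
}
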