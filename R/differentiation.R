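#' Nei's Gst for dominant marker data
#'
#' Partitions gene diversity into within- and among-population components on
#' Lynch-Milligan allele frequencies: per locus `Hs = mean_j 2 p_j q_j` and
#' `Ht = 2 p_bar q_bar` with `p_bar` the unweighted across-population mean of
#' `p`. The multi-locus coefficient sums components across loci,
#' `Gst = (sum Ht - sum Hs) / sum Ht`, excluding loci with `Ht = 0`.
#'
#' @param x a `marker_matrix` or a `locus_freqs` from
#'   [estimate_frequencies()].
#' @param use_band_freqs compute on raw band-presence frequencies instead of
#'   estimated allele frequencies (the dominant-data convention is ambiguous
#'   across programs; the default keeps Gst consistent with He).
#' @return list with `gst`, `ht`, `hs` (multi-locus means over included
#'   loci) and `n_loci_used`.
#' @export
nei_gst <- function(x, use_band_freqs = FALSE) {
  f <- if (inherits(x, "locus_freqs")) x else estimate_frequencies(x)
  if (length(f$populations) < 2L) stop("need >= 2 populations")
  p <- if (use_band_freqs) 1 - f$x else f$p
  hs_l <- colMeans(2 * p * (1 - p))
  pbar <- colMeans(p)
  ht_l <- 2 * pbar * (1 - pbar)
  keep <- ht_l > 0
  if (!any(keep)) stop("Gst undefined: every locus monomorphic in all populations")
  gst <- (sum(ht_l[keep]) - sum(hs_l[keep])) / sum(ht_l[keep])
  list(gst = gst, ht = mean(ht_l[keep]), hs = mean(hs_l[keep]),
       n_loci_used = sum(keep))
}

#' Crow-Aoki gene flow from Gst
#'
#' Effective number of migrants per generation under the n-island correction
#' `alpha = (n/(n-1))^2`: `Nm = ((1/Gst) - 1) / (4 alpha)`.
#'
#' @param gst differentiation coefficient in (0, 1].
#' @param n_pops number of populations (>= 2).
#' @return list with `nm` and `alpha`.
#' @export
gene_flow_crow_aoki <- function(gst, n_pops) {
  stopifnot(n_pops >= 2)
  if (!is.finite(gst) || gst <= 0 || gst > 1)
    stop("gst must lie in (0, 1]; gst = 0 implies infinite gene flow")
  alpha <- (n_pops / (n_pops - 1))^2
  list(nm = ((1 / gst) - 1) / (4 * alpha), alpha = alpha)
}

amova_ss <- function(d2, idx_by_group, n) {
  sstot <- sum(d2[lower.tri(d2)]) / n
  ssw <- 0
  for (idx in idx_by_group) {
    block <- d2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(block[lower.tri(block)]) / length(idx)
  }
  c(total = sstot, within = ssw, among = sstot - ssw)
}

#' Analysis of molecular variance for binary band data
#'
#' One-level AMOVA on pairwise squared Euclidean distances between band
#' vectors (for 0/1 data these equal Hamming counts). Sums of squares are
#' partitioned among and within populations from the distance matrix; variance
#' components use the standard estimator with coefficient
#' `n0 = (N - sum(n_g^2)/N) / (G - 1)`; `Phi_st = sigma2_a / (sigma2_a +
#' sigma2_w)`. Significance is assessed by permuting individuals among
#' populations with fixed sizes; the p-value uses the add-one convention
#' `(1 + #{Phi_perm >= Phi_obs}) / (1 + n_perm)` so it is never exactly zero.
#'
#' @param m a `marker_matrix` with >= 2 populations of >= 2 individuals each.
#' @param n_perm number of label permutations (0 skips the test).
#' @param seed optional RNG seed for the permutations.
#' @return an `amova_result` list: `df`, `ss`, `ms`, `sigma2`, `pct`,
#'   `phi_st`, `p_value`, `n_perm`.
#' @examples
#' sim <- simulate_markers(study_preset())
#' amova_binary(sim$matrix, n_perm = 99, seed = 1)
#' @export
amova_binary <- function(m, n_perm = 10000, seed = NULL) {
  validate_marker_matrix(m, allow_missing = FALSE)
  if (nlevels(m$pop) < 2L) stop("need >= 2 populations")
  sizes <- table(m$pop)
  if (any(sizes < 2L))
    stop("populations with a single individual collapse the within-group df: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  d2 <- as.matrix(dist(m$bands, method = "manhattan"))  # = Hamming = squared Euclidean
  n <- nrow(d2)
  g <- nlevels(m$pop)
  idx <- split(seq_len(n), m$pop)
  ss <- amova_ss(d2, idx, n)
  df_a <- g - 1L
  df_w <- n - g
  ms_a <- ss[["among"]] / df_a
  ms_w <- ss[["within"]] / df_w
  n0 <- (n - sum(sizes^2) / n) / df_a
  s2_a <- (ms_a - ms_w) / n0
  s2_w <- ms_w
  phi <- s2_a / (s2_a + s2_w)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    phi_perm <- amova_perm_cpp(d2, as.integer(sizes), as.integer(n_perm), n0)
    p <- (1 + sum(phi_perm >= phi)) / (1 + n_perm)
  }
  structure(list(
    df = c(among = df_a, within = df_w),
    ss = c(among = ss[["among"]], within = ss[["within"]], total = ss[["total"]]),
    ms = c(among = ms_a, within = ms_w),
    sigma2 = c(among = s2_a, within = s2_w),
    pct = c(among = 100 * s2_a / (s2_a + s2_w),
            within = 100 * s2_w / (s2_a + s2_w)),
    phi_st = phi, p_value = p, n_perm = n_perm, n0 = n0),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (binary band data)\n")
  tab <- data.frame(df = x$df, SS = x$ss[1:2], MS = x$ms,
                    sigma2 = x$sigma2, pct = x$pct)
  print(round(tab, 4))
  cat(sprintf("Phi_st = %.4f", x$phi_st))
  if (!is.na(x$p_value))
    cat(sprintf("   p = %.5g (%d permutations)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Pairwise Phi_st between populations
#'
#' Runs a two-population AMOVA for every population pair and reports the
#' Phi-statistics together with the Slatkin linearization `Fst / (1 - Fst)`.
#' A pair with `Phi_st = 1` gets a `+Inf` linearized value with a warning.
#'
#' @param m a `marker_matrix` with >= 2 populations.
#' @return list of two symmetric matrices with zero diagonals: `phi_st` and
#'   `linearized`.
#' @export
pairwise_fst <- function(m) {
  validate_marker_matrix(m, allow_missing = FALSE)
  pops <- levels(m$pop)
  k <- length(pops)
  if (k < 2L) stop("need >= 2 populations")
  phi <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sub <- subset_markers(m, keep_populations = c(pops[i], pops[j]))
    phi[i, j] <- phi[j, i] <- amova_binary(sub, n_perm = 0)$phi_st
  }
  if (any(phi == 1))
    warning("Phi_st = 1 for some pair; linearized value is +Inf")
  lin <- phi / (1 - phi)
  diag(lin) <- 0
  list(phi_st = phi, linearized = lin)
}

#' Mantel test for isolation by distance
#'
#' Correlates linearized genetic differentiation with log10 geographic
#' distance over the off-diagonal pairs. The permutation null shuffles
#' population labels of one matrix (rows and columns jointly) and the test is
#' one-sided against positive association (`r_perm >= r_obs`), with the
#' add-one p-value convention. A Spearman rank coefficient and a bootstrap
#' (over pairs) 95% CI for r are reported alongside.
#'
#' @param gen symmetric genetic distance matrix (e.g. `linearized` from
#'   [pairwise_fst()]), labelled by population.
#' @param geo a [population_geo()] or a symmetric matrix of geographic
#'   distances in km.
#' @param n_perm number of label permutations.
#' @param seed optional RNG seed.
#' @param n_boot bootstrap replicates for the CI (0 skips it).
#' @return a `mantel_result` list: `r`, `p`, `spearman_rho`, `ci95`,
#'   `n_perm`.
#' @export
mantel_ibd <- function(gen, geo, n_perm = 10000, seed = NULL, n_boot = 1000) {
  dgeo <- if (inherits(geo, "population_geo")) geo_distances(geo) else as.matrix(geo)
  gen <- as.matrix(gen)
  if (!is.null(rownames(gen)) && !is.null(rownames(dgeo)))
    dgeo <- dgeo[rownames(gen), rownames(gen)]
  k <- nrow(gen)
  if (k < 4L) stop("need >= 4 populations for a meaningful permutation null")
  if (any(dgeo[upper.tri(dgeo)] <= 0))
    stop("zero geographic distance between distinct populations: log undefined")
  lgeo <- log10(dgeo)
  ut <- upper.tri(gen)
  gv <- gen[ut]
  xv <- lgeo[ut]
  r_obs <- cor(xv, gv)
  rho <- cor(xv, gv, method = "spearman")
  if (!is.null(seed)) set.seed(seed)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    o <- sample.int(k)
    cor(xv, gen[o, o][ut])
  }, 0)
  p <- (1 + sum(perm_r >= r_obs)) / (1 + n_perm)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    npairs <- length(gv)
    br <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(npairs, replace = TRUE)
      if (sd(xv[idx]) == 0 || sd(gv[idx]) == 0) return(NA_real_)
      cor(xv[idx], gv[idx])
    }, 0)
    ci <- unname(quantile(br, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(r = r_obs, p = p, spearman_rho = rho, ci95 = ci,
                 n_perm = n_perm), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.3g (%d permutations), Spearman rho = %.3f\n",
              x$r, x$p, x$n_perm, x$spearman_rho))
  if (!anyNA(x$ci95))
    cat(sprintf("  bootstrap 95%% CI for r: [%.3f, %.3f]\n", x$ci95[1], x$ci95[2]))
  invisible(x)
}
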