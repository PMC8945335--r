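#' Lynch-Milligan allele frequency estimation
#'
#' For a dominant biallelic locus under Hardy-Weinberg the band-absent
#' phenotype is the recessive homozygote, so the naive estimate of the null
#' (recessive) allele frequency is `sqrt(x)` with `x` the band-absence
#' fraction. The Taylor-expansion bias correction of Lynch & Milligan is
#' applied: `q = sqrt(x) / (1 - Var(x)/(8 x^2))` with `Var(x) = x(1-x)/n`,
#' clamped to [0, 1]; `x = 0` short-circuits to `q = 0` (the bias term would
#' divide by zero). The dominant allele frequency is `p = 1 - q`.
#'
#' @param m a complete (no missing cells) `marker_matrix` with >= 2
#'   individuals in every population.
#' @return a `locus_freqs` object: matrices `x` (band-absence fraction), `q`,
#'   `p` (populations x loci) and the per-population sample sizes `n`.
#' @export
estimate_frequencies <- function(m) {
  validate_marker_matrix(m, allow_missing = FALSE)
  pops <- levels(m$pop)
  ns <- table(m$pop)[pops]
  if (any(ns < 2L))
    stop("Lynch-Milligan bias term needs >= 2 individuals per population")
  x <- do.call(rbind, lapply(pops, function(g)
    colMeans(m$bands[m$pop == g, , drop = FALSE] == 0L)))
  dimnames(x) <- list(pops, colnames(m$bands))
  n <- as.numeric(ns)
  v <- x * (1 - x) / n          # recycled per row (population)
  q <- sqrt(x) / (1 - v / (8 * x^2))
  q[x == 0] <- 0
  q <- pmin(pmax(q, 0), 1)
  structure(list(x = x, q = q, p = 1 - q, n = setNames(n, pops),
                 populations = pops, loci = colnames(m$bands)),
            class = "locus_freqs")
}

#' @export
print.locus_freqs <- function(x, ...) {
  cat(sprintf("locus_freqs: %d populations x %d loci (Lynch-Milligan)\n",
              length(x$populations), length(x$loci)))
  invisible(x)
}

#' Band-based allele counts per population
#'
#' For dominant data, allele counts follow the band-state census convention:
#' each locus contributes the number of distinct states observed in the
#' population (2 if both band-present and band-absent individuals occur, 1 if
#' monomorphic), summed over loci (`na`). A private allele is a locus whose
#' band occurs in this population and in no other (`private`). The effective
#' number of alleles is the mean over loci of `1 / (p^2 + q^2)` on the
#' Lynch-Milligan frequencies (`ne`).
#'
#' @param m a `marker_matrix`.
#' @return data frame with one row per population: `population`, `na`, `ne`,
#'   `private`.
#' @export
allele_counts <- function(m) {
  f <- estimate_frequencies(m)
  pops <- f$populations
  present <- do.call(rbind, lapply(pops, function(g)
    colSums(m$bands[m$pop == g, , drop = FALSE]) > 0L))
  absent <- do.call(rbind, lapply(pops, function(g)
    colSums(m$bands[m$pop == g, , drop = FALSE] == 0L) > 0L))
  rownames(present) <- rownames(absent) <- pops
  na <- rowSums(present) + rowSums(absent)
  priv <- vapply(seq_along(pops), function(i)
    sum(present[i, ] & colSums(present[-i, , drop = FALSE]) == 0L), 0)
  ne <- rowMeans(1 / (f$p^2 + f$q^2))
  data.frame(population = pops, na = as.numeric(na), ne = ne,
             private = priv, row.names = NULL, stringsAsFactors = FALSE)
}

#' Genetic diversity from estimated allele frequencies
#'
#' Per-population expected heterozygosity `He` (mean over loci of `2pq`),
#' Shannon diversity `I` (mean over loci of `-(p ln p + q ln q)`, with
#' `0 ln 0 = 0`), both on Lynch-Milligan allele frequencies, and the
#' percentage of polymorphic loci under the 95% criterion (`pct_p`): a locus
#' counts as polymorphic when its most common *band state* has frequency
#' at most 0.95.
#'
#' @param f a `locus_freqs` from [estimate_frequencies()].
#' @return data frame with one row per population: `population`, `he`, `i`,
#'   `pct_p`.
#' @export
heterozygosity <- function(f) {
  stopifnot(inherits(f, "locus_freqs"))
  he <- rowMeans(2 * f$p * f$q)
  plogp <- function(z) ifelse(z > 0, z * log(z), 0)
  shannon <- rowMeans(-(plogp(f$p) + plogp(f$q)))
  band <- 1 - f$x
  poly <- pmax(band, 1 - band) <= 0.95
  data.frame(population = f$populations, he = he, i = shannon,
             pct_p = 100 * rowMeans(poly), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-population diversity summary
#'
#' Combines [allele_counts()] and [heterozygosity()] into one table and
#' attaches across-population means and standard errors
#' (`se = sd / sqrt(n_pops)`) as the `"means"` attribute.
#'
#' @param m a `marker_matrix`.
#' @return data frame (class `diversity_summary`) with columns `population`,
#'   `n`, `na`, `ne`, `private`, `he`, `i`, `pct_p`.
#' @examples
#' sim <- simulate_markers(study_preset())
#' diversity_summary(sim$matrix)
#' @export
diversity_summary <- function(m) {
  f <- estimate_frequencies(m)
  ac <- allele_counts(m)
  ht <- heterozygosity(f)
  out <- cbind(ac[, "population", drop = FALSE],
               n = as.numeric(f$n[ac$population]),
               ac[, c("na", "ne", "private")],
               ht[, c("he", "i", "pct_p")])
  num <- out[, c("na", "ne", "private", "he", "i", "pct_p")]
  k <- nrow(out)
  attr(out, "means") <- data.frame(
    statistic = names(num),
    mean = vapply(num, mean, 0),
    se = vapply(num, sd, 0) / sqrt(k),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

#' @export
print.diversity_summary <- function(x, digits = 3, ...) {
  print.data.frame(x, digits = digits, ...)
  cat("\nAcross-population mean +/- SE:\n")
  mm <- attr(x, "means")
  cat(paste(sprintf("  %s = %.3f +/- %.3f", mm$statistic, mm$mean, mm$se),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Exact test of allele-frequency differentiation
#'
#' Per locus, Fisher's exact test on the populations x {band, no band}
#' contingency table: full hypergeometric enumeration for two populations, a
#' Monte-Carlo exact test (default 10,000 sampled tables) for more. Loci that
#' are monomorphic across the pooled sample have p = 1 by construction.
#' Per-locus p-values are combined across loci with Fisher's method
#' (`-2 sum log p ~ chi-squared with 2L df`).
#'
#' @param m a `marker_matrix` with >= 2 populations.
#' @param b number of Monte-Carlo tables for > 2 populations.
#' @param seed optional RNG seed for the Monte-Carlo sampler.
#' @return list with `p_locus` (named vector), `p_combined`, `statistic` and
#'   `df` of the combined test.
#' @export
exact_differentiation_test <- function(m, b = 10000, seed = NULL) {
  validate_marker_matrix(m, allow_missing = FALSE)
  if (nlevels(m$pop) < 2L) stop("need >= 2 populations")
  if (!is.null(seed)) set.seed(seed)
  two_pops <- nlevels(m$pop) == 2L
  p_locus <- vapply(seq_len(ncol(m$bands)), function(l) {
    tab <- table(m$pop, factor(m$bands[, l], levels = c(0L, 1L)))
    if (any(colSums(tab) == 0L)) return(1)  # monomorphic overall
    if (two_pops) fisher.test(tab)$p.value
    else fisher.test(tab, simulate.p.value = TRUE, B = b)$p.value
  }, 0)
  names(p_locus) <- colnames(m$bands)
  stat <- -2 * sum(log(p_locus))
  df <- 2L * length(p_locus)
  list(p_locus = p_locus, p_combined = pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df)
}
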