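#' Decline / local-extinction scenario specification
#'
#' Describes a perturbation of a marker matrix: `"decline"` removes
#' `floor(fraction * n)` individuals from each population, chosen uniformly
#' without replacement (odd-sized populations keep the extra individual);
#' `"extinction"` drops the named populations entirely; `"none"` is the
#' identity.
#'
#' @param kind one of `"none"`, `"decline"`, `"extinction"`.
#' @param fraction per-population proportion removed (decline), in (0, 1).
#' @param populations populations to remove (extinction).
#' @param seed RNG seed for the random removals.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(kind = c("none", "decline", "extinction"),
                          fraction = 0.5, populations = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "decline" && (fraction <= 0 || fraction >= 1))
    stop("fraction must lie in (0, 1)")
  if (kind == "extinction" && length(populations) == 0L)
    stop("extinction scenario needs population labels")
  structure(list(kind = kind, fraction = fraction, populations = populations,
                 seed = as.integer(seed)), class = "scenario_spec")
}

#' Apply a scenario to a marker matrix
#'
#' @param m a `marker_matrix`.
#' @param spec a [scenario_spec()].
#' @return the perturbed `marker_matrix`. Same spec and seed give the same
#'   retained individuals.
#' @export
apply_scenario <- function(m, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  validate_marker_matrix(m)
  switch(spec$kind,
    none = m,
    decline = {
      set.seed(spec$seed)
      drop <- character(0)
      for (g in levels(m$pop)) {
        ids <- names(m$pop)[m$pop == g]
        k <- floor(spec$fraction * length(ids))
        if (k >= length(ids))
          stop("removal would empty population ", g)
        if (k > 0) drop <- c(drop, sample(ids, k))
      }
      subset_markers(m, individuals = setdiff(rownames(m$bands), drop))
    },
    extinction = {
      unknown <- setdiff(spec$populations, levels(m$pop))
      if (length(unknown) > 0L)
        stop("unknown population(s): ", paste(unknown, collapse = ", "))
      left <- setdiff(levels(m$pop), spec$populations)
      if (length(left) < 2L)
        stop("extinction must leave >= 2 populations")
      subset_markers(m, keep_populations = left)
    })
}

private_counts <- function(m) {
  ac <- allele_counts(m)
  setNames(ac$private, ac$population)
}

# Goodness-of-fit chi-squared of post-perturbation private-allele counts
# against the baseline counts, over populations present in both matrices.
# Populations with baseline count 0 are pooled into one cell which cannot
# enter the statistic (zero expectation); its post-perturbation gain is
# reported separately as `new_private`.
private_allele_chi2 <- function(before, after) {
  shared <- intersect(names(before), names(after))
  b <- before[shared]; a <- after[shared]
  pos <- b > 0
  new_private <- sum(a[!pos])
  cells_b <- as.numeric(b[pos]); cells_a <- as.numeric(a[pos])
  if (length(cells_b) == 0L)
    return(list(chi2 = 0, df = 1L, p = 1, new_private = new_private))
  chi2 <- sum((cells_a - cells_b)^2 / cells_b)
  df <- max(1L, length(cells_b) - 1L)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       new_private = new_private)
}

#' Compare genetic metrics before and after a scenario
#'
#' Runs the diversity and differentiation suite (diversity summary, Nei's
#' Gst, AMOVA, Crow-Aoki gene flow) on the original and on the perturbed
#' matrix with identical settings, and tests the change in per-population
#' private-allele counts with a goodness-of-fit chi-squared (post counts
#' against baseline counts over populations with a positive baseline;
#' populations with baseline 0 cannot enter a goodness-of-fit statistic and
#' their post-perturbation gains are reported as `new_private`). The
#' comparison tolerates counts moving in either direction — under extinction
#' a band shared only with a removed population becomes private. Admixture
#' re-clustering is optional (off by default: it dominates the runtime).
#'
#' @param m a `marker_matrix`.
#' @param spec a [scenario_spec()].
#' @param n_perm AMOVA permutations per matrix.
#' @param run_structure also rerun the admixture scan + Evanno on both
#'   matrices.
#' @param k_range,n_reps,n_burnin,n_sample admixture settings when
#'   `run_structure = TRUE`.
#' @param seed seed for the AMOVA permutation tests (and the admixture scan).
#' @return a `scenario_comparison` list with `baseline` and `perturbed`
#'   result bundles, the private-allele counts and the chi-squared test.
#' @export
compare_scenarios <- function(m, spec, n_perm = 999, run_structure = FALSE,
                              k_range = 1:4, n_reps = 2, n_burnin = 500,
                              n_sample = 1000, seed = 1L) {
  validate_marker_matrix(m, allow_missing = FALSE)
  m2 <- apply_scenario(m, spec)
  run_suite <- function(mm) {
    gst <- nei_gst(mm)
    nm <- tryCatch(gene_flow_crow_aoki(gst$gst, nlevels(mm$pop))$nm,
                   error = function(e) NA_real_)
    out <- list(diversity = diversity_summary(mm), gst = gst, nm = nm,
                amova = amova_binary(mm, n_perm = n_perm, seed = seed),
                total_bands = total_bands(mm))
    if (run_structure) {
      runs <- admixture_scan(mm, k_range = k_range, n_reps = n_reps,
                             n_burnin = n_burnin, n_sample = n_sample,
                             seed = seed)
      out$evanno <- evanno(runs)
    }
    out
  }
  base <- run_suite(m)
  pert <- run_suite(m2)
  pb <- private_counts(m)
  pa <- private_counts(m2)
  chi <- private_allele_chi2(pb, pa)
  structure(list(spec = spec, baseline = base, perturbed = pert,
                 private_before = pb, private_after = pa,
                 chi2 = chi$chi2, chi2_df = chi$df, chi2_p = chi$p,
                 new_private = chi$new_private),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("scenario '%s': %d -> %d individuals, %d -> %d bands\n",
              x$spec$kind,
              sum(x$baseline$diversity$n), sum(x$perturbed$diversity$n),
              x$baseline$total_bands, x$perturbed$total_bands))
  cat(sprintf("  Phi_st %.3f -> %.3f | Gst %.3f -> %.3f | Nm %.3f -> %.3f\n",
              x$baseline$amova$phi_st, x$perturbed$amova$phi_st,
              x$baseline$gst$gst, x$perturbed$gst$gst,
              x$baseline$nm, x$perturbed$nm))
  cat(sprintf("  private alleles: %d -> %d (chi2 = %.2f, df = %d, p = %.3g)\n",
              sum(x$private_before), sum(x$private_after),
              x$chi2, x$chi2_df, x$chi2_p))
  invisible(x)
}
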