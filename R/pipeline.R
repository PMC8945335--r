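#' Derive a stage-specific seed from the global seed
#'
#' Stages draw their randomness from seeds derived deterministically from the
#' single global seed and the stage name, so any stage can be rerun in
#' isolation and reproduce the pipeline's output.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483646) + 1L
}

#' Pipeline configuration
#'
#' @param design a [sim_design()] to simulate from, or `NULL` when `input`
#'   is given.
#' @param input path to an existing matrix file (csv dialect) instead of
#'   simulating.
#' @param n_perm permutations for AMOVA and the Mantel test.
#' @param run_structure run the admixture scan + Evanno stage.
#' @param k_range,n_reps,n_burnin,n_sample admixture scan settings.
#' @param scenarios named list of [scenario_spec()]s to compare.
#' @param risk_presets MER/IUCN preset names to assess.
#' @param seed global seed.
#' @param out_dir output directory (`NULL` for no files).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(design = study_preset(), input = NULL,
                            n_perm = 999, run_structure = TRUE,
                            k_range = 1:5, n_reps = 2, n_burnin = 500,
                            n_sample = 1000,
                            scenarios = list(
                              decline = scenario_spec("decline", fraction = 0.5),
                              extinction = scenario_spec(
                                "extinction",
                                populations = c("Presa Cebolletas", "Mesa Montoro"))),
                            risk_presets = c("2020e", "2020e+g"),
                            seed = 1L, out_dir = NULL) {
  stopifnot(n_perm >= 0, n_reps >= 1)
  structure(list(design = design, input = input, n_perm = n_perm,
                 run_structure = run_structure, k_range = k_range,
                 n_reps = n_reps, n_burnin = n_burnin, n_sample = n_sample,
                 scenarios = scenarios, risk_presets = risk_presets,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, diversity, differentiation (Gst, AMOVA, gene
#' flow, pairwise Fst, Mantel), optional structure inference (PCA, MSN,
#' admixture scan + Evanno), scenario comparisons and risk assessments, with
#' per-stage seeds derived from the global seed. When `config$out_dir` is
#' set, every stage writes a TSV/JSON artifact and a manifest listing all
#' files, seeds and settings; reruns with the same config and seed are
#' byte-identical except for the manifest timestamp.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list with all stage results (invisibly when
#'   writing files).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(config = config)
  files <- character(0)
  dir_out <- config$out_dir
  if (!is.null(dir_out) && !dir.exists(dir_out))
    dir.create(dir_out, recursive = TRUE)
  emit <- function(name, writer) {
    if (is.null(dir_out)) return(invisible(NULL))
    path <- file.path(dir_out, name)
    writer(path)
    files <<- c(files, name)
  }
  json <- function(x, path) jsonlite::write_json(
    x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE,
    na = "null")

  # --- ingest / simulate ----------------------------------------------------
  if (!is.null(config$input)) {
    m <- read_marker_matrix(config$input, dialect = "csv")
    geo <- if (!is.null(config$design)) config$design$geo else NULL
  } else {
    sim <- simulate_markers(config$design,
                            seed = stage_seed(config$seed, "simulate"))
    m <- sim$matrix
    geo <- config$design$geo
    out$truth <- sim$truth
    emit("matrix.csv", function(p) write_marker_matrix(m, p, "csv"))
  }
  out$matrix <- m

  # --- diversity ------------------------------------------------------------
  div <- diversity_summary(m)
  ex <- exact_differentiation_test(m, seed = stage_seed(config$seed, "exact"))
  out$diversity <- div
  out$exact_test <- ex
  emit("diversity.tsv", function(p) write_tsv(as.data.frame(div), p))

  # --- differentiation ------------------------------------------------------
  gst <- nei_gst(m)
  am <- amova_binary(m, n_perm = config$n_perm,
                     seed = stage_seed(config$seed, "amova"))
  nm <- tryCatch(gene_flow_crow_aoki(gst$gst, nlevels(m$pop))$nm,
                 error = function(e) NA_real_)
  pw <- pairwise_fst(m)
  out$gst <- gst; out$amova <- am; out$nm <- nm; out$pairwise <- pw
  if (!is.null(geo)) {
    out$mantel <- mantel_ibd(pw$linearized, geo, n_perm = config$n_perm,
                             seed = stage_seed(config$seed, "mantel"))
  }
  emit("differentiation.json", function(p) json(list(
    gst = gst, nm = nm,
    amova = list(df = as.list(am$df), ss = as.list(am$ss),
                 sigma2 = as.list(am$sigma2), pct = as.list(am$pct),
                 phi_st = am$phi_st, p_value = am$p_value,
                 n_perm = am$n_perm),
    mantel = if (!is.null(out$mantel)) unclass(out$mantel)), p))
  emit("pairwise_fst.tsv", function(p)
    write_tsv(data.frame(population = rownames(pw$phi_st), pw$phi_st,
                         check.names = FALSE), p))

  # --- structure inference --------------------------------------------------
  pca <- marker_pca(m)
  msn <- minimum_spanning_network(hamming_distances(m))
  out$pca <- pca; out$msn <- msn
  emit("pca_scores.tsv", function(p)
    write_tsv(data.frame(individual = rownames(pca$scores),
                         population = unname(pca$populations),
                         round(pca$scores[, 1:min(5, ncol(pca$scores))], 6)), p))
  emit("msn_edges.tsv", function(p) write_tsv(msn$edges, p))
  if (config$run_structure) {
    runs <- admixture_scan(m, k_range = config$k_range, n_reps = config$n_reps,
                           n_burnin = config$n_burnin,
                           n_sample = config$n_sample,
                           seed = stage_seed(config$seed, "admixture"))
    ev <- evanno(runs)
    out$admixture_runs <- runs
    out$evanno <- ev
    bestk <- attr(ev, "best_k")
    qbest <- runs[[which(vapply(runs, function(r) r$K, 0L) == bestk)[1]]]$Q
    emit("evanno.tsv", function(p) write_tsv(as.data.frame(ev), p))
    emit(sprintf("q_matrix_K%d.tsv", bestk), function(p)
      write_tsv(data.frame(individual = rownames(qbest),
                           population = as.character(m$pop),
                           round(qbest, 5)), p))
  }

  # --- scenarios ------------------------------------------------------------
  out$scenarios <- list()
  for (nm_s in names(config$scenarios)) {
    cmp <- compare_scenarios(m, config$scenarios[[nm_s]],
                             n_perm = config$n_perm,
                             seed = stage_seed(config$seed,
                                               paste0("scenario_", nm_s)))
    out$scenarios[[nm_s]] <- cmp
    emit(sprintf("scenario_%s.json", nm_s), function(p) json(list(
      kind = cmp$spec$kind,
      baseline = list(phi_st = cmp$baseline$amova$phi_st,
                      gst = cmp$baseline$gst$gst, nm = cmp$baseline$nm,
                      total_bands = cmp$baseline$total_bands,
                      private = as.list(cmp$private_before)),
      perturbed = list(phi_st = cmp$perturbed$amova$phi_st,
                       gst = cmp$perturbed$gst$gst, nm = cmp$perturbed$nm,
                       total_bands = cmp$perturbed$total_bands,
                       private = as.list(cmp$private_after)),
      chi2 = cmp$chi2, chi2_df = cmp$chi2_df, chi2_p = cmp$chi2_p), p))
  }

  # --- risk -----------------------------------------------------------------
  out$risk <- list()
  for (pr in config$risk_presets) {
    mer <- score_mer(mer_preset(pr))
    iucn <- iucn_preset(pr)
    out$risk[[pr]] <- list(mer = mer, iucn = iucn)
  }
  if (length(config$risk_presets) > 0)
    emit("risk.json", function(p) json(
      lapply(out$risk, function(r) list(
        mer_total = r$mer$total, mer_category = r$mer$category,
        iucn_category = r$iucn$category,
        iucn_triggered = as.list(r$iucn$triggered))), p))

  # --- manifest -------------------------------------------------------------
  if (!is.null(dir_out)) {
    manifest <- list(
      package = "issrpop",
      version = as.character(utils::packageVersion("issrpop")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = config$seed,
      stage_seeds = sapply(c("simulate", "exact", "amova", "mantel",
                             "admixture"),
                           function(s) stage_seed(config$seed, s)),
      settings = list(n_perm = config$n_perm,
                      run_structure = config$run_structure,
                      k_range = config$k_range, n_reps = config$n_reps,
                      n_burnin = config$n_burnin, n_sample = config$n_sample,
                      risk_presets = config$risk_presets),
      files = files)
    json(manifest, file.path(dir_out, "manifest.json"))
  }
  class(out) <- "pipeline_result"
  if (is.null(dir_out)) out else invisible(out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("issrpop pipeline result\n")
  cat(sprintf("  %d individuals, %d loci, %d populations\n",
              n_individuals(x$matrix), n_loci(x$matrix),
              nlevels(x$matrix$pop)))
  cat(sprintf("  Phi_st = %.3f (p = %.3g), Gst = %.3f, Nm = %.3f\n",
              x$amova$phi_st, x$amova$p_value, x$gst$gst, x$nm))
  if (!is.null(x$evanno))
    cat(sprintf("  Evanno best K = %d\n", attr(x$evanno, "best_k")))
  invisible(x)
}
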