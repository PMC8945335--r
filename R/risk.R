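#' Default MER criteria configuration
#'
#' The Mexican extinction-risk evaluation method (MER, Appendix II of
#' NOM-059-SEMARNAT-2010) scores four criteria in ascending order of risk —
#' (A) breadth of distribution, (B) habitat status, (C) intrinsic biological
#' vulnerability (ecological and genetic), (D) human impact — normalizes each
#' to [0, 1] by its maximum attainable points, and sums them. The per-level
#' point tables below are an editable interpretation (the qualitative
#' level-to-points mapping is configurable by design); the category
#' thresholds on the total are fixed by the standard.
#'
#' The `genetic` block parameterizes how genetic evidence maps to a
#' vulnerability sub-score for criterion C: low heterozygosity
#' (`he < he_low`), restricted gene flow (`nm < nm_low`) and strong
#' differentiation (`gst > gst_high`) are warning flags; two or more flags
#' give a medium genetic sub-score, and an additionally observed significant
#' decline of private alleles under decline/extinction scenarios gives the
#' highest sub-score.
#'
#' @return a nested configuration list.
#' @export
mer_criteria_config <- function() {
  list(
    criteria = list(
      A = list(max = 4, levels = c(very_wide = 1, wide = 2, restricted = 3,
                                   very_restricted = 4)),
      B = list(max = 3, levels = c(favorable = 1, intermediate = 2,
                                   hostile = 3)),
      C = list(max = 3, levels = c(low = 1, medium = 2, high = 3)),
      D = list(max = 4, levels = c(low = 1, moderate = 2, high = 3,
                                   very_high = 4))),
    genetic = list(he_low = 0.25, nm_low = 1.0, gst_high = 0.30))
}

#' Genetic inputs for intrinsic vulnerability
#'
#' @param he mean expected heterozygosity across populations.
#' @param gst among-population differentiation.
#' @param nm effective migrants per generation.
#' @param private_trend direction of the private-allele count under
#'   decline/extinction scenarios: `"none"`, `"decrease"` or `"increase"`.
#' @param trend_significant was the trend significant (chi-squared p < 0.05)?
#' @return a `genetic_vulnerability` list.
#' @export
genetic_vulnerability <- function(he, gst, nm,
                                  private_trend = c("none", "decrease", "increase"),
                                  trend_significant = FALSE) {
  private_trend <- match.arg(private_trend)
  stopifnot(is.finite(he), is.finite(gst), is.finite(nm))
  structure(list(he = he, gst = gst, nm = nm, private_trend = private_trend,
                 trend_significant = trend_significant),
            class = "genetic_vulnerability")
}

genetic_level <- function(gvi, config = mer_criteria_config()) {
  g <- config$genetic
  flags <- (gvi$he < g$he_low) + (gvi$nm < g$nm_low) + (gvi$gst > g$gst_high)
  lvl <- 1L
  if (flags >= 2) lvl <- 2L
  if (flags >= 2 && gvi$private_trend == "decrease" && gvi$trend_significant)
    lvl <- 3L
  lvl
}

#' MER risk category from the total score
#'
#' Step thresholds on the sum of the four normalized criteria: in danger of
#' extinction (`EE`) at total >= 2.0, threatened (`E`) on [1.70, 2.0),
#' special protection (`Pr`) on [1.5, 1.70), below-threshold (`NS`)
#' otherwise. The published interval bounds overlap at exactly 1.70 ("<= 1.70"
#' for Pr, ">= 1.70" for E); the boundary is resolved in favour of the
#' higher-risk category E, consistent with the method's precautionary
#' framing, and flagged.
#'
#' @param total_score finite, non-negative total.
#' @return list with `category` (one of `"EE"`, `"E"`, `"Pr"`, `"NS"`),
#'   `total` and `on_boundary`.
#' @export
classify_mer <- function(total_score) {
  if (!is.finite(total_score)) stop("total score must be finite")
  if (total_score < 0) stop("total score must be non-negative")
  category <- if (total_score >= 2.0) "EE"
    else if (total_score >= 1.70) "E"
    else if (total_score >= 1.5) "Pr"
    else "NS"
  boundary <- total_score %in% c(1.5, 1.70, 2.0)
  list(category = category, total = total_score, on_boundary = boundary)
}

#' Score a species under the MER
#'
#' Maps each criterion's qualitative level to points (ascending risk),
#' normalizes by the criterion maximum, sums and classifies via
#' [classify_mer()]. All four criteria must be named in `inputs`; a criterion
#' whose state is genuinely unassessed may be given as `"unknown"`, which
#' contributes 0 and is flagged in the notes (the method requires all
#' criteria, but historical assessments with partial knowledge are a real use
#' case). When genetic inputs are supplied, criterion C scores the *maximum*
#' of its ecological and genetic sub-scores: genetic evidence can raise, but
#' never lower, intrinsic vulnerability.
#'
#' @param inputs list with elements `A`, `B`, `C`, `D`. `A`, `B`, `D` are
#'   level names from the config; `C` is either a level name or a list
#'   `list(ecological = <level>, genetic = <genetic_vulnerability>)`.
#' @param config a [mer_criteria_config()]-shaped list.
#' @return a `mer_assessment` list: `scores` (per-criterion data frame),
#'   `total`, `category`, `on_boundary`, `notes`.
#' @export
score_mer <- function(inputs, config = mer_criteria_config()) {
  missing <- setdiff(c("A", "B", "C", "D"), names(inputs))
  if (length(missing) > 0L)
    stop("MER requires all criteria; missing: ", paste(missing, collapse = ", "))
  notes <- character(0)
  level_points <- function(crit, level) {
    if (identical(level, "unknown")) return(NA_real_)
    pts <- config$criteria[[crit]]$levels[level]
    if (anyNA(pts)) stop(sprintf("unknown level '%s' for criterion %s", level, crit))
    unname(pts)
  }
  pts <- numeric(4); names(pts) <- c("A", "B", "C", "D")
  lvl_used <- character(4); names(lvl_used) <- names(pts)
  for (cr in c("A", "B", "D")) {
    p <- level_points(cr, inputs[[cr]])
    if (is.na(p)) { notes <- c(notes, sprintf("criterion %s unassessed (0)", cr)); p <- 0 }
    pts[cr] <- p; lvl_used[cr] <- as.character(inputs[[cr]])
  }
  cin <- inputs$C
  if (is.list(cin)) {
    eco <- level_points("C", cin$ecological)
    if (is.na(eco)) { notes <- c(notes, "criterion C ecological unassessed (0)"); eco <- 0 }
    gen <- 0
    if (!is.null(cin$genetic)) {
      stopifnot(inherits(cin$genetic, "genetic_vulnerability"))
      gen <- genetic_level(cin$genetic, config)
      notes <- c(notes, sprintf("criterion C genetic sub-score = %d", gen))
    }
    pts["C"] <- max(eco, gen)
    lvl_used["C"] <- sprintf("eco=%s/gen=%s", cin$ecological,
                             if (is.null(cin$genetic)) "-" else gen)
  } else {
    p <- level_points("C", cin)
    if (is.na(p)) { notes <- c(notes, "criterion C unassessed (0)"); p <- 0 }
    pts["C"] <- p; lvl_used["C"] <- as.character(cin)
  }
  maxima <- vapply(c("A", "B", "C", "D"),
                   function(cr) config$criteria[[cr]]$max, 0)
  normalized <- pts / maxima
  total <- sum(normalized)
  cl <- classify_mer(total)
  if (cl$on_boundary) notes <- c(notes, "total sits exactly on a category boundary")
  scores <- data.frame(criterion = names(pts), level = lvl_used, points = pts,
                       max = maxima, normalized = normalized,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(scores = scores, total = total, category = cl$category,
                 on_boundary = cl$on_boundary, notes = notes),
            class = "mer_assessment")
}

#' @export
print.mer_assessment <- function(x, ...) {
  print.data.frame(x$scores, digits = 3)
  cat(sprintf("total = %.3f -> MER category %s\n", x$total, x$category))
  if (length(x$notes)) cat(paste(" note:", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' MER assessment presets for the study scenarios
#'
#' Named input sets reproducing the assessment timeline of the study system:
#' `"2005"` (basic knowledge: distribution and habitat only) classifies as
#' special protection; `"2020e"` (full ecological assessment) as threatened;
#' `"2020e+g"` (ecological + genetic evidence) as in danger of extinction;
#' `"2020e+g_50"` and `"2020e+g_ex"` (genetic evidence including a
#' significant private-allele decline under the 50%-loss and local-extinction
#' scenarios) as in danger of extinction with a higher total. The
#' ecological-only scenario variants (`"2020e_50"`, `"2020e_ex"`) reuse the
#' 2020 ecological levels. Per-criterion levels are an illustrative
#' reconstruction — the method's qualitative worksheets are not part of the
#' published record — chosen so the category outcomes match the published
#' timeline.
#'
#' @param name one of `"2005"`, `"2020e"`, `"2020e_50"`, `"2020e_ex"`,
#'   `"2020e+g"`, `"2020e+g_50"`, `"2020e+g_ex"`.
#' @param genetics optional `genetic_vulnerability` overriding the preset's
#'   canned genetic inputs (so measured values from a pipeline run can feed
#'   the assessment).
#' @return input list for [score_mer()].
#' @export
mer_preset <- function(name = c("2005", "2020e", "2020e_50", "2020e_ex",
                                "2020e+g", "2020e+g_50", "2020e+g_ex"),
                       genetics = NULL) {
  name <- match.arg(name)
  eco2020 <- list(A = "very_restricted", B = "favorable",
                  C = list(ecological = "low"), D = "low")
  gen_base <- genetic_vulnerability(he = 0.208, gst = 0.471, nm = 0.92)
  gen_sim <- genetic_vulnerability(he = 0.208, gst = 0.471, nm = 0.633,
                                   private_trend = "decrease",
                                   trend_significant = TRUE)
  out <- switch(name,
    "2005" = list(A = "very_restricted", B = "intermediate",
                  C = "unknown", D = "unknown"),
    "2020e" = eco2020,
    "2020e_50" = eco2020,
    "2020e_ex" = eco2020,
    "2020e+g" = modifyList(eco2020, list(
      C = list(ecological = "low", genetic = gen_base))),
    "2020e+g_50" = modifyList(eco2020, list(
      C = list(ecological = "low", genetic = gen_sim))),
    "2020e+g_ex" = modifyList(eco2020, list(
      C = list(ecological = "low", genetic = gen_sim))))
  if (!is.null(genetics) && is.list(out$C))
    out$C$genetic <- genetics
  out
}

#' Default thresholds for the simplified IUCN mapper
#'
#' Standard published category bounds for the criteria the rule engine
#' evaluates (reduction A, restricted geographic range B, small population
#' and decline C, very small population D, quantitative analysis E). These
#' bounds are external, published constants, shipped as an editable config.
#' `local_extinction_prob` is the extinction probability imputed for
#' criterion E when ongoing local population extinctions are observed but no
#' explicit quantitative estimate is supplied.
#'
#' @return nested list of thresholds.
#' @export
iucn_thresholds <- function() {
  list(
    A_decline = c(VU = 0.30, EN = 0.50, CR = 0.80),
    B_area_km2 = c(VU = 2000, EN = 500, CR = 100),
    B_locations = c(VU = 10, EN = 5, CR = 1),
    C_pop = c(VU = 10000, EN = 2500, CR = 250),
    D_pop = c(VU = 1000, EN = 250, CR = 50),
    D2_area_km2 = 20, D2_locations = 5,
    E_prob = c(VU = 0.10, EN = 0.20, CR = 0.50),
    local_extinction_prob = 0.50)
}

iucn_rank <- c(LC = 1, NT = 2, VU = 3, EN = 4, CR = 5)

#' Simplified IUCN red-list category mapper
#'
#' Evaluates each supplied criterion against the configured thresholds and
#' returns the highest category triggered by any criterion (the method does
#' not require all criteria). This is a config-driven rule engine over parts
#' of the red-list system, not a legal-grade implementation: subconditions
#' are reduced to the headline bounds documented in [iucn_thresholds()].
#'
#' @param population_size mature individuals (criteria C, D).
#' @param range_area_km2 occupied area in km2 (criteria B, D2).
#' @param n_locations number of locations (criteria B, D2).
#' @param decline_fraction observed/projected population reduction (criterion
#'   A), in [0, 1].
#' @param continuing_decline is a continuing decline observed (gates B and
#'   C)?
#' @param local_extinction are local population extinctions observed
#'   (feeds criterion E via `local_extinction_prob`)?
#' @param extinction_prob explicit quantitative extinction probability
#'   (criterion E).
#' @param config an [iucn_thresholds()]-shaped list.
#' @return an `iucn_assessment` list: `category`, `triggered` (named vector
#'   criterion -> category), `inputs`.
#' @export
classify_iucn <- function(population_size = NULL, range_area_km2 = NULL,
                          n_locations = NULL, decline_fraction = NULL,
                          continuing_decline = FALSE,
                          local_extinction = FALSE, extinction_prob = NULL,
                          config = iucn_thresholds()) {
  supplied <- any(!vapply(list(population_size, range_area_km2,
                               decline_fraction, extinction_prob),
                          is.null, TRUE)) || local_extinction
  if (!supplied) stop("no criteria supplied")
  triggered <- character(0)
  hit <- function(crit, cat) triggered[crit] <<- cat
  grade <- function(value, bounds, geq = TRUE) {
    # highest category whose bound the value crosses
    cats <- c("CR", "EN", "VU")
    for (cat in cats) {
      ok <- if (geq) value >= bounds[cat] else value < bounds[cat]
      if (ok) return(cat)
    }
    NA_character_
  }
  if (!is.null(decline_fraction) && decline_fraction > 0) {
    g <- grade(decline_fraction, config$A_decline, geq = TRUE)
    if (!is.na(g)) hit("A", g)
  }
  if (!is.null(range_area_km2) && !is.null(n_locations)) {
    for (cat in c("CR", "EN", "VU")) {
      if (range_area_km2 < config$B_area_km2[cat] &&
          n_locations <= config$B_locations[cat]) { hit("B", cat); break }
    }
  }
  if (!is.null(population_size) && continuing_decline) {
    g <- grade(population_size, config$C_pop, geq = FALSE)
    if (!is.na(g)) hit("C", g)
  }
  if (!is.null(population_size)) {
    g <- grade(population_size, config$D_pop, geq = FALSE)
    if (!is.na(g)) hit("D", g)
  }
  if (is.null(extinction_prob) && local_extinction)
    extinction_prob <- config$local_extinction_prob
  if (!is.null(extinction_prob)) {
    g <- grade(extinction_prob, config$E_prob, geq = TRUE)
    if (!is.na(g)) hit("E", g)
  }
  category <- if (length(triggered) == 0L) "LC"
    else names(iucn_rank)[max(iucn_rank[triggered])]
  structure(list(category = category, triggered = triggered,
                 inputs = list(population_size = population_size,
                               range_area_km2 = range_area_km2,
                               n_locations = n_locations,
                               decline_fraction = decline_fraction,
                               continuing_decline = continuing_decline,
                               local_extinction = local_extinction,
                               extinction_prob = extinction_prob)),
            class = "iucn_assessment")
}

#' @export
print.iucn_assessment <- function(x, ...) {
  cat(sprintf("IUCN (simplified): category %s", x$category))
  if (length(x$triggered))
    cat("  [", paste(sprintf("%s:%s", names(x$triggered), x$triggered),
                     collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' IUCN assessment presets for the study scenarios
#'
#' Baseline inputs describe a cliff-dwelling species at six locations on
#' well under 2000 km2 of occupied habitat with a continuing decline:
#' vulnerable. The 50%-loss scenarios add a quantified reduction of 0.5
#' (endangered via criterion A); the local-extinction scenarios flag observed
#' ongoing local extinctions (critically endangered via criterion E).
#'
#' @param name one of `"2005"`, `"2020e"`, `"2020e_50"`, `"2020e_ex"`,
#'   `"2020e+g"`, `"2020e+g_50"`, `"2020e+g_ex"`.
#' @param config threshold config passed through to [classify_iucn()].
#' @return an `iucn_assessment`.
#' @export
iucn_preset <- function(name = c("2005", "2020e", "2020e_50", "2020e_ex",
                                 "2020e+g", "2020e+g_50", "2020e+g_ex"),
                        config = iucn_thresholds()) {
  name <- match.arg(name)
  base <- list(population_size = 6000, range_area_km2 = 0.2, n_locations = 6,
               continuing_decline = TRUE)
  extra <- if (grepl("_50$", name)) list(decline_fraction = 0.5)
    else if (grepl("_ex$", name)) list(local_extinction = TRUE)
    else list()
  do.call(classify_iucn, c(base, extra, list(config = config)))
}
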