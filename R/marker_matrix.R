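#' Dominant binary marker matrix
#'
#' Container for an individuals x loci presence/absence (0/1) band matrix,
#' the universal input of the package. Each individual belongs to exactly one
#' population. Band presence is coded 1, absence 0. An explicit missing-data
#' sentinel (`NA`) may be stored, but every statistics function rejects
#' matrices that contain it: the analysis chain assumes complete data.
#'
#' @param bands numeric or integer matrix of 0/1 values; rows are individuals,
#'   columns are loci. Row and column names are used as individual and locus
#'   identifiers (generated when absent).
#' @param populations character or factor giving the population of each
#'   individual, either in row order or named by individual id.
#' @param individual_ids,locus_ids optional label vectors overriding dimnames.
#'
#' @return An object of class `marker_matrix`: a list with elements `bands`
#'   (integer matrix with dimnames) and `pop` (named factor, individual ->
#'   population).
#' @examples
#' m <- marker_matrix(rbind(a = c(1, 0, 1), b = c(0, 0, 1), c = c(1, 1, 1)),
#'                    populations = c("P1", "P1", "P2"))
#' n_individuals(m)
#' @export
marker_matrix <- function(bands, populations, individual_ids = NULL,
                          locus_ids = NULL) {
  bands <- as.matrix(bands)
  if (!is.null(individual_ids)) rownames(bands) <- individual_ids
  if (!is.null(locus_ids)) colnames(bands) <- locus_ids
  if (is.null(rownames(bands)))
    rownames(bands) <- sprintf("ind%03d", seq_len(nrow(bands)))
  if (is.null(colnames(bands)))
    colnames(bands) <- sprintf("L%03d", seq_len(ncol(bands)))
  storage.mode(bands) <- "integer"
  if (!is.null(names(populations))) {
    populations <- populations[rownames(bands)]
  }
  pop <- factor(as.character(populations))
  names(pop) <- rownames(bands)
  m <- structure(list(bands = bands, pop = pop), class = "marker_matrix")
  validate_marker_matrix(m)
  m
}

#' Validate a marker matrix
#'
#' Checks the invariants of the container: binary cells (0/1, with `NA`
#' tolerated only as the declared missing sentinel), unique individual and
#' locus labels, and a non-empty population for every individual.
#'
#' @param m a `marker_matrix`.
#' @param allow_missing should `NA` cells be tolerated? Statistics functions
#'   call this with `FALSE` and fail fast on incomplete matrices.
#' @return `m`, invisibly. Errors describe the offending cell or label.
#' @export
validate_marker_matrix <- function(m, allow_missing = TRUE) {
  stopifnot(inherits(m, "marker_matrix"))
  b <- m$bands
  if (nrow(b) < 1L || ncol(b) < 1L)
    stop("marker matrix must have at least one individual and one locus")
  bad <- which(!(b %in% c(0L, 1L)) & !is.na(b))
  if (length(bad) > 0L) {
    i <- ((bad[1] - 1) %% nrow(b)) + 1
    j <- ((bad[1] - 1) %/% nrow(b)) + 1
    stop(sprintf("non-binary cell value %s at individual '%s', locus '%s'",
                 b[bad[1]], rownames(b)[i], colnames(b)[j]))
  }
  if (anyNA(b)) {
    if (!allow_missing)
      stop("matrix contains missing cells; this analysis requires complete data")
  }
  if (anyDuplicated(rownames(b)))
    stop("duplicate individual ids: ",
         paste(unique(rownames(b)[duplicated(rownames(b))]), collapse = ", "))
  if (anyDuplicated(colnames(b)))
    stop("duplicate locus ids: ",
         paste(unique(colnames(b)[duplicated(colnames(b))]), collapse = ", "))
  if (length(m$pop) != nrow(b) || !identical(names(m$pop), rownames(b)))
    stop("population assignment must name every individual exactly once")
  if (anyNA(m$pop)) stop("individuals without a population assignment")
  if (any(table(m$pop) < 1L)) stop("every population must have >= 1 individual")
  invisible(m)
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d loci, %d populations\n",
              nrow(x$bands), ncol(x$bands), nlevels(x$pop)))
  tab <- table(x$pop)
  cat("  ", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname marker_matrix
#' @param m a `marker_matrix`.
#' @export
n_individuals <- function(m) nrow(m$bands)

#' @rdname marker_matrix
#' @export
n_loci <- function(m) ncol(m$bands)

#' @rdname marker_matrix
#' @export
populations <- function(m) levels(m$pop)

#' Subset a marker matrix by individuals or populations
#'
#' Returns a matrix restricted to the requested individuals or populations.
#' The locus set is unchanged and invariants are re-validated. Used by the
#' decline/extinction scenario machinery.
#'
#' @param m a `marker_matrix`.
#' @param individuals individual ids to keep (optional).
#' @param keep_populations population labels to keep (optional).
#' @return a `marker_matrix` containing exactly the requested rows.
#' @export
subset_markers <- function(m, individuals = NULL, keep_populations = NULL) {
  validate_marker_matrix(m)
  keep <- rownames(m$bands)
  if (!is.null(keep_populations)) {
    unknown <- setdiff(keep_populations, levels(m$pop))
    if (length(unknown) > 0L)
      stop("unknown population label(s): ", paste(unknown, collapse = ", "))
    keep <- keep[as.character(m$pop[keep]) %in% keep_populations]
  }
  if (!is.null(individuals)) {
    unknown <- setdiff(individuals, rownames(m$bands))
    if (length(unknown) > 0L)
      stop("unknown individual id(s): ", paste(unknown, collapse = ", "))
    keep <- intersect(keep, individuals)
  }
  if (length(keep) == 0L) stop("subset selects no individuals")
  marker_matrix(m$bands[keep, , drop = FALSE],
                populations = droplevels(m$pop[keep]))
}

#' Total number of distinct observed bands
#'
#' Counts loci at which at least one individual shows the band. Non-increasing
#' under any removal of individuals.
#'
#' @param m a `marker_matrix`.
#' @return integer count of loci with at least one band.
#' @export
total_bands <- function(m) sum(colSums(m$bands) > 0L)

#' Planar population coordinates
#'
#' Stores one planar (x, y) coordinate pair per population, in kilometres.
#' Longitude/latitude input is projected with an equirectangular projection at
#' the mean latitude; only relative distances matter for the isolation by
#' distance test, which works on log distances.
#'
#' @param population character vector of population labels.
#' @param x,y planar coordinates in km, or longitude/latitude in degrees when
#'   `lonlat = TRUE`.
#' @param lonlat interpret `x`, `y` as lon/lat degrees and project to km.
#' @return a `population_geo` data frame with columns population, x, y.
#' @export
population_geo <- function(population, x, y, lonlat = FALSE) {
  if (anyDuplicated(population)) stop("one coordinate pair per population")
  if (lonlat) {
    latm <- mean(y) * pi / 180
    x <- x * 111.32 * cos(latm)
    y <- y * 110.57
  }
  g <- data.frame(population = as.character(population), x = x, y = y,
                  stringsAsFactors = FALSE)
  class(g) <- c("population_geo", "data.frame")
  d <- geo_distances(g)
  if (any(d[upper.tri(d)] <= 0))
    stop("distinct populations must have pairwise distance > 0")
  g
}

#' Pairwise geographic distances between populations
#'
#' @param geo a `population_geo`.
#' @return symmetric matrix of Euclidean distances in km.
#' @export
geo_distances <- function(geo) {
  d <- as.matrix(dist(cbind(geo$x, geo$y)))
  dimnames(d) <- list(geo$population, geo$population)
  d
}
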