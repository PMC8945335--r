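#' Read a dominant marker matrix from disk
#'
#' Three plain-text dialects are supported:
#' \describe{
#'   \item{csv}{first column individual id, second column population, one
#'     column per locus with 0/1 values; header row required.}
#'   \item{genalex}{the minimal GenAlEx binary-data layout: a first header row
#'     `n_loci, n_individuals, n_pops, size_1, ..., size_k`, a title row
#'     carrying population names from the fourth cell on, a column-header row,
#'     then one data row per individual.}
#'   \item{structure}{one row per individual (dominant data): a locus-name
#'     header line, then `id pop_index band_1 ... band_L`, whitespace
#'     separated. Population labels are integer-recoded on write, so reading
#'     back recovers the band matrix, individual ids and the population
#'     partition, with generated labels `pop1`, `pop2`, ...}
#' }
#'
#' @param path file to read.
#' @param dialect one of `"csv"`, `"genalex"`, `"structure"`.
#' @return a validated [marker_matrix()].
#' @seealso [write_marker_matrix()]
#' @export
read_marker_matrix <- function(path, dialect = c("csv", "genalex", "structure")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
    csv = {
      df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
      if (ncol(df) < 3L) stop("csv dialect needs id, population and >= 1 locus column")
      bands <- as.matrix(df[, -(1:2), drop = FALSE])
      rownames(bands) <- df[[1]]
      marker_matrix(bands, populations = df[[2]])
    },
    genalex = {
      lines <- readLines(path)
      hdr <- as.integer(strsplit(lines[1], ",")[[1]][1:3])
      df <- read.csv(text = paste(lines[-(1:2)], collapse = "\n"),
                     check.names = FALSE, stringsAsFactors = FALSE)
      if (nrow(df) != hdr[2])
        stop(sprintf("genalex header declares %d individuals, file has %d rows",
                     hdr[2], nrow(df)))
      if (ncol(df) - 2L != hdr[1])
        stop(sprintf("genalex header declares %d loci, file has %d locus columns",
                     hdr[1], ncol(df) - 2L))
      bands <- as.matrix(df[, -(1:2), drop = FALSE])
      rownames(bands) <- df[[1]]
      marker_matrix(bands, populations = df[[2]])
    },
    structure = {
      lines <- readLines(path)
      loci <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
      rows <- strsplit(trimws(lines[-1]), "[ \t]+")
      ids <- vapply(rows, `[`, "", 1L)
      popi <- as.integer(vapply(rows, `[`, "", 2L))
      bands <- t(vapply(rows, function(r) as.integer(r[-(1:2)]),
                        integer(length(loci))))
      dimnames(bands) <- list(ids, loci)
      marker_matrix(bands, populations = sprintf("pop%d", popi))
    })
}

#' Write a dominant marker matrix to disk
#'
#' Inverse of [read_marker_matrix()]; the csv and genalex dialects round-trip
#' with no information loss, the structure dialect integer-recodes population
#' labels (bands, individual ids and the partition are preserved).
#'
#' @param m a `marker_matrix`.
#' @param path output file.
#' @param dialect one of `"csv"`, `"genalex"`, `"structure"`.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path, dialect = c("csv", "genalex", "structure")) {
  dialect <- match.arg(dialect)
  validate_marker_matrix(m)
  b <- m$bands
  switch(dialect,
    csv = {
      df <- data.frame(individual = rownames(b),
                       population = as.character(m$pop),
                       b, check.names = FALSE, stringsAsFactors = FALSE)
      write.csv(df, path, row.names = FALSE, quote = FALSE)
    },
    genalex = {
      sizes <- table(m$pop)
      l1 <- paste(c(ncol(b), nrow(b), nlevels(m$pop), as.integer(sizes)),
                  collapse = ",")
      l2 <- paste(c("issrpop binary export", "", names(sizes)), collapse = ",")
      l3 <- paste(c("individual", "population", colnames(b)), collapse = ",")
      rows <- apply(cbind(rownames(b), as.character(m$pop), b), 1,
                    paste, collapse = ",")
      writeLines(c(l1, l2, l3, rows), path)
    },
    structure = {
      popi <- as.integer(m$pop)
      rows <- vapply(seq_len(nrow(b)), function(i)
        paste(c(rownames(b)[i], popi[i], b[i, ]), collapse = "\t"), "")
      writeLines(c(paste(colnames(b), collapse = "\t"), rows), path)
    })
  invisible(path)
}
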