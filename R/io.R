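#' Read per-lake abundance tables
#'
#' Accepts either a directory of wide CSV files (`abundance_<lake>.csv`,
#' first column `year`, remaining columns taxa) or a single long TSV with
#' columns `lake`, `year`, `taxon`, `count`. Counts are validated as
#' nonnegative integers; years are sorted ascending; duplicate
#' (lake, year, taxon) records are an error.
#'
#' @param path directory of wide CSVs or a long TSV file.
#' @return named list of [abundance_series()], one per lake.
#' @export
read_abundance <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^abundance_.*\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no abundance_*.csv files in ", path)
    out <- lapply(files, read_wide_series, value_kind = "count")
    names(out) <- vapply(out, function(x) x$lake_id, character(1))
    return(out)
  }
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lake", "year", "taxon", "count")
  if (!all(need %in% names(long))) {
    stop("long abundance table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(long$count) | long$count < 0 |
                 long$count != round(long$count))
  if (length(bad)) {
    stop(sprintf("invalid count at line %d of %s: %s", bad[1] + 1L, path,
                 as.character(long$count[bad[1]])))
  }
  key <- paste(long$lake, long$year, long$taxon)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (lake, year, taxon) record at line %d of %s",
                 which(duplicated(key))[1] + 1L, path))
  }
  out <- lapply(split(long, long$lake), function(d) {
    years <- sort(unique(d$year))
    taxa <- sort(unique(d$taxon))
    m <- matrix(0, length(years), length(taxa), dimnames = list(years, taxa))
    m[cbind(match(d$year, years), match(d$taxon, taxa))] <- d$count
    abundance_series(d$lake[1], years, m)
  })
  out[order(names(out))]
}

# one wide per-lake CSV: first column `year`, remaining columns values
read_wide_series <- function(file, value_kind = c("count", "numeric")) {
  value_kind <- match.arg(value_kind)
  lake <- sub("^(abundance|env)_(.*)\\.csv$", "\\2", basename(file))
  d <- utils::read.csv(file, check.names = FALSE)
  if (names(d)[1] != "year") stop("first column of ", file, " must be 'year'")
  if (anyDuplicated(d$year)) {
    stop(sprintf("duplicate year at line %d of %s",
                 which(duplicated(d$year))[1] + 1L, file))
  }
  d <- d[order(d$year), , drop = FALSE]
  m <- as.matrix(d[, -1, drop = FALSE])
  if (value_kind == "count") {
    bad <- which(!is.finite(m) | m < 0 | m != round(m))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(m))
      stop(sprintf("invalid count in %s (year %s, column '%s')", file,
                   d$year[rc[1]], colnames(m)[rc[2]]))
    }
    abundance_series(lake, d$year, m)
  } else {
    env_series(lake, d$year, m)
  }
}

#' Read per-lake environmental tables
#'
#' Accepts a directory of wide CSV files (`env_<lake>.csv`) or a single long
#' TSV with columns `lake`, `year`, `variable`, `value` and optionally
#' `season`. Multiple records per (lake, year, variable) — e.g. summer and
#' autumn water samples — are averaged to one annual value. Missing values
#' are allowed.
#'
#' @param path directory of wide CSVs or a long TSV file.
#' @return named list of [env_series()], one per lake.
#' @export
read_env <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^env_.*\\.csv$", full.names = TRUE))
    if (length(files) == 0L) stop("no env_*.csv files in ", path)
    out <- lapply(files, read_wide_series, value_kind = "numeric")
    names(out) <- vapply(out, function(x) x$lake_id, character(1))
    return(out)
  }
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lake", "year", "variable", "value")
  if (!all(need %in% names(long))) {
    stop("long environmental table needs columns: ", paste(need, collapse = ", "))
  }
  agg <- stats::aggregate(value ~ lake + year + variable, data = long,
                          FUN = mean, na.action = stats::na.omit)
  out <- lapply(split(agg, agg$lake), function(d) {
    years <- sort(unique(d$year))
    vars <- sort(unique(d$variable))
    m <- matrix(NA_real_, length(years), length(vars),
                dimnames = list(years, vars))
    m[cbind(match(d$year, years), match(d$variable, vars))] <- d$value
    env_series(d$lake[1], years, m)
  })
  out[order(names(out))]
}

#' Read lake coordinates
#'
#' CSV with columns `lake_id`, `x`, `y` (planar coordinates in consistent
#' units). Lake ids must be unique and no two lakes may share a coordinate
#' pair.
#'
#' @param path CSV path.
#' @return data frame with columns `lake_id`, `x`, `y`.
#' @export
read_coords <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lake_id", "x", "y") %in% names(d))) {
    stop("coordinates file needs columns lake_id, x, y")
  }
  if (anyDuplicated(d$lake_id)) stop("duplicate lake_id in ", path)
  if (anyDuplicated(d[, c("x", "y")])) stop("duplicate coordinate pair in ", path)
  d[, c("lake_id", "x", "y")]
}

#' Read the genus-level dispersal-trait table
#'
#' CSV with columns `genus`, `AFS`, `FD`; values `low`, `high` or `unknown`.
#'
#' @param path CSV path.
#' @return data frame with columns `genus`, `AFS`, `FD`.
#' @export
read_traits <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("genus", "AFS", "FD") %in% names(d))) {
    stop("trait table needs columns genus, AFS, FD")
  }
  for (col in c("AFS", "FD")) {
    bad <- setdiff(unique(d[[col]]), c("low", "high", "unknown"))
    if (length(bad)) {
      stop("invalid ", col, " level(s): ", paste(bad, collapse = ", "))
    }
  }
  if (anyDuplicated(d$genus)) stop("duplicate genus in ", path)
  d[, c("genus", "AFS", "FD")]
}

#' Write a correlation matrix as CSV
#'
#' Lakes as rows (first column `lake_id`), taxa or variables as columns.
#'
#' @param M a [correlation_matrix][assemble_species_matrix].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(M, path) {
  df <- data.frame(lake_id = rownames(M), as.matrix(M), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
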