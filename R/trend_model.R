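#' Abundance and environmental time series containers
#'
#' Light containers for one site's taxa-by-year count table and
#' variables-by-year environmental table. Rows are years (sorted ascending);
#' columns are taxa or variables.
#'
#' @param lake_id site identifier.
#' @param years integer vector of sampling years, strictly increasing.
#' @param counts years x taxa matrix of nonnegative integer counts.
#' @return an object of class `abundance_series`.
#' @export
abundance_series <- function(lake_id, years, counts) {
  counts <- as.matrix(counts)
  years <- as.integer(years)
  if (length(years) != nrow(counts)) stop("'years' must match rows of 'counts'")
  if (is.unsorted(years, strictly = TRUE)) stop("'years' must be strictly increasing")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be nonnegative integers")
  }
  rownames(counts) <- years
  structure(list(lake_id = as.character(lake_id), years = years,
                 counts = counts), class = "abundance_series")
}

#' @param values years x variables numeric matrix; missing values allowed.
#' @rdname abundance_series
#' @export
env_series <- function(lake_id, years, values) {
  values <- as.matrix(values)
  years <- as.integer(years)
  if (length(years) != nrow(values)) stop("'years' must match rows of 'values'")
  if (is.unsorted(years, strictly = TRUE)) stop("'years' must be strictly increasing")
  rownames(values) <- years
  structure(list(lake_id = as.character(lake_id), years = years,
                 values = values), class = "env_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  cat(sprintf("abundance series '%s': %d years (%d-%d), %d taxa\n", x$lake_id,
              length(x$years), min(x$years), max(x$years), ncol(x$counts)))
  invisible(x)
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("environmental series '%s': %d years, %d variables\n",
              x$lake_id, length(x$years), ncol(x$values)))
  invisible(x)
}

#' Temporal eigenfunction basis for a year vector
#'
#' Convenience wrapper around [build_eigenbasis()] using `year - min(year)`
#' as the 1-D coordinate (unit = one year) and labelling points with the
#' calendar years.
#'
#' @param years integer vector of sampling years, strictly increasing.
#' @param ... passed to [build_eigenbasis()] (`threshold`, `tol`).
#' @return an `eigenbasis` of kind `"temporal"` with `point_ids = years`.
#' @examples
#' temporal_eigenbasis(1988:2007)
#' @export
temporal_eigenbasis <- function(years, ...) {
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE)) stop("'years' must be strictly increasing")
  b <- build_eigenbasis(years - min(years), kind = "temporal", ...)
  b$point_ids <- years
  rownames(b$vectors) <- years
  b
}

#' Fit the temporal species-group model for one site (Step 1)
#'
#' The full time-series modeling chain for one community table: Hellinger
#' transformation, double-stopping forward selection of temporal
#' eigenfunctions, RDA on the selected eigenfunctions, and sequential
#' permutation tests of the canonical axes. Each significant canonical axis
#' is interpreted as one species group with its own temporal scale, its lc
#' scores being the modeled group trend. Axes are counted significant from
#' the first axis up to the first non-significant one (the sequential test
#' conditions each axis on those before it).
#'
#' @param abund an [abundance_series()] (or years x taxa count matrix with
#'   year rownames).
#' @param basis a temporal [eigenbasis][temporal_eigenbasis] built on the
#'   same years.
#' @param alpha significance level for selection and axis tests.
#' @param n_perm permutations for all tests.
#' @param seed optional integer seed for reproducibility.
#' @return object of class `trend_model`: `lake_id`, `years`, `selected`
#'   (eigenfunction ids), `axes` (data frame: axis, eigenvalue, p_value,
#'   adj_var_share, significant), `lc_scores` (years x axes),
#'   `n_significant`, `r2`, `adj_r2`, `forward` (the selection object).
#' @export
fit_temporal_model <- function(abund, basis, alpha = 0.05, n_perm = 999,
                               seed = NULL) {
  if (!inherits(abund, "abundance_series")) {
    ymat <- as.matrix(abund)
    yrs <- as.integer(rownames(ymat))
    if (anyNA(yrs)) stop("matrix input needs year rownames")
    abund <- abundance_series("site", yrs, ymat)
  }
  stopifnot(inherits(basis, "eigenbasis"))
  byrs <- suppressWarnings(as.integer(basis$point_ids))
  if (length(byrs) != length(abund$years) ||
      (!anyNA(byrs) && !all(byrs == abund$years))) {
    stop("year mismatch between abundance series and temporal basis")
  }
  Yh <- hellinger_transform(abund$counts)
  with_seed(seed, {
    fs <- forward_select(Yh, basis, alpha = alpha, n_perm = n_perm)
    if (length(fs$selected) == 0L) {
      return(structure(
        list(lake_id = abund$lake_id, years = abund$years,
             selected = character(0),
             axes = data.frame(axis = integer(0), eigenvalue = numeric(0),
                               p_value = numeric(0), adj_var_share = numeric(0),
                               significant = logical(0)),
             lc_scores = matrix(numeric(0), nrow = length(abund$years), ncol = 0,
                                dimnames = list(abund$years, NULL)),
             n_significant = 0L, r2 = 0, adj_r2 = 0,
             alpha = alpha, n_perm = n_perm, forward = fs),
        class = "trend_model"))
    }
    X <- basis$vectors[, fs$selected, drop = FALSE]
    fit <- rda_fit(Yh, X)
    pvals <- permutation_axis_test(Yh, X, n_perm = n_perm)
    K <- length(fit$eigenvalues)
    adj_factor <- if (fit$r2 > 0 && !is.na(fit$adj_r2)) fit$adj_r2 / fit$r2 else 0
    share <- fit$eigenvalues / fit$total_var * adj_factor
    sig <- rep(FALSE, K)
    run <- which(pvals > alpha)
    n_sig <- as.integer(if (length(run) == 0L) K else run[1L] - 1L)
    if (n_sig > 0L) sig[seq_len(n_sig)] <- TRUE
    axes <- data.frame(axis = seq_len(K), eigenvalue = fit$eigenvalues,
                       p_value = unname(pvals), adj_var_share = share,
                       significant = sig)
    structure(
      list(lake_id = abund$lake_id, years = abund$years,
           selected = fs$selected, axes = axes, lc_scores = fit$lc_scores,
           n_significant = n_sig, r2 = fit$r2, adj_r2 = fit$adj_r2,
           alpha = alpha, n_perm = n_perm, forward = fs),
      class = "trend_model")
  })
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("temporal model '%s': %d eigenfunctions selected (%s)\n",
              x$lake_id, length(x$selected),
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "none"))
  cat(sprintf("%d significant canonical axes at alpha = %g; adj R2 = %.3f\n",
              x$n_significant, x$alpha, x$adj_r2))
  if (nrow(x$axes)) print(x$axes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a fitted temporal model to disk
#'
#' Serializes the model as JSON plus an lc-score CSV (rows = years,
#' columns = axes).
#'
#' @param model a [trend_model][fit_temporal_model].
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_trend_model <- function(model, dir) {
  stopifnot(inherits(model, "trend_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, paste0("trend_", model$lake_id))
  j <- list(lake_id = model$lake_id, years = model$years,
            selected = model$selected, axes = model$axes,
            n_significant = model$n_significant, r2 = model$r2,
            adj_r2 = model$adj_r2, alpha = model$alpha, n_perm = model$n_perm)
  jsonlite::write_json(j, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  lc <- data.frame(year = model$years, model$lc_scores, check.names = FALSE)
  utils::write.csv(lc, paste0(base, "_lc.csv"), row.names = FALSE)
  invisible(c(paste0(base, ".json"), paste0(base, "_lc.csv")))
}
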