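#' Spearman rank correlation with t-approximation
#'
#' Tie-corrected Spearman correlation from mid-ranks, with a two-sided
#' p-value from the t-approximation on n - 2 degrees of freedom. Missing
#' values are handled pairwise-complete. Constant vectors yield an undefined
#' correlation, flagged via `rho = NA` (treated as non-significant
#' downstream).
#'
#' @param x,y numeric vectors of equal length; at least 4 paired non-missing
#'   values.
#' @return list with `rho`, `p`, and `n` (pairs used).
#' @examples
#' spearman_cor(1:4, c(2, 4, 6, 8))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 4L) stop("need at least 4 paired non-missing values")
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlations of raw taxon abundances with modeled group trends (Step 2)
#'
#' For each significant canonical axis of a fitted temporal model, computes
#' the Spearman correlation between each taxon's raw (untransformed) counts
#' and the axis lc scores. Taxa with constant abundance are excluded as
#' undefined.
#'
#' @param abund the [abundance_series()] the model was fitted to.
#' @param model a [trend_model][fit_temporal_model] with at least one
#'   significant axis.
#' @return data frame with columns `lake_id`, `axis`, `taxon`, `rho`, `p`.
#' @export
taxa_trend_correlations <- function(abund, model) {
  stopifnot(inherits(model, "trend_model"))
  if (!inherits(abund, "abundance_series")) stop("'abund' must be an abundance_series")
  if (model$n_significant < 1L) stop("model has no significant axes")
  out <- list()
  for (k in seq_len(model$n_significant)) {
    lc <- model$lc_scores[, k]
    for (tx in colnames(abund$counts)) {
      cnt <- abund$counts[, tx]
      if (length(unique(cnt)) < 2L) next # constant: undefined, excluded
      s <- spearman_cor(cnt, lc)
      if (is.na(s$rho)) next
      out[[length(out) + 1L]] <- data.frame(
        lake_id = abund$lake_id, axis = k, taxon = tx, rho = s$rho, p = s$p)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lake_id = character(0), axis = integer(0),
                      taxon = character(0), rho = numeric(0), p = numeric(0)))
  }
  do.call(rbind, out)
}

#' Correlations of environmental variables with modeled group trends (Step 2)
#'
#' As [taxa_trend_correlations()], for annual environmental values (missing
#' values pairwise-deleted; variables with fewer than 4 complete pairs or
#' constant values are excluded as undefined).
#'
#' @param env the lake's [env_series()]; years must match the model's.
#' @param model a [trend_model][fit_temporal_model] with at least one
#'   significant axis.
#' @return data frame with columns `lake_id`, `axis`, `variable`, `rho`, `p`.
#' @export
env_trend_correlations <- function(env, model) {
  stopifnot(inherits(model, "trend_model"))
  if (!inherits(env, "env_series")) stop("'env' must be an env_series")
  if (model$n_significant < 1L) stop("model has no significant axes")
  if (!identical(as.integer(env$years), as.integer(model$years))) {
    stop("year mismatch between environmental series and model")
  }
  out <- list()
  for (k in seq_len(model$n_significant)) {
    lc <- model$lc_scores[, k]
    for (v in colnames(env$values)) {
      vals <- env$values[, v]
      if (sum(is.finite(vals) & is.finite(lc)) < 4L) next
      s <- spearman_cor(vals, lc)
      if (is.na(s$rho)) next
      out[[length(out) + 1L]] <- data.frame(
        lake_id = env$lake_id, axis = k, variable = v, rho = s$rho, p = s$p)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lake_id = character(0), axis = integer(0),
                      variable = character(0), rho = numeric(0), p = numeric(0)))
  }
  do.call(rbind, out)
}

# shared assembly of lakes x columns |rho| matrices
assemble_matrix <- function(tables, axis, alpha, id_col) {
  if (!is.list(tables) || length(tables) < 2L) stop("need tables from at least 2 lakes")
  lakes <- names(tables) %||% as.character(seq_along(tables))
  rows <- lapply(tables, function(tb) tb[tb$axis == axis, , drop = FALSE])
  if (all(vapply(rows, nrow, 1L) == 0L)) stop("axis not modeled in any lake")
  cols <- sort(unique(unlist(lapply(rows, function(tb) tb[[id_col]]))))
  M <- matrix(0, length(tables), length(cols), dimnames = list(lakes, cols))
  for (i in seq_along(rows)) {
    tb <- rows[[i]]
    sig <- tb[!is.na(tb$p) & tb$p <= alpha, , drop = FALSE]
    if (nrow(sig)) M[i, sig[[id_col]]] <- abs(sig$rho)
  }
  M <- M[, colSums(M) > 0, drop = FALSE] # drop columns significant nowhere
  structure(M, axis = axis, alpha = alpha, class = c("correlation_matrix", "matrix"))
}

#' Assemble the time-explicit species matrix for one canonical axis (Step 2)
#'
#' Builds the lakes x taxa matrix used in the metacommunity analyses: the
#' entry is the absolute Spearman correlation of the taxon's raw abundance
#' with the lake's modeled group trend when that correlation is significant
#' at `alpha`, and 0 otherwise. Taxa significant in no lake are dropped;
#' lakes lacking the axis contribute all-zero rows.
#'
#' @param tables named list (by lake) of [taxa_trend_correlations()] outputs.
#' @param axis 1-based canonical axis index.
#' @param alpha per-correlation significance level (no multiplicity
#'   correction, mirroring the reporting convention of monitoring studies).
#' @return a `correlation_matrix`: numeric lakes x taxa matrix with
#'   attributes `axis` and `alpha`; values in \[0, 1\].
#' @export
assemble_species_matrix <- function(tables, axis, alpha = 0.05) {
  assemble_matrix(tables, axis, alpha, "taxon")
}

#' Assemble the environmental predictor matrix for one canonical axis (Step 3)
#'
#' As [assemble_species_matrix()] for environmental variables, followed by
#' collinearity pruning to avoid overfitting the later variance
#' partitioning. Two variables count as collinear when the absolute Spearman
#' correlation of their matrix columns across lakes exceeds
#' `collinearity_rho`, or — when the per-lake environmental series are
#' supplied via `env` — when the median across lakes of the absolute
#' within-lake Spearman correlation of their annual series exceeds it (the
#' strength columns of strongly coupled variables are often near-constant
#' across lakes, which makes the column criterion alone unstable). While any
#' pair is collinear, the pair with the strongest association is located and
#' its member with the smaller mean absolute trend correlation is dropped
#' (ties: the later column).
#'
#' @inheritParams assemble_species_matrix
#' @param tables named list (by lake) of [env_trend_correlations()] outputs.
#' @param collinearity_rho pruning threshold on between-variable correlation.
#' @param env optional named list (by lake) of [env_series()] used for the
#'   within-lake series-collinearity criterion.
#' @return a `correlation_matrix` (lakes x variables), possibly with zero
#'   columns (with a warning) if no variable survives.
#' @export
assemble_env_matrix <- function(tables, axis, alpha = 0.05,
                                collinearity_rho = 0.7, env = NULL) {
  M <- assemble_matrix(tables, axis, alpha, "variable")
  ax <- attr(M, "axis"); al <- attr(M, "alpha")
  if (ncol(M) == 0L) {
    warning("no significant environmental variables for axis ", axis)
    return(M)
  }
  series_rho <- function(v1, v2) {
    if (is.null(env)) return(0)
    rr <- vapply(env, function(e) {
      vars <- colnames(e$values)
      if (!all(c(v1, v2) %in% vars)) return(NA_real_)
      x <- e$values[, v1]; y <- e$values[, v2]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 4L || length(unique(x[ok])) < 2L ||
          length(unique(y[ok])) < 2L) return(NA_real_)
      abs(stats::cor(rank(x[ok]), rank(y[ok])))
    }, numeric(1))
    if (all(is.na(rr))) 0 else stats::median(rr, na.rm = TRUE)
  }
  repeat {
    k <- ncol(M)
    if (k < 2L) break
    cm <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        colcor <- if (stats::sd(M[, i]) > 0 && stats::sd(M[, j]) > 0) {
          abs(stats::cor(rank(M[, i]), rank(M[, j])))
        } else 0
        cm[i, j] <- max(colcor, series_rho(colnames(M)[i], colnames(M)[j]))
      }
    }
    if (max(cm) <= collinearity_rho) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1L, ] # first = earliest pair
    strength <- colMeans(abs(M))
    drop_j <- if (strength[idx[1L]] < strength[idx[2L]]) idx[1L] else idx[2L]
    M <- M[, -drop_j, drop = FALSE]
  }
  if (ncol(M) == 0L) warning("all environmental variables pruned for axis ", axis)
  structure(as.matrix(M), axis = ax, alpha = al,
            class = c("correlation_matrix", "matrix"))
}

#' Table of per-lake trend correlations in reporting layout
#'
#' Reshapes per-lake signed correlation tables into the conventional
#' variables-by-lakes report, one cell per lake and variable holding
#' `rho` with significance stars for each axis (`axis1/axis2`), `ns` when
#' not significant.
#'
#' @param tables named list (by lake) of [env_trend_correlations()] or
#'   [taxa_trend_correlations()] outputs.
#' @param axes integer vector of axes to report (default 1:2).
#' @param alpha significance level for the `ns` label.
#' @return character data frame: first column the variable/taxon, one column
#'   per lake.
#' @export
correlation_report <- function(tables, axes = 1:2, alpha = 0.05) {
  id_col <- if ("variable" %in% names(tables[[1]])) "variable" else "taxon"
  lakes <- names(tables)
  ids <- sort(unique(unlist(lapply(tables, function(tb) tb[[id_col]]))))
  stars <- function(p) {
    if (is.na(p) || p > 0.05) "" else if (p <= 0.001) "***" else if (p <= 0.01) "**" else "*"
  }
  cell <- function(tb, id) {
    paste(vapply(axes, function(k) {
      row <- tb[tb[[id_col]] == id & tb$axis == k, , drop = FALSE]
      if (nrow(row) == 0L || is.na(row$p[1]) || row$p[1] > alpha) return("ns")
      sprintf("%.2f%s", row$rho[1], stars(row$p[1]))
    }, character(1)), collapse = "/")
  }
  out <- data.frame(id = ids, check.names = FALSE)
  names(out) <- id_col
  for (l in lakes) out[[l]] <- vapply(ids, function(id) cell(tables[[l]], id), character(1))
  out
}
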