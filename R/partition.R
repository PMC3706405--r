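#' Forward-selected spatial eigenfunctions for a species-group matrix (Step 3)
#'
#' Builds a spatial PCNM basis from planar lake coordinates and forward
#' selects eigenfunctions against the Hellinger-transformed species-group
#' matrix. The retained eigenfunctions form the spatial predictor matrix for
#' variance partitioning; the selection may be empty when the group carries
#' no spatial signal.
#'
#' @param Y lakes x taxa [correlation_matrix][assemble_species_matrix] (or
#'   any nonnegative matrix); rows must align with `coords`.
#' @param coords data frame with columns `lake_id`, `x`, `y` (planar,
#'   consistent units), one row per row of `Y`.
#' @param alpha,n_perm,seed forward-selection settings, see [forward_select()].
#' @param tol eigenvalue retention tolerance for [build_eigenbasis()].
#' @return lakes x k matrix of selected spatial eigenfunctions (k may be 0),
#'   with attributes `basis` (the full eigenbasis) and `selection` (the
#'   [forward_select()] result).
#' @export
spatial_predictors <- function(Y, coords, alpha = 0.05, n_perm = 999,
                               seed = NULL, tol = 0.05) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 4L) stop("need at least 4 lakes")
  if (!all(c("x", "y") %in% names(coords))) stop("'coords' needs columns x and y")
  if (nrow(coords) != nrow(Y)) stop("'coords' rows must match 'Y' rows")
  if (anyDuplicated(coords[, c("x", "y")])) stop("duplicate lake coordinates")
  xy <- as.matrix(coords[, c("x", "y")])
  rownames(xy) <- coords$lake_id %||% rownames(Y)
  basis <- build_eigenbasis(xy, kind = "spatial", tol = tol)
  Yh <- hellinger_transform(Y)
  sel <- forward_select(Yh, basis, alpha = alpha, n_perm = n_perm, seed = seed)
  S <- basis$vectors[, sel$selected, drop = FALSE]
  attr(S, "basis") <- basis
  attr(S, "selection") <- sel
  S
}

#' Variance partitioning of a species-group matrix (Step 4)
#'
#' Partitions the variation of the Hellinger-transformed species-group matrix
#' into six named fractions from three RDA fits (environment alone, space
#' alone, both): `environment_uncorrected` = adjR2(Y ~ E),
#' `space_uncorrected` = adjR2(Y ~ S), `pure_environment` = combined -
#' space_uncorrected, `pure_space` = combined - environment_uncorrected,
#' `shared` = environment_uncorrected + space_uncorrected - combined, and
#' `residual` = 1 - combined. Adjusted fractions are reported as computed
#' (negative values are not clipped, preserving additivity:
#' pure_environment + pure_space + shared + residual = 1).
#'
#' Marginal fractions are tested by a global RDA permutation test; pure
#' fractions by a partial-RDA permutation test, either permuting
#' reduced-model residuals (`scheme = "reduced"`, default) or the raw
#' response rows (`scheme = "direct"`). No test exists for the shared and
#' residual fractions.
#'
#' @param Y lakes x taxa species-group matrix (Hellinger transformation is
#'   applied internally).
#' @param E lakes x variables environmental predictor matrix (may be `NULL`
#'   or zero-column: its fractions are reported as 0 without p-values).
#' @param S lakes x k spatial predictor matrix (idem).
#' @param n_perm permutations for the fraction tests.
#' @param seed optional integer seed.
#' @param scheme permutation scheme for the pure fractions.
#' @return object of class `partition_result`: `fractions` (named numeric,
#'   the six fractions), `p_values` (named, testable fractions only; `NA`
#'   when not testable), `r2` (unadjusted R2 of the three fits), `n_perm`,
#'   `seed`, `scheme`, `n`, `m_env`, `m_space`.
#' @export
variance_partition <- function(Y, E, S, n_perm = 999, seed = NULL,
                               scheme = c("reduced", "direct")) {
  scheme <- match.arg(scheme)
  if (!is_count_scalar(n_perm) || n_perm < 99) stop("'n_perm' must be >= 99")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  norm_pred <- function(M) {
    if (is.null(M)) return(matrix(numeric(0), n, 0L))
    M <- as.matrix(M)
    if (ncol(M) > 0L && nrow(M) != n) stop("predictor rows must match 'Y' rows")
    M
  }
  E <- norm_pred(E); S <- norm_pred(S)
  Yh <- hellinger_transform(Y)
  Yc <- center_cols(Yh)
  tot <- sum(Yc^2)
  if (tot <= 0) stop("response matrix has no variance")

  fit_adj <- function(M) {
    if (ncol(M) == 0L) return(list(r2 = 0, adj = 0, Q = NULL, m = 0L))
    ob <- ortho_basis(center_cols(M))
    ssf <- sum(crossprod(ob$Q, Yc)^2)
    r2 <- ssf / tot
    list(r2 = r2, adj = adjusted_r2(r2, n, ob$rank), Q = ob$Q, m = ob$rank)
  }
  fe <- fit_adj(E)
  fs <- fit_adj(S)
  fb <- fit_adj(if (ncol(E) && ncol(S)) cbind(E, S) else if (ncol(E)) E else S)

  fractions <- c(
    pure_environment = fb$adj - fs$adj,
    pure_space = fb$adj - fe$adj,
    space_uncorrected = fs$adj,
    environment_uncorrected = fe$adj,
    shared = fe$adj + fs$adj - fb$adj,
    residual = 1 - fb$adj
  )

  with_seed(seed, {
    pv <- c(pure_environment = NA_real_, pure_space = NA_real_,
            space_uncorrected = NA_real_, environment_uncorrected = NA_real_)
    if (ncol(E)) pv["environment_uncorrected"] <- global_perm_p(Yc, fe, n_perm)
    if (ncol(S)) pv["space_uncorrected"] <- global_perm_p(Yc, fs, n_perm)
    if (ncol(E) && ncol(S)) {
      pv["pure_environment"] <- partial_perm_p(Yc, test = E, cond = S,
                                               n_perm = n_perm, scheme = scheme)
      pv["pure_space"] <- partial_perm_p(Yc, test = S, cond = E,
                                         n_perm = n_perm, scheme = scheme)
    } else if (ncol(E)) {
      pv["pure_environment"] <- pv["environment_uncorrected"]
    } else if (ncol(S)) {
      pv["pure_space"] <- pv["space_uncorrected"]
    }
    structure(
      list(fractions = fractions, p_values = pv,
           r2 = c(environment = fe$r2, space = fs$r2, combined = fb$r2),
           n_perm = n_perm, seed = seed, scheme = scheme, n = n,
           m_env = fe$m, m_space = fs$m),
      class = "partition_result"
    )
  })
}

# global RDA permutation test given a fitted component list from fit_adj()
global_perm_p <- function(Yc, f, n_perm) {
  n <- nrow(Yc)
  tot <- sum(Yc^2)
  df_res <- max(n - 1L - f$m, 1L)
  fstat <- function(ssf) {
    rss <- tot - ssf
    if (rss <= .Machine$double.eps * tot) return(Inf)
    (ssf / f$m) / (rss / df_res)
  }
  f_obs <- fstat(sum(crossprod(f$Q, Yc)^2))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    f_b <- fstat(sum(crossprod(f$Q, Yc[sample.int(n), , drop = FALSE])^2))
    if (f_b >= f_obs) exceed <- exceed + 1L
  }
  (exceed + 1) / (n_perm + 1)
}

# partial RDA permutation test of `test` given `cond`
partial_perm_p <- function(Yc, test, cond, n_perm, scheme) {
  n <- nrow(Yc)
  Qc <- ortho_basis(center_cols(cond))$Q
  mc <- ncol(Qc)
  Tr <- residualize(center_cols(test), Qc)
  obt <- ortho_basis(Tr)
  mt <- obt$rank
  df_res <- max(n - 1L - mc - mt, 1L)
  stat_for <- function(Ym) {
    Yr <- residualize(Ym, Qc)
    ssr_tot <- sum(Yr^2)
    ssf <- sum(crossprod(obt$Q, Yr)^2)
    rss <- ssr_tot - ssf
    if (rss <= .Machine$double.eps * max(ssr_tot, 1)) return(Inf)
    (ssf / mt) / (rss / df_res)
  }
  if (scheme == "direct") {
    f_obs <- stat_for(Yc)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (stat_for(Yc[sample.int(n), , drop = FALSE]) >= f_obs) exceed <- exceed + 1L
    }
  } else {
    # permutation of residuals under the reduced (conditioning-only) model
    Yfit <- Yc - residualize(Yc, Qc)
    Yres <- Yc - Yfit
    f_obs <- stat_for(Yc)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      Yb <- Yfit + Yres[sample.int(n), , drop = FALSE]
      if (stat_for(Yb) >= f_obs) exceed <- exceed + 1L
    }
  }
  (exceed + 1) / (n_perm + 1)
}

#' @export
print.partition_result <- function(x, ...) {
  cat("variance partitioning (adjusted R2):\n")
  lab <- c(pure_environment = "Pure environment", pure_space = "Pure space",
           space_uncorrected = "Space uncorrected for environment",
           environment_uncorrected = "Environment uncorrected for space",
           shared = "Shared variance", residual = "Residual")
  for (nm in names(lab)) {
    p <- if (nm %in% names(x$p_values)) x$p_values[[nm]] else NA_real_
    cat(sprintf("  %-34s %8.4f%s\n", lab[[nm]], x$fractions[[nm]],
                if (is.na(p)) "" else sprintf("  (P = %.4g)", p)))
  }
  invisible(x)
}

#' Write a partition result as a report table plus JSON
#'
#' Writes a fractions-by-columns TSV (`fraction`, `adj_r2`, `p`) in the
#' conventional variance-partitioning report layout, and a JSON file with the
#' full object.
#'
#' @param x a [partition_result][variance_partition] or a named list of them
#'   (one per species group); list names become column suffixes.
#' @param path output TSV path; the JSON is written next to it.
#' @return `path`, invisibly.
#' @export
write_partition <- function(x, path) {
  if (inherits(x, "partition_result")) x <- list(group1 = x)
  stopifnot(all(vapply(x, inherits, TRUE, "partition_result")))
  order_nm <- c("environment_uncorrected", "space_uncorrected",
                "pure_environment", "pure_space", "shared", "residual")
  lab <- c("Environment uncorrected for space",
           "Space uncorrected for environment",
           "Pure environment", "Pure space", "Shared variance", "Residual")
  df <- data.frame(Fractions = lab)
  for (g in names(x)) {
    fr <- x[[g]]$fractions[order_nm]
    pv <- vapply(order_nm, function(nm) {
      if (nm %in% names(x[[g]]$p_values)) x[[g]]$p_values[[nm]] else NA_real_
    }, numeric(1))
    df[[paste0(g, "_adjR2")]] <- sprintf("%.3f", fr)
    df[[paste0(g, "_P")]] <- ifelse(is.na(pv), "", sprintf("%.4f", pv))
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jpath <- paste0(sub("\\.tsv$", "", path), ".json")
  jsonlite::write_json(
    lapply(x, function(p) list(fractions = as.list(p$fractions),
                               p_values = as.list(p$p_values),
                               n_perm = p$n_perm, scheme = p$scheme, n = p$n)),
    jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
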