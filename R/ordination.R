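#' Hellinger transformation
#'
#' Square root of relative abundance per sample row:
#' \eqn{y'_{ij} = \sqrt{y_{ij} / \sum_k y_{ik}}}. Makes Euclidean-based
#' ordination appropriate for zero-rich community tables by removing the
#' double-zero problem. All-zero rows are mapped to all-zero rows.
#'
#' @param Y samples x taxa matrix (or data frame) of nonnegative values.
#' @return numeric matrix of the same dimension; nonzero rows have unit
#'   Euclidean norm.
#' @examples
#' hellinger_transform(rbind(c(1, 1, 2), c(0, 0, 0)))
#' @export
hellinger_transform <- function(Y) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("'Y' must be numeric")
  if (anyNA(Y)) stop("'Y' must not contain missing values")
  if (any(Y < 0)) stop("negative entry in abundance matrix")
  rs <- rowSums(Y)
  out <- sqrt(sweep(Y, 1L, ifelse(rs > 0, rs, 1), `/`))
  dimnames(out) <- dimnames(Y)
  out
}

#' Ezekiel-adjusted R-squared
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - m - 1)}. Corrects explained
#' variance for the number of predictors so fractions fitted with different
#' numbers of variables are comparable; may be negative.
#'
#' @param r2 unadjusted R-squared in \[0, 1\].
#' @param n number of samples.
#' @param m number of predictors.
#' @return adjusted R-squared (scalar, possibly negative).
#' @examples
#' adjusted_r2(0.5, 20, 4) # 0.3666667
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (!is.numeric(r2) || length(r2) != 1L || r2 < 0 || r2 > 1 + 1e-12) {
    stop("'r2' must be a single value in [0, 1]")
  }
  if (!is_count_scalar(n) || !is_count_scalar(m)) stop("'n' and 'm' must be counts")
  if (n <= m + 1) stop("insufficient residual df: need n > m + 1")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Redundancy analysis (RDA)
#'
#' Least-squares projection of the centered response matrix onto the centered
#' predictors, followed by a principal-component decomposition of the fitted
#' values. Canonical eigenvalues are variances (sums of squares divided by
#' n - 1) of the fitted matrix along each axis; site lc scores are the fitted
#' values projected on the axes ("linear combination" scores, i.e. the
#' modeled trend when predictors are temporal eigenfunctions).
#'
#' @param Y samples x taxa response matrix (typically Hellinger-transformed).
#' @param X samples x m predictor matrix; must be full column rank after
#'   centering.
#' @param axis_tol relative singular-value tolerance deciding how many
#'   canonical axes are kept.
#' @return object of class `rda_fit`: `eigenvalues` (descending),
#'   `lc_scores` (samples x axes), `species_scores` (taxa x axes), `r2`,
#'   `adj_r2`, `n`, `m`, `total_var`, `fitted`.
#' @export
rda_fit <- function(Y, X, axis_tol = 1e-8) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("'Y' and 'X' must have the same number of rows")
  if (ncol(X) < 1L) stop("'X' must have at least one column")
  n <- nrow(Y)
  Yc <- center_cols(Y)
  Xc <- center_cols(X)
  ob <- ortho_basis(Xc, strict = TRUE)
  Q <- ob$Q
  m <- ob$rank
  M <- crossprod(Q, Yc)              # m x p core matrix; fitted = Q %*% M
  tot <- sum(Yc^2)
  ssfit <- sum(M^2)
  r2 <- if (tot > 0) ssfit / tot else 0
  sv <- svd(M)
  keep <- which(sv$d > axis_tol * max(sv$d, 0) & sv$d > 0)
  d <- sv$d[keep]
  lc <- Q %*% (sv$u[, keep, drop = FALSE] %*% diag(d, nrow = length(d)))
  spp <- sv$v[, keep, drop = FALSE]
  # reproducible axis orientation: largest-magnitude lc score positive
  for (j in seq_along(keep)) {
    if (lc[which.max(abs(lc[, j])), j] < 0) {
      lc[, j] <- -lc[, j]
      spp[, j] <- -spp[, j]
    }
  }
  rownames(lc) <- rownames(Y)
  colnames(lc) <- paste0("RDA", seq_along(keep))
  rownames(spp) <- colnames(Y)
  colnames(spp) <- colnames(lc)
  adj <- if (n > m + 1) adjusted_r2(r2, n, m) else NA_real_
  structure(
    list(eigenvalues = d^2 / (n - 1), lc_scores = lc, species_scores = spp,
         r2 = r2, adj_r2 = adj, n = n, m = m,
         total_var = tot / (n - 1), fitted = Q %*% M),
    class = "rda_fit"
  )
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA: n = %d samples, m = %d predictors, %d canonical axes\n",
              x$n, x$m, length(x$eigenvalues)))
  cat(sprintf("R2 = %.4f, adjusted R2 = %.4f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' Sequential permutation test of canonical axes
#'
#' Tests each canonical axis by the forward (sequential) method: for axis k,
#' response and predictors are residualized on the lc scores of the previous
#' axes, response rows are permuted freely, and the pseudo-F of the leading
#' canonical eigenvalue of the residualized model is recomputed. Because the
#' canonical axes are orthogonal, each axis is thereby tested conditional on
#' those before it. p = (exceedances + 1) / (n_perm + 1).
#'
#' @inheritParams rda_fit
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed; fixed seed gives identical p-values.
#' @return named numeric vector of p-values, one per canonical axis.
#' @export
permutation_axis_test <- function(Y, X, n_perm = 999, seed = NULL) {
  if (!is_count_scalar(n_perm) || n_perm < 99) stop("'n_perm' must be >= 99")
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Yc <- center_cols(Y)
  Xc <- center_cols(X)
  fit <- rda_fit(Yc, Xc)
  K <- length(fit$eigenvalues)
  with_seed(seed, {
    p <- numeric(K)
    for (k in seq_len(K)) {
      if (k == 1L) {
        Yk <- Yc; Xk <- Xc
      } else {
        Z <- fit$lc_scores[, seq_len(k - 1L), drop = FALSE]
        QZ <- ortho_basis(center_cols(Z))$Q
        Yk <- residualize(Yc, QZ)
        Xk <- residualize(Xc, QZ)
      }
      obq <- ortho_basis(Xk)
      QZ <- if (k == 1L) NULL else ortho_basis(center_cols(
        fit$lc_scores[, seq_len(k - 1L), drop = FALSE]))$Q
      p[k] <- perm_axis_p(Yk, obq$Q, QZ = QZ, n_prior = k - 1L,
                          n_perm = n_perm)
    }
    names(p) <- paste0("RDA", seq_len(K))
    p
  })
}

# Leading-eigenvalue pseudo-F permutation p-value for residualized data.
# Permuted responses are re-residualized on the conditioning axes (QZ) so
# each replicate is treated exactly like the observed (conditioned) data.
perm_axis_p <- function(Yk, Q, QZ = NULL, n_prior, n_perm) {
  n <- nrow(Yk)
  r <- ncol(Q)
  df_res <- max(n - 1L - n_prior - r, 1L)
  stat <- function(Ym) {
    Ym <- residualize(Ym, QZ)
    tot <- sum(Ym^2)
    M <- crossprod(Q, Ym)
    lam1 <- svd(M, nu = 0, nv = 0)$d[1]^2
    rss <- max(tot - sum(M^2), 0)
    if (rss < .Machine$double.eps * max(tot, 1)) return(Inf)
    lam1 / (rss / df_res)
  }
  f_obs <- stat(Yk)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    f_b <- stat(Yk[sample.int(n), , drop = FALSE])
    if (f_b >= f_obs) exceed <- exceed + 1L
  }
  (exceed + 1) / (n_perm + 1)
}

#' Forward selection of eigenfunctions with double stopping
#'
#' Stepwise selection of predictors for RDA with the double stopping
#' criterion: selection only proceeds if the global model containing all
#' candidates is significant; variables are then added in order of added
#' explained variance, each gated by a permutation test of its partial
#' contribution (permutation of reduced-model residuals), and the procedure
#' stops as soon as a candidate is non-significant or the cumulative adjusted
#' R-squared would exceed the global model's adjusted R-squared. Ties in
#' added variance are broken toward the lower-ranked (broader-scale)
#' eigenfunction.
#'
#' @inheritParams permutation_axis_test
#' @param candidates an [eigenbasis][build_eigenbasis] or a samples x k
#'   matrix of candidate predictors.
#' @param alpha significance level for the global gate and each step.
#' @return object of class `forward_selection`: `selected` (character ids in
#'   selection order, possibly empty), `global_p`, `global_adj_r2`, `steps`
#'   (one row per accepted/tested step), `alpha`, `n_perm`.
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, n_perm = 999,
                           seed = NULL) {
  X <- if (inherits(candidates, "eigenbasis")) candidates$vectors else as.matrix(candidates)
  empty <- function(global_p = NA_real_, global_adj = NA_real_, steps = NULL) {
    structure(list(selected = character(0), global_p = global_p,
                   global_adj_r2 = global_adj,
                   steps = steps %||% data.frame(
                     candidate = character(0), added_r2 = numeric(0),
                     cum_r2 = numeric(0), cum_adj_r2 = numeric(0),
                     p = numeric(0), accepted = logical(0)),
                   alpha = alpha, n_perm = n_perm),
              class = "forward_selection")
  }
  if (is.null(X) || ncol(X) == 0L) return(empty())
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("'Y' and 'candidates' must have the same number of rows")
  if (!is_count_scalar(n_perm) || n_perm < 99) stop("'n_perm' must be >= 99")
  n <- nrow(Y)
  Yc <- center_cols(Y)
  tot <- sum(Yc^2)
  if (tot <= 0) return(empty())
  Xc <- center_cols(X)

  with_seed(seed, {
    # global gate: model with all candidates
    obA <- ortho_basis(Xc)
    r <- obA$rank
    ss_all <- sum(crossprod(obA$Q, Yc)^2)
    df_res <- n - 1L - r
    if (df_res < 1L) stop("too many candidates for the number of samples")
    gate_f <- function(ssf) {
      rss <- max(tot - ssf, 0)
      if (rss <= .Machine$double.eps * tot) return(Inf)
      (ssf / r) / (rss / df_res)
    }
    f_obs <- gate_f(ss_all)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      f_b <- gate_f(sum(crossprod(obA$Q, Yc[sample.int(n), , drop = FALSE])^2))
      if (f_b >= f_obs) exceed <- exceed + 1L
    }
    global_p <- (exceed + 1) / (n_perm + 1)
    global_adj <- adjusted_r2(ss_all / tot, n, r)
    if (global_p > alpha) return(empty(global_p, global_adj))

    selected <- integer(0)
    Qsel <- matrix(0, n, 0L)
    cum_ss <- 0
    steps <- list()
    remaining <- seq_len(ncol(Xc))
    while (length(remaining) > 0L && length(selected) < r) {
      Yr <- residualize(Yc, Qsel)
      ss_res <- sum(Yr^2)
      added <- rep(-Inf, length(remaining))
      units <- vector("list", length(remaining))
      for (i in seq_along(remaining)) {
        xr <- residualize(Xc[, remaining[i], drop = FALSE], Qsel)
        nx <- sum(xr^2)
        if (nx < 1e-12) next # collinear with current selection
        u <- xr / sqrt(nx)
        units[[i]] <- u
        added[i] <- sum(crossprod(u, Yr)^2)
      }
      if (all(!is.finite(added))) break
      i_best <- which.max(added) # ties: first index = lower eigenfunction rank
      j <- remaining[i_best]
      u <- units[[i_best]]
      ss_add <- added[i_best]
      q <- length(selected)
      df_step <- max(n - 1L - q - 1L, 1L)
      rss_new <- max(ss_res - ss_add, 0)
      f_stat <- function(ssa, ssr) {
        if (ssr <= .Machine$double.eps * tot) return(Inf)
        ssa / (ssr / df_step)
      }
      f_obs <- f_stat(ss_add, rss_new)
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        # re-residualize the permuted response on the current selection
        Yp <- residualize(Yr[sample.int(n), , drop = FALSE], Qsel)
        ssa_b <- sum(crossprod(u, Yp)^2)
        f_b <- f_stat(ssa_b, sum(Yp^2) - ssa_b)
        if (f_b >= f_obs) exceed <- exceed + 1L
      }
      p_step <- (exceed + 1) / (n_perm + 1)
      cum_r2 <- (cum_ss + ss_add) / tot
      cum_adj <- adjusted_r2(min(cum_r2, 1), n, q + 1L)
      accept <- p_step <= alpha && cum_adj <= global_adj + 1e-8
      steps[[length(steps) + 1L]] <- data.frame(
        candidate = colnames(Xc)[j], added_r2 = ss_add / tot,
        cum_r2 = cum_r2, cum_adj_r2 = cum_adj, p = p_step, accepted = accept
      )
      if (!accept) break
      selected <- c(selected, j)
      cum_ss <- cum_ss + ss_add
      Qsel <- cbind(Qsel, u)
      remaining <- setdiff(remaining, j)
    }
    structure(
      list(selected = colnames(Xc)[selected], global_p = global_p,
           global_adj_r2 = global_adj, steps = do.call(rbind, steps) %||%
             empty()$steps, alpha = alpha, n_perm = n_perm),
      class = "forward_selection"
    )
  })
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf("forward selection: global p = %.4g, global adj R2 = %.4g\n",
              x$global_p, x$global_adj_r2))
  if (length(x$selected) == 0L) {
    cat("no variables selected\n")
  } else {
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}
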