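# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialize the stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Column-center a matrix.
center_cols <- function(x) {
  x <- as.matrix(x)
  sweep(x, 2L, colMeans(x), `-`)
}

# Orthonormal basis of the column space of a centered matrix, with a rank
# check. Returns list(Q, rank, dropped). If `strict`, rank deficiency is an
# error naming the collinear columns.
ortho_basis <- function(Xc, strict = FALSE, tol = 1e-10) {
  qrx <- qr(Xc, tol = tol)
  r <- qrx$rank
  if (r == 0L) stop("predictor matrix has rank 0 after centering")
  dropped <- character(0)
  if (r < ncol(Xc)) {
    bad <- qrx$pivot[(r + 1L):ncol(Xc)]
    nm <- colnames(Xc)
    dropped <- if (is.null(nm)) paste0("column ", bad) else nm[bad]
    if (strict) {
      stop("rank-deficient predictors; collinear columns: ",
           paste(dropped, collapse = ", "))
    }
  }
  list(Q = qr.Q(qrx)[, seq_len(r), drop = FALSE], rank = r, dropped = dropped)
}

# Residualize the columns of (centered) Y on an orthonormal basis Q.
residualize <- function(Yc, Q) {
  if (is.null(Q) || ncol(Q) == 0L) return(Yc)
  Yc - Q %*% crossprod(Q, Yc)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
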