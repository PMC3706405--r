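# Brute-force oracles, independent of the package implementation.

# exhaustive Kruskal minimum spanning tree; returns the longest edge used
oracle_mst_longest_edge <- function(coords) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  edges <- edges[order(d[edges]), , drop = FALSE]
  comp <- seq_len(n)
  longest <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if (comp[i] != comp[j]) {
      longest <- max(longest, d[i, j])
      comp[comp == comp[j]] <- comp[i]
      if (length(unique(comp)) == 1L) break
    }
  }
  longest
}

# explicit PCoA of a truncated distance matrix: double centering + eigen
oracle_pcoa <- function(dmat, tol = 0.05) {
  n <- nrow(dmat)
  A <- -0.5 * dmat^2
  H <- diag(n) - matrix(1 / n, n, n)
  G <- H %*% A %*% H
  e <- eigen(G, symmetric = TRUE)
  keep <- which(e$values > tol * max(e$values))
  list(values = e$values[keep],
       vectors = apply(e$vectors[, keep, drop = FALSE], 2,
                       function(v) v / sqrt(sum(v^2))))
}

# RDA by explicit normal equations + eigen-decomposition of the fitted covariance
oracle_rda <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  B <- solve(crossprod(Xc), crossprod(Xc, Yc))
  fit <- Xc %*% B
  ev <- eigen(crossprod(fit) / (nrow(Y) - 1), symmetric = TRUE)$values
  list(eigenvalues = ev[ev > 1e-12 * max(ev, 1e-300)],
       r2 = sum(fit^2) / sum(Yc^2), fitted = fit)
}

oracle_adj_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

# six-fraction partition from three explicit least-squares fits
oracle_partition <- function(Yh, E, S) {
  n <- nrow(Yh)
  r2of <- function(M) {
    o <- oracle_rda(Yh, M)
    oracle_adj_r2(o$r2, n, qr(scale(M, scale = FALSE))$rank)
  }
  ae <- r2of(E); as_ <- r2of(S); ab <- r2of(cbind(E, S))
  c(pure_environment = ab - as_, pure_space = ab - ae,
    space_uncorrected = as_, environment_uncorrected = ae,
    shared = ae + as_ - ab, residual = 1 - ab)
}

# tie-corrected Spearman rho from the explicit mid-rank Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small metacommunity used by several test files (cheap, deterministic)
small_sim <- function(n_lakes = 4, seed = 10, ...) {
  generate_metacommunity(synthetic_config(n_lakes = n_lakes, seed = seed, ...))
}
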