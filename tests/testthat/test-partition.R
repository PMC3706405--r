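# helper: lakes x taxa matrix whose Hellinger transform is exactly H
squared_profile_matrix <- function(H) {
  H <- abs(H) / sqrt(rowSums(H^2))
  H^2
}

test_that("noiseless limit: environment explains everything, space nothing", {
  set.seed(1)
  n <- 30
  H <- matrix(runif(n * 4, 0.2, 1), n, 4)
  Y <- squared_profile_matrix(H)
  Yh <- hellinger_transform(Y)
  Hc <- scale(Yh, scale = FALSE)
  E <- Hc # spans the centered response space exactly
  S <- qr.Q(qr(cbind(1, Hc)), complete = TRUE)[, 6:7] # orthogonal complement
  vp <- variance_partition(Y, E, S, n_perm = 199, seed = 2)
  expect_equal(unname(vp$fractions["residual"]), 0, tolerance = 1e-9)
  expect_equal(unname(vp$fractions["pure_space"]), 0, tolerance = 1e-9)
  # pure environment = 1 - space_uncorrected exactly; the adjusted R2 of the
  # uninformative spatial fit is slightly negative, so the fraction slightly
  # exceeds 1 (negative fractions are reported, not clipped)
  expect_equal(unname(vp$fractions["pure_environment"]),
               1 - unname(vp$fractions["space_uncorrected"]), tolerance = 1e-12)
  expect_equal(unname(vp$fractions["pure_environment"]), 1, tolerance = 0.1)
  expect_lte(vp$p_values[["environment_uncorrected"]], 0.05)
})

test_that("fractions are additive and match the brute-force oracle", {
  set.seed(7)
  for (r in 1:4) {
    Y <- matrix(rpois(8 * 8, 30), 8, 8)
    E <- matrix(rnorm(8 * 2), 8, 2)
    S <- matrix(rnorm(8 * 2), 8, 2)
    vp <- variance_partition(Y, E, S, n_perm = 99, seed = r)
    fr <- vp$fractions
    expect_equal(unname(fr["pure_environment"] + fr["pure_space"] +
                          fr["shared"] + fr["residual"]), 1, tolerance = 1e-9)
    o <- oracle_partition(hellinger_transform(Y), E, S)
    expect_equal(fr[names(o)], o, tolerance = 1e-9)
  }
})

test_that("adjusted fractions agree with vegan::varpart", {
  set.seed(9)
  Y <- matrix(rpois(10 * 6, 25), 10, 6)
  E <- matrix(rnorm(20), 10, 2)
  S <- matrix(rnorm(20), 10, 2)
  vp <- variance_partition(Y, E, S, n_perm = 99, seed = 1)
  vv <- vegan::varpart(hellinger_transform(Y), E, S)
  adj <- vv$part$indfract$Adj.R.square # [a] X1|X2, [b] X2|X1, [c] shared, [d] resid
  expect_equal(unname(vp$fractions["pure_environment"]), adj[1], tolerance = 1e-10)
  expect_equal(unname(vp$fractions["pure_space"]), adj[2], tolerance = 1e-10)
  expect_equal(unname(vp$fractions["shared"]), adj[3], tolerance = 1e-10)
  expect_equal(unname(vp$fractions["residual"]), adj[4], tolerance = 1e-10)
})

test_that("swapping E and S swaps the corresponding fractions", {
  set.seed(11)
  Y <- matrix(rpois(9 * 5, 40), 9, 5)
  E <- matrix(rnorm(18), 9, 2)
  S <- matrix(rnorm(18), 9, 2)
  a <- variance_partition(Y, E, S, n_perm = 99, seed = 3)$fractions
  b <- variance_partition(Y, S, E, n_perm = 99, seed = 3)$fractions
  expect_equal(a[["pure_environment"]], b[["pure_space"]], tolerance = 1e-12)
  expect_equal(a[["space_uncorrected"]], b[["environment_uncorrected"]],
               tolerance = 1e-12)
  expect_equal(a[["shared"]], b[["shared"]], tolerance = 1e-12)
  expect_equal(a[["residual"]], b[["residual"]], tolerance = 1e-12)
})

test_that("an empty predictor matrix zeroes its fractions without p-values", {
  set.seed(13)
  Y <- matrix(rpois(8 * 4, 30), 8, 4)
  S <- matrix(rnorm(16), 8, 2)
  vp <- variance_partition(Y, NULL, S, n_perm = 99, seed = 5)
  expect_equal(unname(vp$fractions["environment_uncorrected"]), 0)
  expect_equal(unname(vp$fractions["pure_environment"]), 0, tolerance = 1e-12)
  expect_true(is.na(vp$p_values[["environment_uncorrected"]]))
  expect_false(is.na(vp$p_values[["space_uncorrected"]]))
  expect_equal(unname(vp$fractions["shared"]), 0)
})

test_that("both permutation schemes are deterministic under a seed", {
  set.seed(15)
  Y <- matrix(rpois(10 * 5, 30), 10, 5)
  E <- matrix(rnorm(20), 10, 2)
  S <- matrix(rnorm(20), 10, 2)
  for (sc in c("reduced", "direct")) {
    a <- variance_partition(Y, E, S, n_perm = 199, seed = 7, scheme = sc)
    b <- variance_partition(Y, E, S, n_perm = 199, seed = 7, scheme = sc)
    expect_identical(a$p_values, b$p_values)
  }
})

test_that("spatial predictors recover a planted east-west gradient", {
  sim <- small_sim(n_lakes = 12, seed = 31)
  basis <- temporal_eigenbasis(1988:2007)
  models <- lapply(sim$abundance, fit_temporal_model, basis = basis,
                   n_perm = 199, seed = 2)
  tt <- lapply(names(models), function(l)
    taxa_trend_correlations(sim$abundance[[l]], models[[l]]))
  names(tt) <- names(models)
  M <- assemble_species_matrix(tt, 1)
  S <- spatial_predictors(M, sim$coords, n_perm = 199, seed = 6)
  expect_gt(ncol(S), 0)
  # a broad-scale eigenfunction is among those selected
  sel_rank <- as.integer(sub("PCNM", "", colnames(S)))
  expect_lte(min(sel_rank), 2)
  expect_error(spatial_predictors(M[1:3, ], sim$coords[1:3, ]), "at least 4")
})

test_that("randomly permuted rows yield empty spatial selections", {
  sim <- small_sim(n_lakes = 12, seed = 32)
  basis <- temporal_eigenbasis(1988:2007)
  models <- lapply(sim$abundance, fit_temporal_model, basis = basis,
                   n_perm = 199, seed = 2)
  tt <- lapply(names(models), function(l)
    taxa_trend_correlations(sim$abundance[[l]], models[[l]]))
  names(tt) <- names(models)
  M <- assemble_species_matrix(tt, 1)
  set.seed(8)
  nonempty <- replicate(10, {
    Mp <- M[sample(nrow(M)), , drop = FALSE]
    rownames(Mp) <- rownames(M)
    ncol(spatial_predictors(Mp, sim$coords, n_perm = 99)) > 0
  })
  expect_lte(sum(nonempty), 2)
})

test_that("partition report has the six fraction rows", {
  set.seed(17)
  Y <- matrix(rpois(8 * 4, 30), 8, 4)
  vp <- variance_partition(Y, matrix(rnorm(16), 8, 2),
                           matrix(rnorm(16), 8, 2), n_perm = 99, seed = 1)
  d <- withr::local_tempdir()
  path <- file.path(d, "part.tsv")
  write_partition(list(group1 = vp), path)
  tab <- utils::read.delim(path)
  expect_identical(tab$Fractions,
                   c("Environment uncorrected for space",
                     "Space uncorrected for environment",
                     "Pure environment", "Pure space",
                     "Shared variance", "Residual"))
  expect_true(file.exists(file.path(d, "part.json")))
})
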