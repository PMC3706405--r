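test_that("spearman correlation handles monotone, tied and degenerate input", {
  expect_equal(spearman_cor(1:4, c(2, 4, 6, 8))$rho, 1)
  expect_equal(spearman_cor(1:4, c(8, 6, 4, 2))$rho, -1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman_cor(x, y)$rho, oracle_spearman(x, y), tolerance = 1e-12)
  # agrees with cor.test's estimate and t-approximation p-value
  set.seed(12)
  a <- rnorm(15); b2 <- a + rnorm(15)
  s <- spearman_cor(a, b2)
  ct <- suppressWarnings(cor.test(a, b2, method = "spearman", exact = FALSE))
  expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
  tval <- s$rho * sqrt((15 - 2) / (1 - s$rho^2))
  expect_equal(s$p, 2 * pt(-abs(tval), 13), tolerance = 1e-12)
  # constant vectors are undefined, missing values pairwise-deleted
  expect_true(is.na(spearman_cor(rep(1, 6), 1:6)$rho))
  expect_equal(spearman_cor(c(1, 2, 3, 4, NA), c(2, 4, 6, 8, 1))$n, 4L)
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

make_tab <- function(lake, axis, taxon, rho, p) {
  data.frame(lake_id = lake, axis = axis, taxon = taxon, rho = rho, p = p)
}

test_that("species matrices assemble |rho| with thresholding", {
  tabs <- list(
    A = make_tab("A", c(1, 1, 2), c("t1", "t2", "t1"), c(0.9, -0.5, 0.4),
                 c(0.001, 0.2, 0.01)),
    B = make_tab("B", c(1, 1), c("t2", "t3"), c(-0.8, 0.6), c(0.01, 0.04)),
    C = make_tab("C", 2, "t1", 0.7, 0.001)
  )
  M <- assemble_species_matrix(tabs, axis = 1, alpha = 0.05)
  # hand-assembled oracle: t2 in A is non-significant -> 0; C lacks axis 1
  expect_identical(rownames(M), c("A", "B", "C"))
  expect_identical(sort(colnames(M)), c("t1", "t2", "t3"))
  expect_equal(M["A", "t1"], 0.9)
  expect_equal(M["A", "t2"], 0)
  expect_equal(M["B", "t2"], 0.8)
  expect_equal(M["B", "t3"], 0.6)
  expect_true(all(M["C", ] == 0))
  expect_true(all(M >= 0 & M <= 1))
  expect_error(assemble_species_matrix(tabs, axis = 3), "axis not modeled")
  expect_error(assemble_species_matrix(tabs["A"], axis = 1), "2 lakes")
})

test_that("raising alpha never removes nonzero entries", {
  set.seed(20)
  tabs <- lapply(c("A", "B", "C"), function(l) {
    make_tab(l, 1, paste0("t", 1:10), runif(10, -1, 1), runif(10))
  })
  names(tabs) <- c("A", "B", "C")
  n_prev <- -1
  for (alpha in c(0.01, 0.05, 0.2, 0.5)) {
    M <- assemble_species_matrix(tabs, 1, alpha = alpha)
    expect_gte(sum(M > 0), n_prev)
    n_prev <- sum(M > 0)
  }
})

test_that("matrix assembly is invariant to lake order", {
  set.seed(21)
  tabs <- lapply(c("A", "B", "C"), function(l) {
    make_tab(l, 1, paste0("t", 1:6), runif(6, -1, 1), runif(6, 0, 0.2))
  })
  names(tabs) <- c("A", "B", "C")
  M1 <- assemble_species_matrix(tabs, 1)
  M2 <- assemble_species_matrix(tabs[c(3, 1, 2)], 1)
  expect_equal(M1[rownames(M2), colnames(M2)], M2, ignore_attr = TRUE)
})

test_that("environmental matrix prunes collinear variables", {
  mk <- function(lake, vals) {
    data.frame(lake_id = lake, axis = 1, variable = names(vals),
               rho = unname(vals), p = 0.001)
  }
  # v1 and v2 identical across lakes; v3 rank-uncorrelated with both
  v1 <- c(0.9, 0.5, 0.7, 0.6, 0.8, 0.4)
  v3 <- c(0.3, 0.4, 0.9, 0.2, 0.7, 0.5)
  stopifnot(abs(cor(rank(v1), rank(v3))) < 0.7)
  lakes <- LETTERS[1:6]
  tabs <- lapply(seq_along(lakes), function(i) {
    mk(lakes[i], c(v1 = v1[i], v2 = v1[i], v3 = v3[i]))
  })
  names(tabs) <- lakes
  M <- assemble_env_matrix(tabs, 1, collinearity_rho = 0.7)
  # one of the identical pair dropped (tie in strength drops the later column)
  expect_identical(sort(colnames(M)), c("v1", "v3"))
  # rank-uncorrelated variables both survive
  tabs2 <- lapply(seq_along(lakes), function(i) {
    mk(lakes[i], c(v1 = v1[i], v2 = v3[i]))
  })
  names(tabs2) <- lakes
  expect_identical(ncol(assemble_env_matrix(tabs2, 1)), 2L)
})

test_that("trend correlations flag generator taxa and drivers on the right axis", {
  sim <- small_sim(n_lakes = 4, seed = 21, dispersion = 1e-4)
  basis <- temporal_eigenbasis(1988:2007)
  ab <- sim$abundance[[2]]
  m <- fit_temporal_model(ab, basis, n_perm = 499, seed = 3)
  tt <- taxa_trend_correlations(ab, m)
  # a taxon whose counts follow the lc-score ranks correlates perfectly
  fake <- ab
  fake$counts <- cbind(ab$counts, mono = rank(m$lc_scores[, 1]))
  tt2 <- taxa_trend_correlations(fake, m)
  expect_equal(tt2$rho[tt2$taxon == "mono" & tt2$axis == 1], 1)
  # constant-abundance taxa are excluded
  fake$counts <- cbind(ab$counts, flat = rep(5, 20))
  expect_false("flat" %in% taxa_trend_correlations(fake, m)$taxon)
  # strongly responding slow taxa: significant on axis 1, not on axis 2
  tr <- sim$truth
  slow <- names(which(tr$group_of_taxon == "slow"))
  eff <- abs(tr$taxon_response[slow]) *
    plogis(2 * sim$config$spatial_gradient_strength *
             tr$taxon_spatial_pref[slow] * tr$spatial_loading[ab$lake_id])
  strong <- slow[eff > 0.3]
  ok <- vapply(strong, function(tx) {
    tt$p[tt$taxon == tx & tt$axis == 1] <= 0.05 &&
      tt$p[tt$taxon == tx & tt$axis == 2] > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.8)
  # environmental drivers: sulfate significant on axis 1 with the right sign
  et <- env_trend_correlations(sim$env[[2]], m)
  so4 <- et[et$variable == "SO4" & et$axis == 1, ]
  expect_lte(so4$p, 0.05)
  orient <- sign(cor(m$lc_scores[, 1], tr$planted_slow_trend))
  expect_equal(sign(so4$rho), -orient) # sulfate declines as the trend rises
  # a variable equal to the lc scores correlates perfectly
  fake_env <- sim$env[[2]]
  fake_env$values <- cbind(fake_env$values, lc_copy = m$lc_scores[, 1])
  et2 <- env_trend_correlations(fake_env, m)
  expect_equal(et2$rho[et2$variable == "lc_copy" & et2$axis == 1], 1)
})

test_that("generator sulfate/conductivity collinearity is pruned keeping the stronger", {
  sim <- generate_metacommunity(synthetic_config(n_lakes = 8, seed = 5,
                                                 dispersion = 1e-4))
  basis <- temporal_eigenbasis(1988:2007)
  models <- lapply(sim$abundance, fit_temporal_model, basis = basis,
                   n_perm = 199, seed = 4)
  et <- lapply(names(models), function(l)
    env_trend_correlations(sim$env[[l]], models[[l]]))
  names(et) <- names(models)
  M <- assemble_env_matrix(et, 1, collinearity_rho = 0.7, env = sim$env)
  kept <- c("SO4", "cond") %in% colnames(M)
  expect_identical(sum(kept), 1L) # exactly one of the coupled pair survives
  # the stronger trend-correlate is the one kept
  strengths <- sapply(c("SO4", "cond"), function(v) {
    mean(sapply(et, function(tb) {
      r <- tb$rho[tb$variable == v & tb$axis == 1 & tb$p <= 0.05]
      if (length(r)) abs(r) else 0
    }))
  })
  expect_identical(colnames(M)[which(colnames(M) %in% c("SO4", "cond"))],
                   names(which.max(strengths)))
})

test_that("correlation report uses the rho/stars layout", {
  tabs <- list(
    A = data.frame(lake_id = "A", axis = c(1, 2), variable = "SO4",
                   rho = c(-0.8, 0.3), p = c(0.0005, 0.3)),
    B = data.frame(lake_id = "B", axis = 1, variable = "pH",
                   rho = 0.55, p = 0.03)
  )
  rep <- correlation_report(tabs, axes = 1:2)
  expect_identical(rep$A[rep$variable == "SO4"], "-0.80***/ns")
  expect_identical(rep$B[rep$variable == "pH"], "0.55*/ns")
  expect_identical(rep$B[rep$variable == "SO4"], "ns/ns")
})
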