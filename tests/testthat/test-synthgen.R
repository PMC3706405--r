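test_that("a fixed seed reproduces the dataset bit-identically", {
  cf <- synthetic_config(n_lakes = 3, seed = 123)
  s1 <- generate_metacommunity(cf)
  s2 <- generate_metacommunity(cf)
  expect_identical(lapply(s1$abundance, `[[`, "counts"),
                   lapply(s2$abundance, `[[`, "counts"))
  expect_identical(lapply(s1$env, `[[`, "values"),
                   lapply(s2$env, `[[`, "values"))
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$truth, s2$truth)
})

test_that("invalid configuration values are rejected naming the field", {
  expect_error(synthetic_config(n_lakes = 0), "n_lakes")
  expect_error(synthetic_config(fast_period_years = 1), "fast_period_years")
  expect_error(synthetic_config(n_years = 20, fast_period_years = 11),
               "fast_period_years")
  expect_error(synthetic_config(env_coupling = 1.5), "env_coupling")
  expect_error(synthetic_config(dispersion = -0.1), "dispersion")
  expect_error(synthetic_config(mean_abundance = 0), "mean_abundance")
  expect_error(synthetic_config(seed = 1.5), "seed")
})

test_that("counts are nonnegative integers around group intensity curves", {
  sim <- small_sim(n_lakes = 3, seed = 2)
  for (ab in sim$abundance) {
    expect_true(all(ab$counts >= 0))
    expect_true(all(ab$counts == round(ab$counts)))
    expect_identical(dim(ab$counts), c(20L, 30L))
  }
  expect_identical(as.integer(table(sim$truth$group_of_taxon)[c("slow", "fast", "noise")]),
                   c(12L, 8L, 10L))
  # coordinates span a plane with dominant east-west (x) extent
  expect_gt(diff(range(sim$coords$x)), diff(range(sim$coords$y)))
})

test_that("the sulfate-like driver is coupled to the planted slow trend", {
  sim <- generate_metacommunity(synthetic_config(
    n_lakes = 8, seed = 4, env_coupling = 0.9, dispersion = 1e-4))
  rhos <- vapply(sim$env, function(ev) {
    cor(ev$values[, "SO4"], sim$truth$planted_slow_trend, method = "spearman")
  }, numeric(1))
  expect_true(all(abs(rhos) > 0.8))
  expect_true(all(rhos < 0)) # sulfate declines as the slow trend rises
  # conductivity tracks sulfate
  cc <- vapply(sim$env, function(ev) {
    cor(ev$values[, "SO4"], ev$values[, "cond"], method = "spearman")
  }, numeric(1))
  expect_true(all(cc > 0.6))
})

test_that("the fast group's dominant discrete-Fourier period matches the config", {
  sim <- generate_metacommunity(synthetic_config(
    n_lakes = 4, seed = 4, fast_period_years = 5))
  tr <- sim$truth
  fast <- names(tr$group_of_taxon)[tr$group_of_taxon == "fast"]
  for (ab in sim$abundance[1:2]) {
    # response-sign-aware group mean (plain means are signal-free by design)
    wm <- as.vector(ab$counts[, fast] %*% sign(tr$taxon_response[fast]))
    spec <- Mod(fft(wm - mean(wm)))[2:10]^2
    period <- 20 / which.max(spec)
    expect_true(abs(period - 5) <= 20 / 3 - 5 + 1e-9) # within one frequency bin
  }
  # the planted signal itself satisfies the same property
  ps <- Mod(fft(tr$planted_fast_signal))[2:10]^2
  expect_equal(20 / which.max(ps), 5)
})

test_that("as dispersion vanishes taxa track their planted signals", {
  sim <- generate_metacommunity(synthetic_config(
    n_lakes = 3, seed = 6, mean_abundance = 1e5, dispersion = 0))
  tr <- sim$truth
  sig <- cbind(slow = tr$planted_slow_trend, fast = tr$planted_fast_signal)
  ab <- sim$abundance[[2]]
  planted <- names(tr$group_of_taxon)[tr$group_of_taxon != "noise"]
  rr <- vapply(planted, function(tx) {
    abs(cor(ab$counts[, tx], sig[, tr$group_of_taxon[tx]], method = "spearman"))
  }, numeric(1))
  expect_true(all(rr > 0.9))
})

test_that("label shuffling collapses group coherence", {
  sim <- small_sim(n_lakes = 4, seed = 10)
  ab <- sim$abundance[[2]]
  tr <- sim$truth
  grp <- tr$group_of_taxon
  sig <- cbind(slow = tr$planted_slow_trend, fast = tr$planted_fast_signal)
  coherence <- function(labels) {
    mean(vapply(names(labels), function(tx) {
      g <- labels[[tx]]
      if (g == "noise") return(NA_real_)
      abs(cor(ab$counts[, tx], sig[, g], method = "spearman"))
    }, numeric(1)), na.rm = TRUE)
  }
  true_score <- coherence(grp)
  expect_gt(true_score, 0.8)
  set.seed(77)
  shuffled <- replicate(100, coherence(setNames(sample(grp), names(grp))))
  expect_true(all(shuffled < true_score))
  expect_lt(quantile(shuffled, 0.95), 0.65)
})

test_that("the slow trend shape options behave as documented", {
  lin <- generate_metacommunity(synthetic_config(n_lakes = 3, seed = 1,
                                                 slow_trend_shape = "linear"))
  expect_true(all(diff(lin$truth$planted_slow_trend) > 0)) # monotone
  lgs <- generate_metacommunity(synthetic_config(n_lakes = 3, seed = 1,
                                                 slow_trend_shape = "logistic"))
  expect_true(all(diff(lgs$truth$planted_slow_trend) > 0))
  expect_equal(range(lgs$truth$planted_slow_trend), c(-1, 1), tolerance = 0.05)
})

test_that("trait table mixture follows the configured proportions", {
  sim <- generate_metacommunity(synthetic_config(
    n_lakes = 3, n_taxa_slow = 60, n_taxa_fast = 60, n_taxa_noise = 80,
    seed = 14, trait_unknown_prop = 0))
  tr <- sim$traits
  expect_equal(mean(tr$AFS == "low"), 0.85, tolerance = 0.1)
  expect_equal(mean(tr$FD == "high"), 0.6, tolerance = 0.12)
})
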