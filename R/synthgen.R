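#' Configuration for the synthetic metacommunity generator
#'
#' Validated parameter set describing a boreal-lake-style monitoring design:
#' a set of lakes sampled annually, with two planted taxon groups — a slow
#' (decadal, monotone or sigmoid) trend group and a faster cyclic group —
#' plus stationary noise taxa, an east-west compositional gradient confined
#' to the slow group, and a declining sulfate-like driver coupled to the slow
#' trend. Counts are negative-binomial around the intensity curves.
#'
#' @param n_lakes,n_years,n_taxa_slow,n_taxa_fast number of lakes, annual
#'   samples and planted taxa per group (all >= 1).
#' @param n_taxa_noise number of stationary taxa (>= 0).
#' @param fast_period_years period of the fast cycle, in `[2, n_years/2]`.
#' @param slow_trend_shape `"linear"` (monotone ramp) or `"logistic"`
#'   (sigmoid) shape of the slow trend.
#' @param spatial_gradient_strength nonnegative loading of the east-west
#'   (x) coordinate on slow-group composition; 0 removes the gradient.
#' @param env_coupling target absolute correlation of the sulfate-like driver
#'   with the slow trend, in `[0, 1]`.
#' @param mean_abundance baseline expected count per taxon and year.
#' @param dispersion negative-binomial overdispersion coefficient
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param seed integer seed; a fixed seed makes the dataset bit-identical.
#' @param start_year first calendar year.
#' @param fd_high_prop,afs_low_prop,trait_unknown_prop trait-table mixture:
#'   share of genera with high female dispersal, weak adult flying strength,
#'   and entirely unknown traits.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_lakes = 26, n_years = 20, n_taxa_slow = 12,
                             n_taxa_fast = 8, n_taxa_noise = 10,
                             fast_period_years = 5,
                             slow_trend_shape = c("linear", "logistic"),
                             spatial_gradient_strength = 1.5,
                             env_coupling = 0.9, mean_abundance = 400,
                             dispersion = 0.001, seed = 1, start_year = 1988,
                             fd_high_prop = 0.6, afs_low_prop = 0.85,
                             trait_unknown_prop = 0.1) {
  slow_trend_shape <- match.arg(slow_trend_shape)
  chk_count <- function(x, field, min = 1) {
    if (!is_count_scalar(x) || x < min) {
      stop(sprintf("invalid '%s': must be an integer >= %d", field, min))
    }
  }
  chk_count(n_lakes, "n_lakes"); chk_count(n_years, "n_years", 3)
  chk_count(n_taxa_slow, "n_taxa_slow"); chk_count(n_taxa_fast, "n_taxa_fast")
  chk_count(n_taxa_noise, "n_taxa_noise", 0)
  chk_num <- function(x, field, lo = 0, hi = Inf, strict_lo = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
      (if (strict_lo) x > lo else x >= lo) && x <= hi
    if (!ok) stop(sprintf("invalid '%s': must be in %s%g, %g]",
                          field, if (strict_lo) "(" else "[", lo, hi))
  }
  chk_num(fast_period_years, "fast_period_years", 2, n_years / 2)
  chk_num(spatial_gradient_strength, "spatial_gradient_strength")
  chk_num(env_coupling, "env_coupling", 0, 1)
  chk_num(mean_abundance, "mean_abundance", 0, Inf, strict_lo = TRUE)
  chk_num(dispersion, "dispersion")
  chk_num(fd_high_prop, "fd_high_prop", 0, 1)
  chk_num(afs_low_prop, "afs_low_prop", 0, 1)
  chk_num(trait_unknown_prop, "trait_unknown_prop", 0, 1)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed)) {
    stop("invalid 'seed': must be an integer")
  }
  chk_count(start_year, "start_year")
  structure(
    list(n_lakes = n_lakes, n_years = n_years, n_taxa_slow = n_taxa_slow,
         n_taxa_fast = n_taxa_fast, n_taxa_noise = n_taxa_noise,
         fast_period_years = fast_period_years,
         slow_trend_shape = slow_trend_shape,
         spatial_gradient_strength = spatial_gradient_strength,
         env_coupling = env_coupling, mean_abundance = mean_abundance,
         dispersion = dispersion, seed = as.integer(seed),
         start_year = start_year, fd_high_prop = fd_high_prop,
         afs_low_prop = afs_low_prop, trait_unknown_prop = trait_unknown_prop),
    class = "synthetic_config"
  )
}

#' Generate a synthetic metacommunity dataset with planted ground truth
#'
#' Draws per-lake count tables, environmental tables, lake coordinates and a
#' genus-level dispersal-trait table under the design described in
#' [synthetic_config()]. Within each planted group, taxa respond to the group
#' signal in balanced positive/negative pairs (log-linear intensities), so the
#' plain community mean carries no group signal while relative composition
#' does; the signed per-taxon response coefficients are returned in the truth
#' object. The east-west gradient acts on which slow taxa dominate (an
#' exponential weight of taxon spatial preference times lake x-position),
#' not on the trend shape. The sulfate-like driver declines over the series
#' with correlation about `env_coupling` to the slow trend, and conductivity
#' tracks sulfate (correlation about 0.9); remaining variables are
#' uncorrelated noise in realistic ranges.
#'
#' @param config a [synthetic_config()].
#' @return object of class `metacommunity_sim`: list with `abundance` (named
#'   list of [abundance_series()]), `env` (named list of [env_series()]),
#'   `coords` (data frame `lake_id, x, y`), `traits` (data frame
#'   `genus, AFS, FD`), `truth` (planted signals, group and response of each
#'   taxon, spatial loadings), and `config`.
#' @examples
#' sim <- generate_metacommunity(synthetic_config(n_lakes = 4, seed = 7))
#' sim$abundance[[1]]
#' @export
generate_metacommunity <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  with_seed(cf$seed, {
    years <- cf$start_year + seq_len(cf$n_years) - 1L
    t01 <- seq(0, 1, length.out = cf$n_years)
    slow <- switch(cf$slow_trend_shape,
                   linear = 2 * t01 - 1,
                   logistic = 2 / (1 + exp(-8 * (t01 - 0.5))) - 1)
    fast <- sin(2 * pi * (seq_len(cf$n_years) - 1) / cf$fast_period_years)

    ntot <- cf$n_taxa_slow + cf$n_taxa_fast + cf$n_taxa_noise
    genera <- sprintf("Genus%03d", seq_len(ntot))
    taxa <- paste(genera, "sp.")
    group <- rep(c("slow", "fast", "noise"),
                 c(cf$n_taxa_slow, cf$n_taxa_fast, cf$n_taxa_noise))
    names(group) <- taxa

    # balanced +/- response pairs within each planted group
    paired_coefs <- function(k, lo, hi, odd) {
      if (k == 0L) return(numeric(0))
      npair <- k %/% 2L
      mag <- if (npair > 0) seq(lo, hi, length.out = npair) else numeric(0)
      out <- as.vector(rbind(mag, -mag))
      if (k %% 2L == 1L) out <- c(out, odd)
      out
    }
    resp <- numeric(ntot); names(resp) <- taxa
    # the slow (decadal) group responds more strongly than the fast group, so
    # it always carries the leading canonical axis (spatial affinity halves
    # the slow response on average, which these magnitudes anticipate)
    resp[group == "slow"] <- paired_coefs(cf$n_taxa_slow, 0.5, 0.75, 0.3)
    resp[group == "fast"] <- paired_coefs(cf$n_taxa_fast, 0.18, 0.28, 0.12)

    # spatial preference: members of a +/- pair share a preference so the
    # gradient shifts composition, not the community total
    pref <- numeric(ntot); names(pref) <- taxa
    if (cf$n_taxa_slow > 0L) {
      npair <- max(cf$n_taxa_slow %/% 2L, 1L)
      pr <- if (npair > 1) seq(-1, 1, length.out = npair) else 0
      full <- as.vector(rbind(pr, pr))[seq_len(cf$n_taxa_slow)]
      pref[group == "slow"] <- full
    }

    lake_ids <- sprintf("L%02d", seq_len(cf$n_lakes))
    x <- sort(stats::runif(cf$n_lakes, 0, 10)) # dominant east-west extent
    y <- stats::runif(cf$n_lakes, 0, 3)
    loading <- if (diff(range(x)) > 0) 2 * (x - min(x)) / diff(range(x)) - 1 else rep(0, cf$n_lakes)
    names(loading) <- lake_ids
    coords <- data.frame(lake_id = lake_ids, x = x, y = y)

    draw_counts <- function(mu) {
      mu <- pmax(mu, 0.5) # intensity floor: rows rarely all-zero
      if (cf$dispersion <= 1e-12) {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / cf$dispersion)
      }
    }

    signal <- matrix(0, cf$n_years, ntot)
    signal[, group == "slow"] <- slow
    signal[, group == "fast"] <- fast

    abund <- vector("list", cf$n_lakes); names(abund) <- lake_ids
    env <- vector("list", cf$n_lakes); names(env) <- lake_ids
    for (l in seq_len(cf$n_lakes)) {
      w <- exp(cf$spatial_gradient_strength * pref * loading[l])
      w[group != "slow"] <- 1
      w[group == "noise"] <- exp(stats::rnorm(cf$n_taxa_noise, 0, 0.3))
      # the gradient also decides WHICH slow taxa respond to the trend:
      # spatial affinity scales the response amplitude (logistic in x),
      # so regionally distinct responder sets carry the same slow change
      r_eff <- resp
      slow_idx <- group == "slow"
      r_eff[slow_idx] <- resp[slow_idx] *
        stats::plogis(2 * cf$spatial_gradient_strength * pref[slow_idx] * loading[l])
      logmu <- sweep(signal, 2L, r_eff, `*`)
      mu <- cf$mean_abundance * sweep(exp(logmu), 2L, w, `*`)
      cnt <- matrix(draw_counts(mu), cf$n_years, ntot,
                    dimnames = list(years, taxa))
      abund[[l]] <- abundance_series(lake_ids[l], years, cnt)

      slow_z <- as.vector(scale(slow))
      mix <- function(rho, base) rho * base + sqrt(max(1 - rho^2, 0)) * stats::rnorm(cf$n_years)
      so4_z <- mix(cf$env_coupling, -slow_z) # declining sulfate
      cond_z <- mix(0.9, so4_z)              # conductivity tracks sulfate
      vals <- cbind(
        SO4 = pmax(0.25 + 0.08 * so4_z, 0.01),
        cond = pmax(0.05 + 0.012 * cond_z, 0.005),
        pH = 6.2 + 0.4 * stats::rnorm(cf$n_years),
        TOC = pmax(8 + 2 * stats::rnorm(cf$n_years), 0.5),
        Secchi = pmax(3 + stats::rnorm(cf$n_years), 0.3),
        TP = pmax(12 + 4 * stats::rnorm(cf$n_years), 1),
        alkalinity = pmax(0.12 + 0.05 * stats::rnorm(cf$n_years), 0.001),
        NH4N = pmax(15 + 5 * stats::rnorm(cf$n_years), 1),
        temperature = 10 + 1.5 * stats::rnorm(cf$n_years)
      )
      env[[l]] <- env_series(lake_ids[l], years, vals)
    }

    unknown <- stats::runif(ntot) < cf$trait_unknown_prop
    afs <- ifelse(stats::runif(ntot) < cf$afs_low_prop, "low", "high")
    fd <- ifelse(stats::runif(ntot) < cf$fd_high_prop, "high", "low")
    afs[unknown] <- "unknown"; fd[unknown] <- "unknown"
    traits <- data.frame(genus = genera, AFS = afs, FD = fd)

    truth <- list(
      group_of_taxon = group,
      taxon_response = resp,
      taxon_spatial_pref = pref,
      planted_slow_trend = slow,
      planted_fast_signal = fast,
      spatial_loading = loading,
      env_drivers = c("SO4", "cond")
    )
    structure(list(abundance = abund, env = env, coords = coords,
                   traits = traits, truth = truth, config = cf),
              class = "metacommunity_sim")
  })
}

#' @export
print.metacommunity_sim <- function(x, ...) {
  cf <- x$config
  cat(sprintf(paste0("synthetic metacommunity: %d lakes x %d years; ",
                     "%d slow + %d fast + %d noise taxa (seed %d)\n"),
              cf$n_lakes, cf$n_years, cf$n_taxa_slow, cf$n_taxa_fast,
              cf$n_taxa_noise, cf$seed))
  invisible(x)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' One wide abundance CSV and one wide environmental CSV per lake
#' (rows = years), a coordinates CSV (`lake_id,x,y`), a traits CSV
#' (`genus,AFS,FD`) and the ground truth as JSON.
#'
#' @param sim a [metacommunity_sim][generate_metacommunity].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metacommunity <- function(sim, dir) {
  stopifnot(inherits(sim, "metacommunity_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ab in sim$abundance) {
    utils::write.csv(data.frame(year = ab$years, ab$counts, check.names = FALSE),
                     file.path(dir, paste0("abundance_", ab$lake_id, ".csv")),
                     row.names = FALSE)
  }
  for (ev in sim$env) {
    utils::write.csv(data.frame(year = ev$years, ev$values, check.names = FALSE),
                     file.path(dir, paste0("env_", ev$lake_id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(sim$coords, file.path(dir, "coords.csv"), row.names = FALSE)
  utils::write.csv(sim$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
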