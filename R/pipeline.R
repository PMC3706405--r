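#' Pipeline configuration
#'
#' Bundles the inputs and settings for [run_pipeline()]. Exactly one of
#' `synthetic` (a [synthetic_config()] or a list of its arguments) or the
#' four file paths must be supplied. The seed is mandatory: every stochastic
#' stage (permutation tests, synthetic generation) draws from it.
#'
#' @param synthetic a [synthetic_config()] or argument list for one.
#' @param abundance,env path (directory of wide CSVs or long TSV), see
#'   [read_abundance()] / [read_env()].
#' @param coords,traits CSV paths, see [read_coords()] / [read_traits()].
#' @param alpha significance level used throughout.
#' @param n_perm permutations for all tests.
#' @param collinearity_rho environmental collinearity pruning threshold.
#' @param seed integer seed (mandatory).
#' @param out_dir output directory for the report bundle.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, abundance = NULL, env = NULL,
                            coords = NULL, traits = NULL, alpha = 0.05,
                            n_perm = 999, collinearity_rho = 0.7, seed,
                            out_dir) {
  have_paths <- !is.null(abundance)
  if (is.null(synthetic) == !have_paths) {
    stop("supply exactly one of 'synthetic' or the input file paths")
  }
  if (have_paths && (is.null(env) || is.null(coords) || is.null(traits))) {
    stop("file-based input needs 'abundance', 'env', 'coords' and 'traits'")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      seed != round(seed)) {
    stop("'seed' is mandatory and must be an integer")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    synthetic <- do.call(synthetic_config, as.list(synthetic))
  }
  if (missing(out_dir)) stop("'out_dir' is required")
  structure(list(synthetic = synthetic, abundance = abundance, env = env,
                 coords = coords, traits = traits, alpha = alpha,
                 n_perm = n_perm, collinearity_rho = collinearity_rho,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `synthetic`
#' is a mapping of [synthetic_config()] arguments, and file inputs live under
#' `paths: {abundance, env, coords, traits}`.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  paths <- y$paths %||% list()
  pipeline_config(
    synthetic = y$synthetic,
    abundance = paths$abundance, env = paths$env,
    coords = paths$coords, traits = paths$traits,
    alpha = y$alpha %||% 0.05, n_perm = y$n_perm %||% 999,
    collinearity_rho = y$collinearity_rho %||% 0.7,
    seed = y$seed, out_dir = y$out_dir
  )
}

#' Run the full four-step analysis and write a report bundle
#'
#' Executes, in order: per-lake temporal modeling (Step 1), species and
#' environmental trend correlations and matrix assembly (Steps 2-3), spatial
#' eigenfunction selection and variance partitioning per species group
#' (Step 4), and the dispersal-trait comparison. Writes per-lake trend-model
#' files, the correlation report, per-axis correlation matrices, the
#' partition table, the trait summary, a machine-readable manifest and an
#' append-only stage log to `config$out_dir`. With a fixed seed the bundle is
#' byte-identical across runs. When no lake has a significant temporal axis
#' the partition and trait stages are skipped with a notice in the log.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the fitted objects (`models`, `taxa_tables`,
#'   `env_tables`, `species_matrices`, `env_matrices`, `spatial`,
#'   `partitions`, `trait_props`, `trait_tests`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out, "pipeline.log")
  if (file.exists(logfile)) unlink(logfile)
  logln <- function(...) cat(sprintf(...), "\n", sep = "", file = logfile,
                             append = TRUE)
  stage <- function(name, lake, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed for '%s': %s",
                   name, lake, conditionMessage(e)), call. = FALSE)
    })
  }

  with_seed(config$seed, {
    # ---- inputs ------------------------------------------------------------
    if (!is.null(config$synthetic)) {
      sim <- generate_metacommunity(config$synthetic)
      abund <- sim$abundance; env <- sim$env
      coords <- sim$coords; traits <- sim$traits
      write_metacommunity(sim, file.path(out, "input"))
      logln("stage=input mode=synthetic lakes=%d years=%d taxa=%d",
            length(abund), length(abund[[1]]$years), ncol(abund[[1]]$counts))
    } else {
      abund <- stage("read", config$abundance, read_abundance(config$abundance))
      env <- stage("read", config$env, read_env(config$env))
      coords <- stage("read", config$coords, read_coords(config$coords))
      traits <- stage("read", config$traits, read_traits(config$traits))
      logln("stage=input mode=files lakes=%d", length(abund))
    }
    lakes <- names(abund)

    # ---- step 1: temporal models -------------------------------------------
    models <- list()
    for (l in lakes) {
      models[[l]] <- stage("temporal", l, {
        basis <- temporal_eigenbasis(abund[[l]]$years)
        m <- fit_temporal_model(abund[[l]], basis, alpha = config$alpha,
                                n_perm = config$n_perm)
        write_trend_model(m, file.path(out, "trends"))
        logln("stage=temporal lake=%s years=%d taxa=%d selected=%d sig_axes=%d",
              l, length(abund[[l]]$years), ncol(abund[[l]]$counts),
              length(m$selected), m$n_significant)
        m
      })
    }
    n_axes <- max(vapply(models, function(m) m$n_significant, integer(1)))

    bundle <- list(models = models, out_dir = out)
    if (n_axes == 0L) {
      logln("stage=partition status=skipped reason=no significant temporal axes")
      write_manifest(config, out, lakes, n_axes)
      return(invisible(bundle))
    }

    # ---- steps 2-3: correlation tables and matrices ------------------------
    with_sig <- lakes[vapply(models, function(m) m$n_significant > 0L, TRUE)]
    taxa_tabs <- lapply(with_sig, function(l) stage("species-correlations", l, {
      tb <- taxa_trend_correlations(abund[[l]], models[[l]])
      logln("stage=species-correlations lake=%s rows=%d", l, nrow(tb))
      tb
    }))
    names(taxa_tabs) <- with_sig
    env_tabs <- lapply(with_sig, function(l) stage("env-correlations", l, {
      tb <- env_trend_correlations(env[[l]], models[[l]])
      logln("stage=env-correlations lake=%s rows=%d", l, nrow(tb))
      tb
    }))
    names(env_tabs) <- with_sig

    rep_env <- correlation_report(env_tabs, axes = seq_len(min(n_axes, 2L)),
                                  alpha = config$alpha)
    utils::write.table(rep_env, file.path(out, "env_correlations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    spe_mats <- list(); env_mats <- list(); spatial <- list(); parts <- list()
    for (k in seq_len(n_axes)) {
      gname <- paste0("group", k)
      spe_mats[[gname]] <- stage("species-matrix", gname, {
        M <- assemble_species_matrix(taxa_tabs, k, alpha = config$alpha)
        write_correlation_matrix(M, file.path(out, paste0("species_matrix_axis", k, ".csv")))
        logln("stage=species-matrix axis=%d lakes=%d taxa=%d", k, nrow(M), ncol(M))
        M
      })
      env_mats[[gname]] <- stage("env-matrix", gname, {
        M <- assemble_env_matrix(env_tabs, k, alpha = config$alpha,
                                 collinearity_rho = config$collinearity_rho,
                                 env = env[with_sig])
        write_correlation_matrix(M, file.path(out, paste0("env_matrix_axis", k, ".csv")))
        logln("stage=env-matrix axis=%d lakes=%d variables=%d", k, nrow(M), ncol(M))
        M
      })

      # ---- step 4: spatial selection + variance partitioning ---------------
      Yk <- spe_mats[[gname]]
      ck <- coords[match(rownames(Yk), coords$lake_id), , drop = FALSE]
      spatial[[gname]] <- stage("spatial-selection", gname, {
        S <- spatial_predictors(Yk, ck, alpha = config$alpha,
                                n_perm = config$n_perm)
        logln("stage=spatial-selection axis=%d selected=%d", k, ncol(S))
        S
      })
      parts[[gname]] <- stage("partition", gname, {
        p <- variance_partition(Yk, env_mats[[gname]], spatial[[gname]],
                                n_perm = config$n_perm)
        logln("stage=partition axis=%d pure_space=%.4f pure_env=%.4f residual=%.4f",
              k, p$fractions["pure_space"], p$fractions["pure_environment"],
              p$fractions["residual"])
        p
      })
    }
    write_partition(parts, file.path(out, "variance_partition.tsv"))

    # ---- dispersal traits ---------------------------------------------------
    props <- stage("traits", "all", {
      pr <- suppressWarnings(group_trait_proportions(spe_mats, traits))
      write_trait_summary(pr, file.path(out, "trait_summary.tsv"))
      logln("stage=traits lake_groups=%d", nrow(pr$per_lake))
      pr
    })
    trait_tests <- NULL
    if (n_axes >= 2L) {
      trait_tests <- stage("trait-comparison", "group1 vs group2", {
        pl <- props$per_lake
        rows <- list()
        for (tr in unique(pl$trait)) for (cl in unique(pl$class)) {
          p1 <- pl$pct[pl$group == "group1" & pl$trait == tr & pl$class == cl] / 100
          p2 <- pl$pct[pl$group == "group2" & pl$trait == tr & pl$class == cl] / 100
          if (length(p1) < 2L || length(p2) < 2L) next
          cmp <- compare_trait_groups(p1, p2)
          rows[[length(rows) + 1L]] <- data.frame(
            trait = tr, class = cl, F = cmp$F, p = cmp$p)
        }
        tt <- if (length(rows)) do.call(rbind, rows) else NULL
        if (!is.null(tt)) {
          utils::write.table(tt, file.path(out, "trait_anova.tsv"), sep = "\t",
                             row.names = FALSE, quote = FALSE)
        }
        logln("stage=trait-comparison tests=%d", length(rows))
        tt
      })
    }

    write_manifest(config, out, lakes, n_axes)
    bundle <- list(models = models, taxa_tables = taxa_tabs,
                   env_tables = env_tabs, species_matrices = spe_mats,
                   env_matrices = env_mats, spatial = spatial,
                   partitions = parts, trait_props = props,
                   trait_tests = trait_tests, out_dir = out)
    invisible(bundle)
  })
}

write_manifest <- function(config, out, lakes, n_axes) {
  manifest <- list(
    package = "metascale",
    version = as.character(utils::packageVersion("metascale")),
    seed = config$seed, alpha = config$alpha, n_perm = config$n_perm,
    collinearity_rho = config$collinearity_rho,
    input_mode = if (is.null(config$synthetic)) "files" else "synthetic",
    n_lakes = length(lakes), n_species_groups = n_axes
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
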