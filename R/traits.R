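#' Genus of a taxon label
#'
#' The first whitespace-separated token of the taxon label, the key into the
#' genus-level dispersal-trait table.
#'
#' @param taxa character vector of taxon labels (e.g. `"Caenis luctuosa"`).
#' @return character vector of genus names.
#' @export
taxon_genus <- function(taxa) {
  vapply(strsplit(as.character(taxa), "\\s+"), `[[`, character(1), 1L)
}

#' Dispersal-trait composition of species groups
#'
#' For each lake and species group, the percentage of group-contributing taxa
#' (the nonzero columns of the lake's row in the group's correlation matrix)
#' in each class of the dispersal traits AFS (adult flying strength) and FD
#' (female dispersal distance). Percentages are computed over classified taxa
#' only; genera missing from the trait table or recorded as `unknown` are
#' counted and reported as excluded, never coerced. Lakes with no classified
#' taxon for a trait are omitted from that trait's summary with a warning.
#'
#' @param groups named list of [correlation_matrix][assemble_species_matrix]
#'   objects, one per species group (e.g. `list(group1 = ..., group2 = ...)`),
#'   or a single matrix.
#' @param traits data frame with columns `genus`, `AFS`, `FD`; levels `low`,
#'   `high`, `unknown`.
#' @return list with `per_lake` (data frame: group, lake_id, trait, class,
#'   pct, n_classified, n_excluded) and `summary` (data frame: group, trait,
#'   class, mean_pct, sd_pct, n_lakes).
#' @export
group_trait_proportions <- function(groups, traits) {
  if (is.matrix(groups)) groups <- list(group1 = groups)
  stopifnot(is.list(groups), all(c("genus", "AFS", "FD") %in% names(traits)))
  per <- list()
  omitted <- character(0)
  for (g in names(groups)) {
    M <- groups[[g]]
    for (l in rownames(M)) {
      taxa <- colnames(M)[M[l, ] > 0]
      if (length(taxa) == 0L) next
      gen <- taxon_genus(taxa)
      hit <- match(gen, traits$genus)
      for (tr in c("AFS", "FD")) {
        cls <- ifelse(is.na(hit), "unknown", as.character(traits[[tr]][hit]))
        known <- cls[cls %in% c("low", "high")]
        n_exc <- sum(!cls %in% c("low", "high"))
        if (length(known) == 0L) {
          omitted <- c(omitted, sprintf("%s/%s/%s", g, l, tr))
          next
        }
        for (level in c("low", "high")) {
          per[[length(per) + 1L]] <- data.frame(
            group = g, lake_id = l, trait = tr, class = level,
            pct = 100 * mean(known == level),
            n_classified = length(known), n_excluded = n_exc)
        }
      }
    }
  }
  if (length(omitted)) {
    warning("lake-groups omitted (no classified taxa): ",
            paste(omitted, collapse = ", "))
  }
  per_lake <- if (length(per)) do.call(rbind, per) else
    data.frame(group = character(0), lake_id = character(0),
               trait = character(0), class = character(0), pct = numeric(0),
               n_classified = integer(0), n_excluded = integer(0))
  summ <- NULL
  if (nrow(per_lake)) {
    agg <- split(per_lake, list(per_lake$group, per_lake$trait, per_lake$class),
                 drop = TRUE)
    summ <- do.call(rbind, lapply(agg, function(d) data.frame(
      group = d$group[1], trait = d$trait[1], class = d$class[1],
      mean_pct = mean(d$pct), sd_pct = stats::sd(d$pct), n_lakes = nrow(d))))
    summ <- summ[order(summ$group, summ$trait, summ$class), ]
    rownames(summ) <- NULL
  }
  list(per_lake = per_lake, summary = summ)
}

#' Compare a trait-class proportion between two species groups
#'
#' One-way ANOVA on arcsine-square-root-transformed per-lake proportions,
#' the conventional variance-stabilizing analysis for percentage data.
#'
#' @param props_group1,props_group2 numeric vectors of per-lake proportions
#'   in \[0, 1\] (at least 2 lakes each).
#' @return list with `F`, `p`, `df` (between, within degrees of freedom).
#' @examples
#' compare_trait_groups(c(0.8, 0.7, 0.75), c(0.6, 0.65, 0.7))
#' @export
compare_trait_groups <- function(props_group1, props_group2) {
  chk <- function(p, nm) {
    if (!is.numeric(p) || length(p) < 2L) stop("'", nm, "' needs >= 2 lakes")
    if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
      stop("proportion outside [0, 1] in '", nm, "'")
    }
  }
  chk(props_group1, "props_group1"); chk(props_group2, "props_group2")
  y <- asin(sqrt(c(props_group1, props_group2)))
  g <- factor(rep(c("g1", "g2"), c(length(props_group1), length(props_group2))))
  n <- length(y)
  ybar <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (ybar - mean(y))^2)
  ssw <- sum((y - ybar[g])^2)
  df1 <- 1L
  df2 <- n - 2L
  if (ssw <= .Machine$double.eps * max(ssb, 1)) {
    # no within-group variance: identical vectors give F = 0, p = 1
    if (ssb <= .Machine$double.eps) return(list(F = 0, p = 1, df = c(df1, df2)))
    return(list(F = Inf, p = 0, df = c(df1, df2)))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE), df = c(df1, df2))
}

#' Trait summary report
#'
#' Writes the trait composition summary as TSV (trait class by group:
#' mean and SD of per-lake percentages).
#'
#' @param props output of [group_trait_proportions()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trait_summary <- function(props, path) {
  s <- props$summary
  if (is.null(s)) s <- data.frame()
  utils::write.table(s, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
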