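## Engram reactivation quantification from per-region cell counts:
## density-extrapolated totals, c-Fos rates, EYFP+ -> c-Fos+ reactivation
## proportions, group comparisons with BH-FDR, behavior correlations.

.regionCountCols <- c("mouse", "group", "region", "dapi_density",
                      "region_area", "n_images", "n_eyfp", "n_cfos",
                      "n_double")

#' Validate a region-counts table
#'
#' Checks the per-mouse, per-region cell-count schema: columns `mouse`,
#' `group`, `region`, `dapi_density` (cells/µm²), `region_area` (µm²),
#' `n_images`, `n_eyfp`, `n_cfos`, `n_double`. Hard invariants (counts
#' non-negative, `n_double <= min(n_eyfp, n_cfos)`, positive densities
#' and areas) raise errors; fewer than 4 sampled images per region only
#' warns (the recommended sampling floor).
#'
#' @param df a data.frame.
#' @return `df`, invisibly, after validation.
#' @export
validateRegionCounts <- function(df) {
  missing <- setdiff(.regionCountCols, names(df))
  if (length(missing))
    stop(sprintf("region-counts table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (any(df$dapi_density <= 0) || any(df$region_area <= 0))
    stop("densities and areas must be positive")
  if (any(df$n_eyfp < 0 | df$n_cfos < 0 | df$n_double < 0))
    stop("counts must be non-negative")
  if (any(df$n_double > pmin(df$n_eyfp, df$n_cfos)))
    stop("n_double must not exceed min(n_eyfp, n_cfos)")
  if (any(df$n_images < 4))
    warning("fewer than 4 images sampled for some mouse x region cells")
  invisible(df)
}

#' Read a region-counts CSV
#'
#' @param path CSV path with the [validateRegionCounts()] schema.
#' @param regionOntology optional character vector of admissible region
#'   names; unknown names raise an error.
#' @return validated data.frame.
#' @export
readRegionCounts <- function(path, regionOntology = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validateRegionCounts(df)
  if (!is.null(regionOntology)) {
    bad <- setdiff(unique(df$region), regionOntology)
    if (length(bad))
      stop(sprintf("unknown region name(s): %s", paste(bad, collapse = ", ")))
  }
  df
}

#' Density-extrapolated total cell count
#'
#' Total cells in a region = sampled DAPI density (cells/µm²) times the
#' total counted area (µm²). The product is kept real-valued; rounding
#' happens only at report time so downstream rates are unbiased.
#'
#' @param dapiDensity cells/µm², positive.
#' @param regionArea µm², positive.
#' @return estimated cell count (numeric, not rounded).
#' @examples
#' estimateTotalCells(0.001, 1e6)  # 1000
#' @export
estimateTotalCells <- function(dapiDensity, regionArea) {
  if (any(dapiDensity <= 0) || any(regionArea < 0))
    stop("density must be positive and area non-negative")
  dapiDensity * regionArea
}

#' c-Fos expression rate
#'
#' Fraction of the density-extrapolated total cell population expressing
#' c-Fos. With `perArea = TRUE` the alternative per-area density
#' (c-Fos cells per µm²) is returned instead.
#'
#' @param rc one row (or vectorized columns) of a region-counts table.
#' @param perArea report cells/µm² instead of a fraction.
#' @return fraction in \[0, 1\] (or density).
#' @export
cfosRate <- function(rc, perArea = FALSE) {
  total <- estimateTotalCells(rc$dapi_density, rc$region_area)
  if (perArea) return(rc$n_cfos / rc$region_area)
  if (any(total <= 0)) stop("total cell estimate must be positive")
  rc$n_cfos / total
}

#' Engram reactivation fraction
#'
#' Proportion of initially tagged EYFP+ cells that also express c-Fos
#' after the second experience: `n_double / n_eyfp`. With
#' `normalized = TRUE` the fraction is divided by the overall c-Fos
#' rate, giving fold-over-chance reactivation — an optional derived
#' measure, not part of the standard group comparison.
#'
#' @param rc region-counts row(s) with `n_eyfp > 0`.
#' @param normalized divide by [cfosRate()] (fold over chance).
#' @return fraction in \[0, 1\] (or fold change when normalized).
#' @export
reactivationFraction <- function(rc, normalized = FALSE) {
  if (any(rc$n_eyfp == 0))
    stop("reactivation undefined when no EYFP+ cells were tagged")
  frac <- rc$n_double / rc$n_eyfp
  if (normalized) frac <- frac / cfosRate(rc)
  frac
}

#' Per-mouse, per-region reactivation table
#'
#' Derives `total_cells`, `cfos_rate` and `reactivation` for every row
#' of a validated region-counts table.
#'
#' @param counts a validated region-counts data.frame.
#' @return the input with the three derived columns appended.
#' @export
reactivationTable <- function(counts) {
  validateRegionCounts(counts)
  counts$total_cells <- estimateTotalCells(counts$dapi_density,
                                           counts$region_area)
  counts$cfos_rate <- counts$n_cfos / counts$total_cells
  counts$reactivation <- ifelse(counts$n_eyfp > 0,
                                counts$n_double / counts$n_eyfp, NA_real_)
  counts
}

#' Region-wise group comparison with BH-FDR
#'
#' For each region, compares `value` between groups: an unpaired
#' Student t test for two groups, a one-way ANOVA for three or more.
#' q values are BH-adjusted across the region family of one contrast
#' (matching the convention of reporting one FDR family per figure
#' panel). Regions with a singleton group are skipped with a warning.
#'
#' @param tab a data.frame as from [reactivationTable()].
#' @param value column to compare (default `"reactivation"`).
#' @param groups optional subset/order of group labels.
#' @return data.frame: `region`, `test`, `n`, `statistic`, `df`, `p`,
#'   `q`.
#' @export
compareRegions <- function(tab, value = "reactivation", groups = NULL) {
  if (!value %in% names(tab)) stop(sprintf("no column '%s'", value))
  if (is.null(groups)) groups <- unique(tab$group)
  tab <- tab[tab$group %in% groups & !is.na(tab[[value]]), , drop = FALSE]
  out <- list()
  for (rg in unique(tab$region)) {
    sub <- tab[tab$region == rg, , drop = FALSE]
    sizes <- table(factor(sub$group, levels = groups))
    if (any(sizes < 2)) {
      warning(sprintf("region %s skipped: singleton or empty group", rg))
      next
    }
    if (length(groups) == 2) {
      res <- tTest(sub[[value]][sub$group == groups[1]],
                   sub[[value]][sub$group == groups[2]], paired = FALSE)
      out[[rg]] <- data.frame(region = rg, test = res@method,
                              n = nrow(sub), statistic = res@statistic,
                              df = paste(signif(res@df, 6), collapse = ","),
                              p = res@p)
    } else {
      fit <- aov(v ~ g, data = data.frame(v = sub[[value]],
                                          g = factor(sub$group)))
      s <- summary(fit)[[1]]
      out[[rg]] <- data.frame(region = rg, test = "one-way ANOVA",
                              n = nrow(sub), statistic = s["g", "F value"],
                              df = paste(s[, "Df"], collapse = ","),
                              p = s["g", "Pr(>F)"])
    }
  }
  if (!length(out)) stop("no region had enough mice per group")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$q <- bhFDR(res$p)
  res
}

#' Region x behavior Pearson correlation matrix
#'
#' Pairs each mouse's per-region value (reactivation by default) with a
#' per-mouse behavioral measure (time spent freezing, top speed) and
#' reports Pearson r and p per region. Cells with fewer than 3 paired
#' mice are reported as `NA`.
#'
#' @param tab a data.frame as from [reactivationTable()].
#' @param behavior data.frame with columns `mouse` and one column per
#'   behavioral measure.
#' @param value region-level column to correlate.
#' @return data.frame: `region`, `behavior`, `n`, `r`, `p`.
#' @export
correlateWithBehavior <- function(tab, behavior, value = "reactivation") {
  measures <- setdiff(names(behavior), "mouse")
  if (!length(measures)) stop("behavior table has no measure columns")
  out <- list()
  for (rg in unique(tab$region)) {
    sub <- merge(tab[tab$region == rg, c("mouse", value)], behavior,
                 by = "mouse")
    for (ms in measures) {
      ok <- complete.cases(sub[[value]], sub[[ms]])
      n <- sum(ok)
      if (n >= 3 && sd(sub[[value]][ok]) > 0 && sd(sub[[ms]][ok]) > 0) {
        pc <- pearsonCor(sub[[value]][ok], sub[[ms]][ok])
        row <- data.frame(region = rg, behavior = ms, n = n, r = pc$r,
                          p = pc$p)
      } else {
        row <- data.frame(region = rg, behavior = ms, n = n, r = NA_real_,
                          p = NA_real_)
      }
      out[[paste(rg, ms)]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
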