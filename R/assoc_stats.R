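# Association analyses: phenotype vs fluorescence correlations by
# generation grouping, sister-pair differences, dividing vs non-dividing
# comparisons, and cross-experiment summary tests.

#' Per-cell phenotype table
#'
#' One row per cell with the three phenotypes the correlations use: the
#' cell-profile area and circularity measured at the cell's final
#' fluorescence frame (the same frame that defines Fa), and the mean
#' migration velocity over the cell's centroid track.
#'
#' @param forest A [lineage_forest()].
#' @param interval Velocity grid spacing, hours.
#' @param cell_type,condition Restrict to these cells.
#' @param exclude_short_tracks Drop velocities from tracks spanning less
#'   than one grid interval.
#' @return Data frame: `cell_id`, `generation`, `area`, `circularity`,
#'   `velocity`.
#' @export
cell_phenotypes <- function(forest, interval = 2, cell_type = "SAOS-2",
                            condition = "co-culture",
                            exclude_short_tracks = FALSE) {
  cells <- forest$cells
  keep <- cells$cell_type == cell_type & cells$condition == condition
  cells <- cells[keep, , drop = FALSE]
  vel <- migration_velocities(forest, interval, cell_type, condition)
  if (exclude_short_tracks)
    vel$velocity_um_per_day[vel$short_track] <- NA_real_
  shape <- lapply(cells$cell_id, function(id) {
    o <- cell_obs(forest, id)
    o <- o[o$frame_kind == "fluorescence" & !is.na(o$area_um2), , drop = FALSE]
    if (nrow(o) == 0L)
      return(data.frame(cell_id = id, area = NA_real_,
                        circularity = NA_real_, stringsAsFactors = FALSE))
    last <- o[nrow(o), ]
    data.frame(cell_id = id, area = last$area_um2,
               circularity = last$circularity, stringsAsFactors = FALSE)
  })
  shape <- do.call(rbind, shape)
  out <- merge(data.frame(cell_id = cells$cell_id,
                          generation = cells$generation,
                          stringsAsFactors = FALSE),
               shape, by = "cell_id")
  out <- merge(out, vel[, c("cell_id", "velocity_um_per_day")], by = "cell_id")
  names(out)[names(out) == "velocity_um_per_day"] <- "velocity"
  out[order(out$cell_id), , drop = FALSE]
}

# Generation groupings: each generation alone, cumulative prefixes, all.
generation_groupings <- function(gens) {
  gens <- sort(unique(gens))
  gr <- list()
  for (g in gens) gr[[paste0("gen-", g)]] <- g
  if (length(gens) > 1L)
    for (k in 2:length(gens))
      gr[[paste0("cumulative-", gens[k])]] <- gens[1:k]
  gr[["all"]] <- gens
  gr
}

#' Correlate a phenotype with fluorescence by generation groupings
#'
#' Kendall's tau-b between one phenotype and one fluorescence measure, for
#' each generation alone, for sequentially added generations (0+1, 0+1+2,
#' ...), and for all generations together.  Groupings with fewer than 5
#' complete cells are computed but flagged `low_n`; cells with missing
#' values are excluded and counted.
#'
#' @param forest A normalized [lineage_forest()].
#' @param accounts Output of [fluorescence_accounts()].
#' @param phenotype `"area"`, `"circularity"` or `"velocity"`.
#' @param fluorescence_kind `"Fa"` or `"Fmc"`.
#' @param phenotypes Optional precomputed [cell_phenotypes()] table.
#' @return Data frame of correlation results: `experiment_id`, `phenotype`,
#'   `fluorescence_kind`, `grouping`, `generations`, `n`, `tau`, `p_value`,
#'   `low_n`; attribute `n_excluded` counts incomplete cells.
#' @export
correlate_by_generations <- function(forest, accounts,
                                     phenotype = c("area", "circularity", "velocity"),
                                     fluorescence_kind = c("Fa", "Fmc"),
                                     phenotypes = NULL) {
  phenotype <- match.arg(phenotype)
  fluorescence_kind <- match.arg(fluorescence_kind)
  if (is.null(phenotypes)) phenotypes <- cell_phenotypes(forest)
  d <- merge(accounts[, c("cell_id", "generation", "Fa", "Fmc")],
             phenotypes[, c("cell_id", phenotype)], by = "cell_id")
  d$fl <- d[[fluorescence_kind]]
  d$ph <- d[[phenotype]]
  d <- d[is.finite(d$fl) & is.finite(d$ph), , drop = FALSE]
  n_excluded <- nrow(accounts) - nrow(d)
  empty <- data.frame(experiment_id = character(), phenotype = character(),
                      fluorescence_kind = character(), grouping = character(),
                      generations = character(), n = integer(),
                      tau = numeric(), p_value = numeric(), low_n = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(d) == 0L) {
    message("no eligible cells for ", phenotype, " vs ", fluorescence_kind,
            " in experiment ", forest$experiment_id)
    attr(empty, "n_excluded") <- n_excluded
    return(empty)
  }
  groupings <- generation_groupings(d$generation)
  rows <- lapply(names(groupings), function(gname) {
    gens <- groupings[[gname]]
    sub <- d[d$generation %in% gens, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) {
      tau <- NA_real_; p <- NA_real_
    } else {
      kt <- suppressWarnings(kendall_tau(sub$fl, sub$ph))
      tau <- kt$tau; p <- kt$p_value
    }
    data.frame(experiment_id = forest$experiment_id, phenotype = phenotype,
               fluorescence_kind = fluorescence_kind, grouping = gname,
               generations = paste(gens, collapse = "+"), n = n,
               tau = tau, p_value = p, low_n = n < 5L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Sister-pair differences in fluorescence and phenotype
#'
#' For every sister pair where both cells have the needed measures, orders
#' the sisters so the within-pair Fa difference is non-negative (cell_id
#' order breaks exact ties), and correlates the Fa difference with the
#' correspondingly signed phenotype difference by generation grouping.
#'
#' @param forest A normalized [lineage_forest()].
#' @param accounts Output of [fluorescence_accounts()].
#' @param phenotype `"area"`, `"circularity"` or `"velocity"`.
#' @param phenotypes Optional precomputed [cell_phenotypes()] table.
#' @return List with `pairs` (per-pair `dFa`, `dphenotype`, `generation`)
#'   and `correlations` (Kendall tau-b per generation grouping).  When
#'   fewer than 3 eligible pairs exist, `correlations` is empty and the
#'   result carries `insufficient = TRUE`.
#' @export
sister_pair_differences <- function(forest, accounts,
                                    phenotype = c("area", "circularity", "velocity"),
                                    phenotypes = NULL) {
  phenotype <- match.arg(phenotype)
  if (is.null(phenotypes)) phenotypes <- cell_phenotypes(forest)
  pairs <- sister_pairs(forest)
  d <- merge(accounts[, c("cell_id", "generation", "Fa")],
             phenotypes[, c("cell_id", phenotype)], by = "cell_id")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- d[d$cell_id == pairs$cell_id_1[i], , drop = FALSE]
    b <- d[d$cell_id == pairs$cell_id_2[i], , drop = FALSE]
    if (nrow(a) != 1L || nrow(b) != 1L) return(NULL)
    if (!is.finite(a$Fa) || !is.finite(b$Fa) ||
        !is.finite(a[[phenotype]]) || !is.finite(b[[phenotype]])) return(NULL)
    # order by descending Fa; canonical cell_id order on exact ties
    if (b$Fa > a$Fa) { tmp <- a; a <- b; b <- tmp }
    data.frame(mother_id = pairs$mother_id[i], generation = a$generation,
               dFa = a$Fa - b$Fa, dphenotype = a[[phenotype]] - b[[phenotype]],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  pair_df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(mother_id = character(), generation = integer(),
               dFa = numeric(), dphenotype = numeric(), stringsAsFactors = FALSE)
  if (nrow(pair_df) < 3L) {
    return(list(pairs = pair_df,
                correlations = data.frame(), insufficient = TRUE))
  }
  groupings <- generation_groupings(pair_df$generation)
  cors <- lapply(names(groupings), function(gname) {
    sub <- pair_df[pair_df$generation %in% groupings[[gname]], , drop = FALSE]
    if (nrow(sub) < 2L)
      return(data.frame(experiment_id = forest$experiment_id,
                        phenotype = phenotype, grouping = gname,
                        n = nrow(sub), tau = NA_real_, p_value = NA_real_,
                        low_n = TRUE, stringsAsFactors = FALSE))
    kt <- suppressWarnings(kendall_tau(sub$dFa, sub$dphenotype))
    data.frame(experiment_id = forest$experiment_id, phenotype = phenotype,
               grouping = gname, n = nrow(sub), tau = kt$tau,
               p_value = kt$p_value, low_n = nrow(sub) < 5L,
               stringsAsFactors = FALSE)
  })
  list(pairs = pair_df, correlations = do.call(rbind, cors),
       insufficient = FALSE)
}

#' Compare fluorescence uptake rates of dividing vs non-dividing cells
#'
#' Medians of Fa/day and Fmc/day in cells that divided versus cells that
#' did not, their ratios pFa and pFmc (dividing over non-dividing), and
#' two-sided Mann-Whitney p-values.  Cells with fate "incomplete-division"
#' count as non-dividing by default (no daughters exist to inherit
#' anything).  Cells observed for less than the experiment's median
#' intermitotic time can be excluded (they had insufficient time to
#' divide), as can whole generations.
#'
#' @param forest A normalized [lineage_forest()].
#' @param accounts Output of [fluorescence_accounts()].
#' @param exclude_generations Integer vector of generations to drop.
#' @param min_window_policy `"median-intermitotic"` (drop non-dividing
#'   cells observed for less than the experiment's median intermitotic
#'   time) or `"none"`.
#' @param incomplete_division `"non-dividing"` (default) or `"dividing"`.
#' @return List: `experiment_id`, per-kind medians, `pFa`, `pFmc`,
#'   `p_Fa`, `p_Fmc`, group sizes `n_dividing`, `n_nondividing`.
#' @export
compare_dividing_vs_nondividing <- function(forest, accounts,
                                            exclude_generations = integer(),
                                            min_window_policy = c("median-intermitotic", "none"),
                                            incomplete_division = c("non-dividing", "dividing")) {
  min_window_policy <- match.arg(min_window_policy)
  incomplete_division <- match.arg(incomplete_division)
  d <- accounts[is.finite(accounts$Fa_rate) & is.finite(accounts$Fmc_rate), ,
                drop = FALSE]
  d <- d[!d$generation %in% exclude_generations, , drop = FALSE]
  dividing_fates <- "divided"
  if (incomplete_division == "dividing")
    dividing_fates <- c("divided", "incomplete-division")
  d$dividing <- d$fate %in% dividing_fates
  if (min_window_policy == "median-intermitotic") {
    cells <- forest$cells
    imt <- cells$end_time_h - cells$birth_time_h
    imt <- imt[cells$fate == "divided" & !is.na(imt)]
    if (length(imt) > 0L) {
      min_days <- stats::median(imt) / 24
      d <- d[d$dividing | d$observation_days >= min_days, , drop = FALSE]
    }
  }
  n_div <- sum(d$dividing); n_non <- sum(!d$dividing)
  if (n_div == 0L || n_non == 0L)
    stop("comparison-undefined: ",
         if (n_div == 0L) "no dividing cells" else "no non-dividing cells",
         " after exclusions")
  med <- function(v, g) stats::median(v[g])
  mw <- function(v) suppressWarnings(
    stats::wilcox.test(v[d$dividing], v[!d$dividing])$p.value)
  fa_div <- med(d$Fa_rate, d$dividing); fa_non <- med(d$Fa_rate, !d$dividing)
  fmc_div <- med(d$Fmc_rate, d$dividing); fmc_non <- med(d$Fmc_rate, !d$dividing)
  list(experiment_id = forest$experiment_id,
       median_Fa_rate_dividing = fa_div, median_Fa_rate_nondividing = fa_non,
       median_Fmc_rate_dividing = fmc_div,
       median_Fmc_rate_nondividing = fmc_non,
       pFa = fa_div / fa_non, pFmc = fmc_div / fmc_non,
       p_Fa = mw(d$Fa_rate), p_Fmc = mw(d$Fmc_rate),
       n_dividing = n_div, n_nondividing = n_non)
}

#' Cross-experiment summary test
#'
#' Median of per-experiment statistics with a nonparametric test: the
#' one-sample Wilcoxon test against 0 (e.g. divergence of Kendall's tau
#' from no correlation), the paired Wilcoxon signed-rank test, or the
#' Mann-Whitney U test for unpaired groups.  Exact distributions are used
#' for n <= 25 without ties or zeros; otherwise the normal approximation.
#'
#' @param values Numeric vector of per-experiment statistics (first group).
#' @param test `"one-sample-wilcoxon-vs-0"`, `"wilcoxon-signed-rank-paired"`
#'   or `"mann-whitney"`.
#' @param values2 Second vector for paired/unpaired two-sample tests.
#' @return List: `median` (of `values`), `p_value`, `n`.
#' @export
cross_experiment_summary <- function(values,
                                     test = c("one-sample-wilcoxon-vs-0",
                                              "wilcoxon-signed-rank-paired",
                                              "mann-whitney"),
                                     values2 = NULL) {
  test <- match.arg(test)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("parameter error: at least 3 values required")
  exact_ok <- function(v) length(v) <= 25 && !any(duplicated(abs(v))) &&
    !any(v == 0)
  p <- switch(test,
    "one-sample-wilcoxon-vs-0" = {
      if (all(values == 0)) stop("undefined: all values are zero")
      suppressWarnings(stats::wilcox.test(values, mu = 0,
                                          exact = exact_ok(values))$p.value)
    },
    "wilcoxon-signed-rank-paired" = {
      stopifnot(!is.null(values2), length(values2) == n)
      dd <- values - values2
      if (all(dd == 0)) stop("undefined: all paired differences are zero")
      suppressWarnings(stats::wilcox.test(values, values2, paired = TRUE,
                                          exact = exact_ok(dd))$p.value)
    },
    "mann-whitney" = {
      stopifnot(!is.null(values2))
      suppressWarnings(stats::wilcox.test(values, values2)$p.value)
    })
  list(median = stats::median(values), p_value = p, n = n)
}
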