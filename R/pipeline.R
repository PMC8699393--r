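# Full analysis pipeline and published-table reproduction.

#' Published per-experiment summary tables
#'
#' The per-experiment Kendall tau pairs (cell-profile area over all
#' generations; circularity over starting + first generations; velocity
#' over the per-experiment groupings the source selected) and the
#' dividing/non-dividing fluorescence-uptake rates, as printed in the
#' study this package's analysis reproduces.  These are the inputs to
#' [table_reproduction_mode()].
#'
#' @param which One of `"area"`, `"circularity"`, `"velocity"`,
#'   `"mitosis"`.
#' @return Data frame of printed per-experiment values.
#' @export
published_tables <- function(which = c("area", "circularity", "velocity",
                                       "mitosis")) {
  which <- match.arg(which)
  file <- switch(which,
    area = "printed_table1_area_tau.csv",
    circularity = "printed_table2_circularity_tau.csv",
    velocity = "printed_table3_velocity_tau.csv",
    mitosis = "printed_table4_mitosis_rates.csv")
  path <- system.file("extdata", file, package = "lineagepump")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute summary statistics from printed per-experiment values
#'
#' Feeds printed per-experiment statistics through the same summary
#' machinery the full pipeline uses: cross-experiment medians, and the
#' persistence index from the per-experiment (tau_Fa, tau_Fmc) or
#' (pFa, pFmc) pairs.  Printed values are compared at their 2-decimal
#' reporting precision.  For the mitosis table, the pFa/pFmc ratios are
#' also recomputed from the printed group medians; a printed ratio that
#' disagrees with its own medians is surfaced as a warning (the printed
#' value is still the one scored).
#'
#' @param taus Data frame with columns `experiment`, `tau_fa`, `tau_fmc`
#'   (ordinal phenotypes), or `NULL`.
#' @param mitosis Data frame shaped like `published_tables("mitosis")`, or
#'   `NULL`.
#' @return List with, for `taus`: `median_tau_fa`, `median_tau_fmc`,
#'   `persistence`; for `mitosis`: including-`a*` and excluding-`a`
#'   medians of the dividing and non-dividing Fa/day, and `persistence`
#'   over the experiments with both ratios (experiment `a*` has no pFmc).
#' @export
table_reproduction_mode <- function(taus = NULL, mitosis = NULL) {
  out <- list()
  if (!is.null(taus)) {
    if (!all(c("tau_fa", "tau_fmc") %in% names(taus)))
      stop("schema error: taus needs columns tau_fa, tau_fmc")
    out$median_tau_fa <- stats::median(taus$tau_fa)
    out$median_tau_fmc <- stats::median(taus$tau_fmc)
    out$persistence <- persistence_from_taus(taus, digits = 2)
  }
  if (!is.null(mitosis)) {
    need <- c("experiment", "fa_rate_dividing", "fa_rate_nondividing",
              "pFa", "pFmc")
    if (!all(need %in% names(mitosis)))
      stop("schema error: mitosis table needs columns ",
           paste(need, collapse = ", "))
    recomputed <- round(mitosis$fa_rate_dividing /
                          mitosis$fa_rate_nondividing, 2)
    off <- which(abs(recomputed - mitosis$pFa) > 0.005 + 1e-9)
    for (i in off)
      warning(sprintf(
        "experiment %s: printed pFa %.2f differs from ratio of printed medians %.2f",
        mitosis$experiment[i], mitosis$pFa[i], recomputed[i]))
    # "a*" restates experiment a without its first generation; the
    # including-a* summary uses it in place of "a"
    with_star <- mitosis[mitosis$experiment != "a", , drop = FALSE]
    no_a <- mitosis[!mitosis$experiment %in% c("a", "a*"), , drop = FALSE]
    scored <- mitosis[!is.na(mitosis$pFmc) &
                        !mitosis$experiment %in% c("a", "a*"), , drop = FALSE]
    out$mitosis <- list(
      median_fa_dividing_incl_astar = stats::median(with_star$fa_rate_dividing),
      median_fa_nondividing_incl_astar = stats::median(with_star$fa_rate_nondividing),
      median_fa_dividing_excl_a = stats::median(no_a$fa_rate_dividing),
      median_fa_nondividing_excl_a = stats::median(no_a$fa_rate_nondividing),
      persistence = persistence_from_ratios(scored))
  }
  out
}

#' Run the full analysis over a set of experiments
#'
#' Executes the pipeline stage by stage for each experiment — normalize,
#' fluorescence accounts, velocities, phenotype correlations by generation
#' grouping, sister-pair differences, dividing/non-dividing comparison —
#' then assembles cross-experiment summaries and persistence indices.
#' Deterministic given its inputs; per-stage exclusion counts are kept in
#' the report.
#'
#' @param forests Named list of [lineage_forest()] objects (one per
#'   experiment), e.g. from [read_track_table()] or the simulator.
#' @param config List of analysis settings; see [default_run_config()].
#' @return An `analysis_report`: list with `correlations` (all
#'   per-experiment tau results), `sister` (per-experiment sister-pair
#'   correlations), `mitosis` (per-experiment comparison rows),
#'   `persistence` (per phenotype and for mitosis), `summary`
#'   (cross-experiment medians and tests) and `meta`.
#' @export
run_analysis <- function(forests, config = default_run_config()) {
  config <- utils::modifyList(default_run_config(), config)
  stopifnot(length(forests) > 0)
  phenos <- c("area", "circularity", "velocity")
  cors <- list(); sis <- list(); mit <- list(); excl <- list()

  for (nm in names(forests)) {
    forest <- forests[[nm]]
    stage <- "normalize"
    res <- tryCatch({
      forest <- normalize_fluorescence(forest)
      stage <- "accounts"
      accounts <- fluorescence_accounts(forest)
      stage <- "phenotypes"
      ptab <- cell_phenotypes(forest, interval = config$velocity_interval_h,
                              exclude_short_tracks = config$exclude_short_tracks)
      stage <- "correlations"
      cc <- list()
      for (ph in phenos)
        for (fk in c("Fa", "Fmc"))
          cc[[paste(ph, fk)]] <- correlate_by_generations(
            forest, accounts, ph, fk, phenotypes = ptab)
      stage <- "sister"
      ss <- lapply(phenos, function(ph)
        sister_pair_differences(forest, accounts, ph, phenotypes = ptab))
      names(ss) <- phenos
      stage <- "mitosis"
      mm <- compare_dividing_vs_nondividing(
        forest, accounts,
        exclude_generations = config$mitosis_exclude_generations,
        min_window_policy = config$mitosis_min_window_policy,
        incomplete_division = config$treat_incomplete_division_as)
      list(cors = do.call(rbind, cc), sister = ss, mitosis = mm,
           excluded = attr(accounts, "excluded"))
    }, error = function(e)
      stop("stage '", stage, "' failed for experiment '", nm, "': ",
           conditionMessage(e), call. = FALSE))
    cors[[nm]] <- res$cors
    sis[[nm]] <- res$sister
    mit[[nm]] <- res$mitosis
    excl[[nm]] <- res$excluded
  }

  correlations <- do.call(rbind, cors)
  rownames(correlations) <- NULL
  mitosis_tab <- do.call(rbind, lapply(mit, function(m)
    data.frame(experiment_id = m$experiment_id,
               fa_rate_dividing = m$median_Fa_rate_dividing,
               fa_rate_nondividing = m$median_Fa_rate_nondividing,
               pFa = m$pFa,
               fmc_rate_dividing = m$median_Fmc_rate_dividing,
               fmc_rate_nondividing = m$median_Fmc_rate_nondividing,
               pFmc = m$pFmc, p_Fa = m$p_Fa, p_Fmc = m$p_Fmc,
               n_dividing = m$n_dividing, n_nondividing = m$n_nondividing,
               stringsAsFactors = FALSE)))
  rownames(mitosis_tab) <- NULL

  # persistence per phenotype from the configured grouping
  persistence <- list()
  summary_rows <- list()
  for (ph in phenos) {
    grouping <- config$persistence_grouping[[ph]]
    taus <- persistence_taus(correlations, ph, grouping)
    if (nrow(taus) > 0) {
      persistence[[ph]] <- persistence_from_taus(taus, digits = NULL)
      persistence[[ph]]$grouping <- grouping
      summary_rows[[ph]] <- data.frame(
        phenotype = ph, grouping = grouping,
        median_tau_fa = stats::median(taus$tau_fa),
        median_tau_fmc = stats::median(taus$tau_fmc),
        p_tau_fa_vs_0 = if (nrow(taus) >= 3)
          cross_experiment_summary(taus$tau_fa)$p_value else NA_real_,
        p_tau_fmc_vs_0 = if (nrow(taus) >= 3)
          cross_experiment_summary(taus$tau_fmc)$p_value else NA_real_,
        p_fa_vs_fmc = if (nrow(taus) >= 3)
          cross_experiment_summary(taus$tau_fa, "wilcoxon-signed-rank-paired",
                                   taus$tau_fmc)$p_value else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  persistence$mitosis <- persistence_from_ratios(mitosis_tab)

  structure(list(
    correlations = correlations,
    sister = sis,
    mitosis = mitosis_tab,
    persistence = persistence,
    summary = do.call(rbind, summary_rows),
    meta = list(config = config, n_experiments = length(forests),
                excluded_cells = unlist(excl),
                package_version = as.character(utils::packageVersion("lineagepump")))),
    class = "analysis_report")
}

# Per-experiment (tau_fa, tau_fmc) rows for one phenotype and grouping.
# Falls back from "cumulative-1" to "all" for experiments with a single
# generation (where no cumulative grouping exists).
persistence_taus <- function(correlations, phenotype, grouping) {
  sub <- correlations[correlations$phenotype == phenotype, , drop = FALSE]
  rows <- lapply(unique(sub$experiment_id), function(e) {
    se <- sub[sub$experiment_id == e, , drop = FALSE]
    g <- if (grouping %in% se$grouping) grouping else "all"
    fa <- se$tau[se$fluorescence_kind == "Fa" & se$grouping == g]
    fmc <- se$tau[se$fluorescence_kind == "Fmc" & se$grouping == g]
    if (length(fa) != 1 || length(fmc) != 1 || is.na(fa) || is.na(fmc))
      return(NULL)
    data.frame(experiment = e, tau_fa = fa, tau_fmc = fmc,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(experiment = character(), tau_fa = numeric(),
                      tau_fmc = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d experiment(s)\n", x$meta$n_experiments))
  if (!is.null(x$summary)) {
    s <- x$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-11s (%s): median tau Fa %.2f, Fmc %.2f; persistence index %.2f\n",
                  s$phenotype[i], s$grouping[i], s$median_tau_fa[i],
                  s$median_tau_fmc[i], x$persistence[[s$phenotype[i]]]$index))
  }
  cat(sprintf("  mitosis: persistence index %.2f\n",
              x$persistence$mitosis$index))
  invisible(x)
}

#' Write an analysis report to files
#'
#' Emits the report's tables as CSV and the persistence/summary results as
#' JSON under `out_dir`.  Output is deterministic: no timestamps, fixed
#' ordering, so identical reports give identical bytes.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    con <- file(file.path(out_dir, name), open = "wb")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE)
  }
  wcsv(report$correlations, "correlations.csv")
  wcsv(report$mitosis, "mitosis.csv")
  if (!is.null(report$summary)) wcsv(report$summary, "summary.csv")
  sis <- do.call(rbind, lapply(names(report$sister), function(e) {
    rows <- lapply(report$sister[[e]], function(s)
      if (!s$insufficient) s$correlations else NULL)
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) > 0) do.call(rbind, rows) else NULL
  }))
  if (!is.null(sis)) wcsv(sis, "sister_correlations.csv")
  jsonlite::write_json(
    list(persistence = report$persistence,
         meta = report$meta[c("n_experiments", "excluded_cells")]),
    file.path(out_dir, "persistence.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
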