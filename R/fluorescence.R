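# Fluorescence accounting: normalization, absolute fluorescence (Fa),
# mother-compensated fluorescence (Fmc), and uptake rates.
#
# Fa is a single per-cell scalar: the cell's fluorescence at its final
# fluorescence frame (the 4-h frame at or immediately before its end
# event), matching the segment-at-fate-time convention of the tracking
# protocol.  Fmc adds half of the immediate mother's Fa, compensating each
# daughter for the share of mother fluorescence handed to its sister at
# division.  Compensation stops at the immediate mother: measurement
# variance swamps any signal from deeper ancestors.

#' Normalize fluorescence to reference units
#'
#' Rescales every fluorescence value in the forest so that the median
#' first-frame fluorescence of co-cultured SAOS-2 starting-generation cells
#' equals exactly 100 normalized units.  The first fluorescence frame of
#' each reference cell is used because it precedes any transfer-driven
#' drift and is independent of cell lifespan.  The operation is idempotent
#' and invariant to a global rescaling of the raw inputs.
#'
#' @param forest A [lineage_forest()].
#' @param reference_value Override for the reference median, in raw units
#'   (e.g. to normalize a control forest against a co-culture forest's
#'   reference).  Default `NULL` computes it from the forest.
#' @return The forest with `obs$fluor` rescaled; the scale factor is kept
#'   in `attr(forest, "fluor_scale")`.
#' @export
normalize_fluorescence <- function(forest, reference_value = NULL) {
  stopifnot(inherits(forest, "lineage_forest"))
  if (is.null(reference_value)) {
    cells <- forest$cells
    ref_ids <- cells$cell_id[cells$cell_type == "SAOS-2" &
                             cells$condition == "co-culture" &
                             cells$generation == 0L]
    ref_vals <- vapply(ref_ids, function(id) {
      o <- cell_obs(forest, id)
      v <- o$fluor[o$frame_kind == "fluorescence" & !is.na(o$fluor)]
      if (length(v) == 0L) NA_real_ else v[1L]
    }, numeric(1))
    ref_vals <- ref_vals[!is.na(ref_vals)]
    if (length(ref_vals) == 0L)
      stop("normalization error: no co-cultured SAOS-2 starting-generation cell with a fluorescence observation")
    reference_value <- stats::median(ref_vals)
  }
  if (!is.finite(reference_value) || reference_value <= 0)
    stop("degenerate-data error: reference median is not positive")
  s <- 100 / reference_value
  forest$obs$fluor <- forest$obs$fluor * s
  attr(forest, "fluor_scale") <- s
  forest
}

#' Absolute fluorescence of one cell (Fa)
#'
#' The fluorescence value at the cell's final fluorescence frame — the 4-h
#' frame at or immediately before its end event.
#'
#' @param forest A [lineage_forest()] (normalized if normalized units are
#'   wanted).
#' @param cell_id Cell identifier.
#' @return Fa, or `NA` with a `"lineagepump_missing_fluor"` condition class
#'   message suppressed to a plain `NA` when the cell has no fluorescence
#'   frame within its lifetime (such cells are excluded downstream).
#' @export
compute_Fa <- function(forest, cell_id) {
  o <- cell_obs(forest, cell_id)
  v <- o$fluor[o$frame_kind == "fluorescence" & !is.na(o$fluor)]
  if (length(v) == 0L) return(NA_real_)
  v[length(v)]
}

#' Mother-compensated fluorescence (Fmc)
#'
#' For generation >= 1: `Fa + mother_Fa / 2`, restoring the half of the
#' mother's fluorescence awarded to the sister at division (equal split
#' assumed).  For generation 0 (no observed mother): `Fmc = Fa`.
#'
#' @param Fa The cell's own absolute fluorescence.
#' @param mother_Fa The immediate mother's Fa, or `NULL`/`NA` for
#'   starting-generation cells.
#' @param generation The cell's generation number.
#' @return Fmc in the same units as `Fa`.
#' @export
compute_Fmc <- function(Fa, mother_Fa = NULL, generation = 0L) {
  if (generation == 0L) return(Fa)
  if (is.null(mother_Fa) || is.na(mother_Fa))
    stop("lineage-data error: generation >= 1 cell without mother Fa")
  Fa + mother_Fa / 2
}

#' Fluorescence uptake rates
#'
#' Divides Fa and Fmc by the cell's observation time in days, yielding the
#' rates (Fa/day, Fmc/day) that make asynchronously arising cells with very
#' different observation windows comparable.
#'
#' @param Fa,Fmc Fluorescence values, normalized units.
#' @param observation_days Time from the cell's first to last observation,
#'   days (positive).
#' @return List with `Fa_rate` and `Fmc_rate`, units/day.
#' @export
compute_rates <- function(Fa, Fmc, observation_days) {
  if (!is.finite(observation_days) || observation_days <= 0)
    stop("parameter error: observation_days must be positive")
  list(Fa_rate = Fa / observation_days, Fmc_rate = Fmc / observation_days)
}

#' Fluorescence accounts for every cell of a forest
#'
#' Runs [compute_Fa()], [compute_Fmc()] and [compute_rates()] across the
#' forest in generation order (mothers before daughters).  Cells without a
#' fluorescence frame, or whose mother lacks one, get `NA` accounts and are
#' counted in the `excluded` attribute.
#'
#' @param forest A normalized [lineage_forest()].
#' @param cell_type,condition Restrict accounting to these cells (defaults:
#'   co-cultured SAOS-2, the fluorescence acceptors).
#' @return Data frame: `cell_id`, `generation`, `fate`, `Fa`, `Fmc`,
#'   `observation_days`, `Fa_rate`, `Fmc_rate`; attribute `excluded` counts
#'   cells dropped for missing fluorescence data.
#' @export
fluorescence_accounts <- function(forest, cell_type = "SAOS-2",
                                  condition = "co-culture") {
  stopifnot(inherits(forest, "lineage_forest"))
  cells <- forest$cells
  keep <- cells$cell_type == cell_type & cells$condition == condition
  cells <- cells[keep, , drop = FALSE]
  cells <- cells[order(cells$generation, cells$cell_id), , drop = FALSE]

  fa <- setNames(rep(NA_real_, nrow(cells)), cells$cell_id)
  fmc <- fa
  obs_days <- fa
  for (i in seq_len(nrow(cells))) {
    id <- cells$cell_id[i]
    fa[[id]] <- compute_Fa(forest, id)
    o <- cell_obs(forest, id)
    if (nrow(o) >= 2L) obs_days[[id]] <- (max(o$time_h) - min(o$time_h)) / 24
    if (is.na(fa[[id]])) next
    gen <- cells$generation[i]
    if (gen == 0L) {
      fmc[[id]] <- fa[[id]]
    } else {
      mid <- cells$parent_id[i]
      m_fa <- if (!is.na(mid) && mid %in% names(fa)) fa[[mid]] else NA_real_
      if (!is.na(m_fa)) fmc[[id]] <- compute_Fmc(fa[[id]], m_fa, gen)
    }
  }
  res <- data.frame(
    cell_id = cells$cell_id, generation = cells$generation, fate = cells$fate,
    Fa = unname(fa), Fmc = unname(fmc), observation_days = unname(obs_days),
    stringsAsFactors = FALSE)
  ok <- !is.na(res$Fa) & !is.na(res$observation_days) & res$observation_days > 0
  res$Fa_rate <- ifelse(ok, res$Fa / res$observation_days, NA_real_)
  res$Fmc_rate <- ifelse(ok & !is.na(res$Fmc),
                         res$Fmc / res$observation_days, NA_real_)
  attr(res, "excluded") <- sum(is.na(res$Fa) | is.na(res$Fmc))
  res
}
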