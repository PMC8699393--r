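# Persistence index: does a phenotypic effect of fluorescence receipt
# survive mitosis?
#
# Rationale: if an effect persists into daughters, mother-compensated
# fluorescence (Fmc) restores the ordering that division halved, so the
# Fmc correlation strengthens relative to Fa; if it does not persist, the
# compensation adds disorder and weakens it.  Each experiment is scored
# +1/0/-1 by comparing its (tau_Fa, tau_Fmc) pair; scores are averaged and
# mapped onto [0, 1].  The index reads as the proportionate weight of
# experiments showing persistence, not the strength of persistence.

#' Score one experiment's ordinal-phenotype tau pair
#'
#' When `tau_fa` is negative (an inverse correlation) both values are first
#' multiplied by -1 so that "stronger" always means larger.  The score is
#' then +1 if adjusted `tau_fa < tau_fmc` (evidence of persistence), 0 on
#' equality, -1 otherwise.  When consuming printed tables the comparison is
#' made at 2-decimal reporting precision (`digits = 2`); computed taus are
#' compared exactly (`digits = NULL`).
#'
#' @param tau_fa,tau_fmc Kendall's tau for Fa and Fmc.
#' @param digits Optional rounding applied before comparison.
#' @return +1, 0 or -1.
#' @export
score_experiment_ordinal <- function(tau_fa, tau_fmc, digits = NULL) {
  stopifnot(is.finite(tau_fa), is.finite(tau_fmc))
  if (!is.null(digits)) {
    tau_fa <- round(tau_fa, digits)
    tau_fmc <- round(tau_fmc, digits)
  }
  if (tau_fa < 0) {
    tau_fa <- -tau_fa
    tau_fmc <- -tau_fmc
  }
  if (tau_fa < tau_fmc) 1L else if (tau_fa == tau_fmc) 0L else -1L
}

#' Score one experiment's mitosis-association ratios
#'
#' +1 when `pFmc > pFa` (evidence of persistence); -1 when pFmc is lower
#' than or equivalent to pFa (ties score -1).
#'
#' @param pFa,pFmc Proportionate fluorescence ratios (positive).
#' @return +1 or -1.
#' @export
score_experiment_mitosis <- function(pFa, pFmc) {
  stopifnot(is.finite(pFa), is.finite(pFmc), pFa > 0, pFmc > 0)
  if (pFmc > pFa) 1L else -1L
}

#' Persistence index from per-experiment scores
#'
#' Averages the +1/0/-1 scores into a final score in [-1, 1] and maps it to
#' the unit interval: `index = (1 + final_score) / 2`.
#'
#' @param scores Integer vector of per-experiment scores in \{-1, 0, +1\}.
#' @return List: `scores`, `final_score`, `index` (full precision) and
#'   `index_2dp` (rounded to the 2-decimal reporting convention).
#' @export
persistence_index <- function(scores) {
  if (length(scores) == 0L) stop("parameter error: at least one score required")
  stopifnot(all(scores %in% c(-1L, 0L, 1L)))
  final <- mean(scores)
  idx <- (1 + final) / 2
  list(scores = as.integer(scores), final_score = final, index = idx,
       index_2dp = round(idx, 2))
}

#' Persistence index for a table of per-experiment tau pairs
#'
#' Convenience wrapper: scores every row of a (`tau_fa`, `tau_fmc`) table
#' with [score_experiment_ordinal()] and aggregates with
#' [persistence_index()].
#'
#' @param taus Data frame with columns `tau_fa` and `tau_fmc` (one row per
#'   experiment).
#' @param digits Rounding before comparison (2 for printed tables, `NULL`
#'   for computed values).
#' @return As [persistence_index()].
#' @export
persistence_from_taus <- function(taus, digits = NULL) {
  scores <- mapply(score_experiment_ordinal, taus$tau_fa, taus$tau_fmc,
                   MoreArgs = list(digits = digits))
  persistence_index(scores)
}

#' Persistence index for a table of per-experiment pFa/pFmc pairs
#'
#' @param ratios Data frame with columns `pFa` and `pFmc`.
#' @return As [persistence_index()].
#' @export
persistence_from_ratios <- function(ratios) {
  scores <- mapply(score_experiment_mitosis, ratios$pFa, ratios$pFmc)
  persistence_index(scores)
}
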