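# Lineage forest data model.
#
# A forest holds every tracked cell of one experiment in two flat tables:
# `cells` (one row per cell: identity, lineage links, fate) and `obs` (one
# row per observation: time-stamped centroid, morphometrics, fluorescence).
# This two-table layout is the idiomatic R rendering of "a collection of
# tracked cells, each with an observation series".

CELL_FATES <- c("divided", "incomplete-division", "apoptosis", "incomplete")
FRAME_KINDS <- c("phase", "fluorescence", "centroid-only")
CELL_TYPES <- c("SAOS-2", "HDF")
CONDITIONS <- c("co-culture", "control")

# Daughters must be born within one phase frame of the mother's division.
BIRTH_TIME_TOL_H <- 0.25

#' Construct a lineage forest
#'
#' Assembles the tracked cells of one experiment into a `lineage_forest`
#' object.  Cell-level fields (lineage links, generation, fate) and
#' observation series are supplied as two data frames keyed by `cell_id`.
#'
#' @param experiment_id Single experiment label (e.g. `"a"`).
#' @param cells Data frame with columns `cell_id`, `cell_type`, `condition`,
#'   `generation`, `parent_id` (NA for the starting generation),
#'   `birth_time_h` (NA for the starting generation), `end_time_h`, `fate`.
#' @param obs Data frame with columns `cell_id`, `time_h`, `x_um`, `y_um`,
#'   `area_um2`, `perimeter_um`, `circularity`, `fluor`, `frame_kind`.
#'   Missing measurements are `NA`.
#' @param duration_days Experiment duration in days.
#'
#' @return A `lineage_forest`: a list with elements `experiment_id`,
#'   `cells`, `obs` (sorted by cell and time) and `duration_days`.
#' @seealso [validate_lineage_forest()], [sister_pairs()]
#' @export
lineage_forest <- function(experiment_id, cells, obs, duration_days) {
  stopifnot(is.character(experiment_id), length(experiment_id) == 1L)
  cell_cols <- c("cell_id", "cell_type", "condition", "generation",
                 "parent_id", "birth_time_h", "end_time_h", "fate")
  obs_cols <- c("cell_id", "time_h", "x_um", "y_um", "area_um2",
                "perimeter_um", "circularity", "fluor", "frame_kind")
  missing_c <- setdiff(cell_cols, names(cells))
  if (length(missing_c) > 0L)
    stop("cells table lacks column(s): ", paste(missing_c, collapse = ", "))
  missing_o <- setdiff(obs_cols, names(obs))
  if (length(missing_o) > 0L)
    stop("obs table lacks column(s): ", paste(missing_o, collapse = ", "))
  cells <- cells[order(cells$cell_id), cell_cols, drop = FALSE]
  obs <- obs[order(obs$cell_id, obs$time_h), obs_cols, drop = FALSE]
  rownames(cells) <- NULL
  rownames(obs) <- NULL
  structure(list(experiment_id = experiment_id,
                 cells = cells,
                 obs = obs,
                 duration_days = as.numeric(duration_days)),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest> experiment %s: %d cells, %d observations, %.2f days\n",
              x$experiment_id, nrow(x$cells), nrow(x$obs), x$duration_days))
  tab <- table(factor(x$cells$fate, levels = CELL_FATES))
  cat("  fates:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  generations:", paste(sort(unique(x$cells$generation)), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a lineage forest
#'
#' Checks every structural invariant of the data model and reports each
#' violation as a row; the forest is never modified and violations are
#' reported, not raised.
#'
#' Rules checked: fate vocabulary; non-negative times; `generation == 0`
#' if and only if `parent_id` and `birth_time_h` are absent; `end_time_h >=
#' birth_time_h`; strictly increasing observation times per cell; parent
#' resolves to a cell with generation one lower; divided mothers have
#' exactly two daughters born at the mother's end time (within one 15-min
#' phase frame); fluorescence values appear only on fluorescence frames;
#' circularity consistent with `4*pi*area/perimeter^2` where all three are
#' present.
#'
#' @param forest A [lineage_forest()].
#' @return Data frame with columns `cell_id`, `rule`, `severity`
#'   (`"error"`), one row per violation; zero rows when the forest is valid.
#' @export
validate_lineage_forest <- function(forest) {
  stopifnot(inherits(forest, "lineage_forest"))
  cells <- forest$cells
  obs <- forest$obs
  issues <- list()
  bad <- function(cell_id, rule) {
    issues[[length(issues) + 1L]] <<- data.frame(
      cell_id = as.character(cell_id), rule = rule, severity = "error",
      stringsAsFactors = FALSE)
  }

  if (anyDuplicated(cells$cell_id))
    bad(cells$cell_id[duplicated(cells$cell_id)][1L], "duplicate cell_id")

  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    if (!cl$fate %in% CELL_FATES)
      bad(cl$cell_id, sprintf("unknown fate '%s'", cl$fate))
    gen0 <- !is.na(cl$generation) && cl$generation == 0
    if (gen0 && !is.na(cl$parent_id))
      bad(cl$cell_id, "generation 0 cell has a parent_id")
    if (gen0 && !is.na(cl$birth_time_h))
      bad(cl$cell_id, "generation 0 cell has a birth_time_h")
    if (!gen0 && is.na(cl$parent_id))
      bad(cl$cell_id, "generation >= 1 cell lacks parent_id")
    if (!gen0 && is.na(cl$birth_time_h))
      bad(cl$cell_id, "generation >= 1 cell lacks birth_time_h")
    if (!is.na(cl$birth_time_h) && cl$end_time_h < cl$birth_time_h)
      bad(cl$cell_id, "end_time_h before birth_time_h")
    if (!is.na(cl$parent_id)) {
      j <- match(cl$parent_id, cells$cell_id)
      if (is.na(j)) {
        bad(cl$cell_id, sprintf("parent_id '%s' not in forest", cl$parent_id))
      } else if (cells$generation[j] != cl$generation - 1L) {
        bad(cl$cell_id, "generation is not mother's generation + 1")
      } else {
        if (abs(cl$birth_time_h - cells$end_time_h[j]) > BIRTH_TIME_TOL_H)
          bad(cl$cell_id, "birth_time_h differs from mother's end_time_h by more than one phase frame")
      }
    }
  }

  # daughter counts per fate
  n_daughters <- table(cells$parent_id[!is.na(cells$parent_id)])
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    nd <- if (cl$cell_id %in% names(n_daughters)) as.integer(n_daughters[[cl$cell_id]]) else 0L
    if (cl$fate == "divided" && nd != 2L)
      bad(cl$cell_id, sprintf("fate 'divided' but %d daughter(s); exactly 2 required", nd))
    if (cl$fate != "divided" && nd > 0L)
      bad(cl$cell_id, sprintf("fate '%s' but %d daughter(s) present", cl$fate, nd))
  }

  # per-cell observation series
  for (id in unique(obs$cell_id)) {
    if (!id %in% cells$cell_id) {
      bad(id, "observation for unknown cell_id")
      next
    }
    o <- obs[obs$cell_id == id, ]
    if (any(o$time_h < 0)) bad(id, "negative observation time")
    if (nrow(o) > 1L && any(diff(o$time_h) <= 0))
      bad(id, "observation times not strictly increasing")
    if (any(!is.na(o$fluor) & o$frame_kind != "fluorescence"))
      bad(id, "fluorescence value on a non-fluorescence frame")
    has_all <- !is.na(o$area_um2) & !is.na(o$perimeter_um) & !is.na(o$circularity)
    if (any(has_all)) {
      expect <- 4 * pi * o$area_um2[has_all] / o$perimeter_um[has_all]^2
      relerr <- abs(o$circularity[has_all] - expect) /
        pmax(abs(expect), .Machine$double.eps)
      if (any(relerr > 1e-9))
        bad(id, "circularity inconsistent with 4*pi*area/perimeter^2")
    }
    if (any(!o$frame_kind %in% FRAME_KINDS))
      bad(id, "unknown frame_kind")
  }

  if (length(issues) == 0L)
    return(data.frame(cell_id = character(), rule = character(),
                      severity = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Enumerate sister pairs
#'
#' Sister cells share a mother and, by construction, exist from generation 1
#' onwards only.  Every divided mother contributes exactly one pair.  Pair
#' members are ordered lexicographically by `cell_id` so the output is
#' reproducible; analyses that need an Fa-based ordering reorder downstream.
#'
#' @param forest A valid [lineage_forest()].
#' @return Data frame with columns `mother_id`, `cell_id_1`, `cell_id_2`
#'   (`cell_id_1 < cell_id_2`), one row per divided mother.
#' @export
sister_pairs <- function(forest) {
  stopifnot(inherits(forest, "lineage_forest"))
  cells <- forest$cells
  kids <- cells[!is.na(cells$parent_id), c("cell_id", "parent_id")]
  mothers <- cells$cell_id[cells$fate == "divided"]
  out <- lapply(mothers, function(m) {
    d <- sort(kids$cell_id[kids$parent_id == m])
    if (length(d) != 2L) return(NULL)  # invalid forests filtered by validation
    data.frame(mother_id = m, cell_id_1 = d[1L], cell_id_2 = d[2L],
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(mother_id = character(), cell_id_1 = character(),
                      cell_id_2 = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$mother_id), , drop = FALSE]
}

# Observations of one cell, time-ordered.
cell_obs <- function(forest, cell_id) {
  o <- forest$obs[forest$obs$cell_id == cell_id, , drop = FALSE]
  o[order(o$time_h), , drop = FALSE]
}

# Display labels for internal generation numbers 0,1,2,...
#' Map generation numbers to report labels
#'
#' Generations are numbered 0 (starting population), 1, 2, ... internally;
#' reports label them "starting", "first", "second", ...
#'
#' @param gen Integer vector of generation numbers.
#' @return Character vector of labels.
#' @export
generation_label <- function(gen) {
  lab <- c("starting", "first", "second", "third", "fourth", "fifth")
  ifelse(gen < length(lab), lab[gen + 1L], paste0("generation-", gen))
}
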