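# Track-table I/O.
#
# Long (tidy) layout: one row per (cell, observation), cell-level columns
# repeated on every row of that cell.  Times are stored in hours; missing
# numeric fields are empty cells.  This schema is a semantic reconstruction
# of the per-experiment tracking spreadsheets such studies summarise their
# recordings into; a spreadsheet export is converted by renaming columns to
# this layout.

TRACK_TABLE_COLUMNS <- c(
  "experiment_id", "cell_id", "cell_type", "condition", "generation",
  "parent_id", "fate", "birth_time_h", "end_time_h",
  "time_h", "x_um", "y_um", "area_um2", "perimeter_um", "circularity",
  "fluor_raw", "frame_kind")

#' Read a track table into lineage forests
#'
#' Reads a long-format CSV/TSV track table (one row per cell observation,
#' cell-level columns repeated) and returns one [lineage_forest()] per
#' `experiment_id`.  Each forest is validated; any invariant violation
#' aborts the read with a diagnostic listing the offending cells.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param duration_days Named numeric vector of experiment durations in
#'   days, or `NULL` to infer each duration as the latest observation time
#'   divided by 24.
#' @return Named list of `lineage_forest`, one per experiment label.
#' @export
read_track_table <- function(path, dialect = c("csv", "tsv"),
                             duration_days = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "",
                           colClasses = NA, check.names = FALSE)
  missing <- setdiff(TRACK_TABLE_COLUMNS, names(tab))
  if (length(missing) > 0L)
    stop("track table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) return(list())
  tab$cell_id <- as.character(tab$cell_id)
  tab$parent_id <- as.character(tab$parent_id)
  tab$experiment_id <- as.character(tab$experiment_id)

  forests <- list()
  for (exp_id in sort(unique(tab$experiment_id))) {
    sub <- tab[tab$experiment_id == exp_id, , drop = FALSE]
    first <- sub[!duplicated(sub$cell_id), , drop = FALSE]
    cells <- data.frame(
      cell_id = first$cell_id, cell_type = first$cell_type,
      condition = first$condition, generation = as.integer(first$generation),
      parent_id = first$parent_id,
      birth_time_h = as.numeric(first$birth_time_h),
      end_time_h = as.numeric(first$end_time_h),
      fate = first$fate, stringsAsFactors = FALSE)
    unknown <- !is.na(cells$parent_id) & !cells$parent_id %in% cells$cell_id
    if (any(unknown))
      stop("track table link error: parent_id not found: ",
           paste(unique(cells$parent_id[unknown]), collapse = ", "))
    obs <- data.frame(
      cell_id = sub$cell_id, time_h = as.numeric(sub$time_h),
      x_um = as.numeric(sub$x_um), y_um = as.numeric(sub$y_um),
      area_um2 = as.numeric(sub$area_um2),
      perimeter_um = as.numeric(sub$perimeter_um),
      circularity = as.numeric(sub$circularity),
      fluor = as.numeric(sub$fluor_raw), frame_kind = sub$frame_kind,
      stringsAsFactors = FALSE)
    # circularity is derived from area and perimeter; rederive it exactly
    # from the stored (quantized) values, checking the stored column only
    # at file precision
    has_ap <- !is.na(obs$area_um2) & !is.na(obs$perimeter_um)
    derived <- 4 * pi * obs$area_um2[has_ap] / obs$perimeter_um[has_ap]^2
    stored <- obs$circularity[has_ap]
    bad_circ <- !is.na(stored) & abs(stored - derived) > 1e-3 * pmax(derived, 1e-12)
    if (any(bad_circ))
      stop("track table consistency error: stored circularity inconsistent with ",
           "area and perimeter for cell(s) ",
           paste(unique(obs$cell_id[has_ap][bad_circ]), collapse = ", "))
    obs$circularity[has_ap] <- derived
    ord <- order(obs$cell_id, obs$time_h)
    nonmono <- tapply(obs$time_h, obs$cell_id, function(t) any(diff(sort(t)) <= 0))
    if (any(unlist(nonmono)))
      stop("track table order error: non-monotone observation times for cell(s) ",
           paste(names(nonmono)[unlist(nonmono)], collapse = ", "))
    dur <- if (!is.null(duration_days) && exp_id %in% names(duration_days))
      duration_days[[exp_id]] else max(obs$time_h) / 24
    forest <- lineage_forest(exp_id, cells, obs[ord, , drop = FALSE], dur)
    rep <- validate_lineage_forest(forest)
    if (nrow(rep) > 0L)
      stop("track table for experiment '", exp_id, "' violates the data model:\n",
           paste(sprintf("  %s: %s", rep$cell_id, rep$rule), collapse = "\n"))
    forests[[exp_id]] <- forest
  }
  forests
}

#' Write lineage forests to a track table
#'
#' Deterministic inverse of [read_track_table()]: rows ordered by
#' (`experiment_id`, `cell_id`, `time_h`), numeric values at 6 significant
#' digits, missing values as empty cells.  Writing the same forests twice
#' produces identical bytes.
#'
#' @param forests A `lineage_forest` or list of them.
#' @param path Output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(forests, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  if (inherits(forests, "lineage_forest")) forests <- list(forests)
  rows <- lapply(forests, function(f) {
    if (nrow(f$obs) == 0L) return(NULL)
    i <- match(f$obs$cell_id, f$cells$cell_id)
    data.frame(
      experiment_id = f$experiment_id,
      cell_id = f$obs$cell_id,
      cell_type = f$cells$cell_type[i],
      condition = f$cells$condition[i],
      generation = f$cells$generation[i],
      parent_id = f$cells$parent_id[i],
      fate = f$cells$fate[i],
      birth_time_h = f$cells$birth_time_h[i],
      end_time_h = f$cells$end_time_h[i],
      time_h = f$obs$time_h, x_um = f$obs$x_um, y_um = f$obs$y_um,
      area_um2 = f$obs$area_um2, perimeter_um = f$obs$perimeter_um,
      circularity = f$obs$circularity, fluor_raw = f$obs$fluor,
      frame_kind = f$obs$frame_kind, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  fmt_num <- function(x) ifelse(is.na(x), "", formatC(x, digits = 6, format = "g"))
  fmt_chr <- function(x) ifelse(is.na(x), "", x)
  lines <- paste(TRACK_TABLE_COLUMNS, collapse = sep)
  if (length(rows) > 0L) {
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$experiment_id, tab$cell_id, tab$time_h), , drop = FALSE]
    cols <- lapply(TRACK_TABLE_COLUMNS, function(cn) {
      x <- tab[[cn]]
      if (is.numeric(x)) fmt_num(x) else fmt_chr(as.character(x))
    })
    lines <- c(lines, do.call(paste, c(cols, sep = sep)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a segmentation mask and matched fluorescence image
#'
#' Loads a binary or labelled integer mask together with a single-channel
#' intensity raster of the same shape.  Labelled masks are split into one
#' binary mask per label.  Inputs may be file paths (TIFF or PNG; 8- or
#' 16-bit single channel) or numeric matrices.
#'
#' @param mask Mask raster: matrix or path.
#' @param image Intensity raster: matrix or path.
#' @param pixel_size Micrometres per pixel (positive scalar).
#' @return List with `masks` (named list of logical matrices, one per
#'   label), `image` (numeric matrix) and `pixel_size`.
#' @export
read_mask_and_image <- function(mask, image, pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("parameter error: pixel_size must be a positive scalar")
  mask <- load_raster(mask)
  image <- load_raster(image)
  if (!identical(dim(mask), dim(image)))
    stop(sprintf("geometry error: mask is %dx%d but image is %dx%d",
                 nrow(mask), ncol(mask), nrow(image), ncol(image)))
  labels <- sort(unique(as.vector(mask[mask > 0])))
  masks <- lapply(labels, function(l) mask == l)
  names(masks) <- as.character(labels)
  list(masks = masks, image = image, pixel_size = pixel_size)
}

load_raster <- function(x) {
  if (is.matrix(x)) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop("raster must be a matrix or a file path")
  ext <- tolower(tools::file_ext(x))
  img <- switch(ext,
    png = png::readPNG(x),
    tif = , tiff = tiff::readTIFF(x),
    stop("unsupported raster format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel only
  img
}

#' Read a run configuration
#'
#' Reads a YAML analysis configuration (paths, pixel size, normalization
#' scope, analysis switches, seeds) and merges it over the defaults in
#' [default_run_config()].
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), cfg)
}

#' Default run configuration
#'
#' @return Named list: `pixel_size_um` (micrometres per pixel),
#'   `velocity_interval_h` (centroid resampling grid), `exclude_short_tracks`
#'   (drop velocities measured over less than one grid interval),
#'   `mitosis_exclude_generations` (generations excluded from the
#'   dividing/non-dividing comparison), `mitosis_min_window_policy`
#'   (`"median-intermitotic"` or `"none"`), `persistence_grouping` (per
#'   phenotype, which generation grouping feeds the persistence index) and
#'   `treat_incomplete_division_as` (`"non-dividing"` or `"dividing"`).
#' @export
default_run_config <- function() {
  list(
    pixel_size_um = 1,
    velocity_interval_h = 2,
    exclude_short_tracks = FALSE,
    mitosis_exclude_generations = integer(),
    mitosis_min_window_policy = "median-intermitotic",
    persistence_grouping = list(area = "all", circularity = "cumulative-1",
                                velocity = "all"),
    treat_incomplete_division_as = "non-dividing",
    seed = 1L)
}
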