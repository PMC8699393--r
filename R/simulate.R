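# Agent-based co-culture simulator.
#
# Emulates the structure of the study system: donor fibroblasts (HDF-like,
# red-labelled) co-cultured with acceptor osteosarcoma cells (SAOS-2-like)
# over up to 5 days; asynchronous mitosis with log-normal intermitotic
# times; per-cell heterogeneous fluorescence uptake (gamma increments per
# 4-h fluorescence frame around a log-normal per-cell propensity);
# fluorescence halved (configurably split) at division; weak-to-strong
# monotone couplings of area, circularity and velocity to a per-cell
# phenotype driver; and an on/off persistence switch per phenotype that
# controls whether a daughter's driver restarts from its own fluorescence
# ("reset") or carries the mother's accumulated exposure ("inherit").
#
# All magnitudes are synthetic order-of-magnitude choices anchored to the
# study's reported scales (cell counts, division/apoptosis frequencies,
# rate units); the couplings encode its qualitative findings as known
# ground truth so the pipeline's recovery of them can be tested.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_experiment()].  Defaults
#' describe one co-culture experiment: 100 starting acceptor cells and 86
#' starting donors followed for 4 days, fluorescence frames every 4 h,
#' centroid samples every 2 h, event times quantized to the 15-min phase
#' frame grid.
#'
#' @param seed Integer seed; all randomness derives from it (per-cell
#'   substreams are derived from (seed, cell index)).
#' @param experiment_id Experiment label.
#' @param n_start_acceptors,n_start_donors Starting population sizes.
#' @param duration_days Experiment duration (<= 5 days).
#' @param phase_interval_h,fluor_interval_h,centroid_interval_h Frame grids
#'   in hours.
#' @param intermitotic_median_h,intermitotic_log_sd Log-normal intermitotic
#'   time (median hours, log-sd); the default median 80 h makes roughly a
#'   third of tracked cells divide within a 4-day window.
#' @param beta_div Division-hazard link: the drawn intermitotic time is
#'   divided by the saturating monotone factor
#'   `1 + beta_div * propensity / (propensity + uptake_median_per_day)`,
#'   which shortens high-uptake cells' cycles by up to `1 + beta_div`-fold
#'   while staying bounded (an unbounded link would let rare high-uptake
#'   lineages grow without limit).  0 decouples division from uptake.
#' @param apoptosis_rate_per_day Exponential apoptosis hazard.
#' @param prob_incomplete_division Probability that a division event fails
#'   (fate "incomplete-division", no daughters).
#' @param uptake_median_per_day,uptake_log_sd Per-cell uptake propensity
#'   (log-normal, raw units/day).
#' @param uptake_shape Gamma shape per 4-h increment (smaller = noisier).
#' @param pre_record_hours Co-culture time before the recording starts;
#'   cells begin the recording carrying `propensity * pre_record_hours/24`
#'   units, so the starting generation has a positive first-frame reference
#'   for normalization.
#' @param sister_propensity_cor Correlation of sister deviations in log
#'   propensity (shared division-event effect).
#' @param propensity_inherit_sd Log-sd of a daughter's propensity deviation
#'   from its mother's.
#' @param split_frac Fraction of mother fluorescence passed to daughter 1.
#' @param baseline_area,beta_area,sd_area Area coupling, micrometres^2:
#'   `area = baseline + beta * driver + N(0, sd)`.
#' @param baseline_circ,beta_circ,sd_circ Circularity coupling (inverse:
#'   `baseline - beta * driver + noise`, clamped into (0, 1]).
#' @param baseline_vel,beta_vel,sd_vel Migration-speed coupling,
#'   micrometres/day.
#' @param donor_fluor,donor_intermitotic_median_h Donor label level and
#'   division timing.
#' @param persistence Named list with elements `area`, `circularity`,
#'   `velocity`, each `"reset"` or `"inherit"`.  Defaults mirror the study
#'   system: area and velocity effects reset at division, circularity
#'   inherits.
#' @param field_um Field of view (width, height) in micrometres.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              experiment_id = "a",
                              n_start_acceptors = 100L,
                              n_start_donors = 86L,
                              duration_days = 4,
                              phase_interval_h = 0.25,
                              fluor_interval_h = 4,
                              centroid_interval_h = 2,
                              intermitotic_median_h = 120,
                              intermitotic_log_sd = 0.5,
                              beta_div = 1,
                              apoptosis_rate_per_day = 0.015,
                              prob_incomplete_division = 0.02,
                              uptake_median_per_day = 40,
                              uptake_log_sd = 1.0,
                              uptake_shape = 2,
                              pre_record_hours = 24,
                              sister_propensity_cor = 0.7,
                              propensity_inherit_sd = 0.5,
                              split_frac = 0.5,
                              baseline_area = 1359, beta_area = 2,
                              sd_area = 300,
                              baseline_circ = 0.79, beta_circ = 2e-4,
                              sd_circ = 0.08,
                              baseline_vel = 84, beta_vel = 0.03,
                              sd_vel = 40,
                              donor_fluor = 5000,
                              donor_intermitotic_median_h = 140,
                              persistence = list(area = "reset",
                                                 circularity = "inherit",
                                                 velocity = "reset"),
                              field_um = c(1920, 1440)) {
  cfg <- as.list(environment())
  if (cfg$duration_days <= 0 || cfg$duration_days > 5)
    stop("duration_days must be in (0, 5]")
  if (cfg$split_frac <= 0 || cfg$split_frac >= 1)
    stop("split_frac must be in (0, 1)")
  nonneg <- c("intermitotic_median_h", "intermitotic_log_sd", "beta_div",
              "apoptosis_rate_per_day", "prob_incomplete_division",
              "uptake_median_per_day", "uptake_log_sd", "pre_record_hours",
              "propensity_inherit_sd", "baseline_area", "beta_area",
              "sd_area", "baseline_circ", "beta_circ", "sd_circ",
              "baseline_vel", "beta_vel", "sd_vel")
  for (nm in nonneg)
    if (cfg[[nm]] < 0) stop(nm, " must be non-negative")
  stopifnot(all(unlist(cfg$persistence) %in% c("reset", "inherit")),
            all(c("area", "circularity", "velocity") %in% names(cfg$persistence)))
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-cell RNG substream from (seed, cell index).
cell_seed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %%
               .Machine$integer.max)
}

#' Simulate one co-culture experiment
#'
#' Runs the agent-based model and returns the resulting lineage forest
#' together with the per-cell ground truth (uptake propensity, phenotype
#' driver values, division outcome).  Identical seeds give identical
#' output.
#'
#' @param config A [simulation_config()].
#' @return List with `forest` (a [lineage_forest()]) and `truth` (data
#'   frame: `cell_id`, `cell_type`, `generation`, `propensity`,
#'   `driver_area`, `driver_circularity`, `driver_velocity`, `divided`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dur_h <- cfg$duration_days * 24
  n0 <- cfg$n_start_acceptors + cfg$n_start_donors
  expected_pop <- n0 * 2^(dur_h / min(cfg$intermitotic_median_h,
                                      cfg$donor_intermitotic_median_h))
  if (expected_pop > 1e5)
    stop("guard error: expected population ", round(expected_pop),
         " exceeds 100000; reduce duration or starting counts")

  # seed the starting populations (deterministic layout of the queue)
  set.seed(cfg$seed)
  queue <- vector("list", 2 * n0)  # grows as needed
  n_queued <- 0L
  push <- function(cell) {
    n_queued <<- n_queued + 1L
    if (n_queued > length(queue)) length(queue) <<- 2L * n_queued
    queue[[n_queued]] <<- cell
  }
  start_logprop <- log(cfg$uptake_median_per_day) +
    cfg$uptake_log_sd * rnorm(cfg$n_start_acceptors)
  start_pos <- cbind(runif(n0, 0, cfg$field_um[1]),
                     runif(n0, 0, cfg$field_um[2]))
  for (i in seq_len(cfg$n_start_acceptors)) {
    prop <- exp(start_logprop[i])
    f0 <- prop * cfg$pre_record_hours / 24
    push(list(type = "SAOS-2", gen = 0L, parent = NA_character_,
              birth = 0, F_birth = f0, H_birth = f0, logprop = start_logprop[i],
              pos = start_pos[i, ]))
  }
  for (i in seq_len(cfg$n_start_donors)) {
    push(list(type = "HDF", gen = 0L, parent = NA_character_,
              birth = 0, F_birth = cfg$donor_fluor, H_birth = cfg$donor_fluor,
              logprop = -Inf, pos = start_pos[cfg$n_start_acceptors + i, ]))
  }

  cells_acc <- list()
  obs_acc <- list()
  truth_acc <- list()
  i <- 0L
  while (i < n_queued) {
    i <- i + 1L
    if (n_queued > 1e5)
      stop("guard error: simulated population exceeded 100000 cells")
    cell <- queue[[i]]
    id <- sprintf("%s-%04d", cfg$experiment_id, i)
    set.seed(cell_seed(cfg$seed, i))
    is_donor <- cell$type == "HDF"
    prop <- if (is_donor) 0 else exp(cell$logprop)

    # --- fate and end time -------------------------------------------------
    imt_median <- if (is_donor) cfg$donor_intermitotic_median_h else
      cfg$intermitotic_median_h
    t0 <- rlnorm(1, log(imt_median), cfg$intermitotic_log_sd)
    hazard_link <- if (prop > 0)
      1 + cfg$beta_div * prop / (prop + cfg$uptake_median_per_day) else 1
    t_div <- cell$birth + t0 / (if (is_donor) 1 else hazard_link)
    t_apo <- cell$birth + if (cfg$apoptosis_rate_per_day > 0)
      rexp(1, cfg$apoptosis_rate_per_day / 24) else Inf
    # quantize to the next phase frame, tolerant of float noise on the grid
    q <- function(t) if (is.finite(t))
      ceiling(t / cfg$phase_interval_h - 1e-9) * cfg$phase_interval_h else t
    t_div <- q(t_div); t_apo <- q(t_apo)
    if (t_div <= min(t_apo, dur_h)) {
      fate <- if (runif(1) < cfg$prob_incomplete_division)
        "incomplete-division" else "divided"
      end <- t_div
    } else if (t_apo <= dur_h) {
      fate <- "apoptosis"; end <- t_apo
    } else {
      fate <- "incomplete"; end <- dur_h
    }

    # --- fluorescence trajectory on the 4-h frame grid ---------------------
    tf_start <- ceiling(cell$birth / cfg$fluor_interval_h) * cfg$fluor_interval_h
    tf <- if (tf_start <= end)
      seq(tf_start, end, by = cfg$fluor_interval_h) else numeric(0)
    if (is_donor) {
      F_frames <- rep(cfg$donor_fluor, length(tf))
      F_end <- cfg$donor_fluor
    } else {
      bounds <- c(cell$birth, tf, end)  # increments frame to frame, then to end
      dts <- diff(bounds)
      incr <- vapply(dts, function(dt) {
        if (dt <= 0 || prop <= 0) return(0)
        shape <- cfg$uptake_shape * dt / cfg$fluor_interval_h
        rgamma(1, shape = shape, scale = prop * dt / 24 / shape)
      }, numeric(1))
      cum <- cell$F_birth + cumsum(incr)
      F_frames <- if (length(tf) > 0) cum[seq_along(tf)] else numeric(0)
      F_end <- cum[length(cum)]
    }

    # --- phenotype drivers at the final fluorescence frame -----------------
    has_frame <- length(tf) > 0
    F_last <- if (has_frame) F_frames[length(F_frames)] else NA_real_
    H_last <- if (has_frame)
      cell$H_birth + (F_last - cell$F_birth) else NA_real_
    drv <- function(switch_val) if (identical(switch_val, "inherit"))
      H_last else F_last
    d_area <- drv(cfg$persistence$area)
    d_circ <- drv(cfg$persistence$circularity)
    d_vel <- drv(cfg$persistence$velocity)

    if (is_donor) {
      area <- max(200, 4179 + rnorm(1, 0, 800))
      circ <- min(1, max(0.01, 0.35 + rnorm(1, 0, 0.08)))
      v_exp <- max(5, 316 + rnorm(1, 0, 80))
    } else {
      area <- if (has_frame)
        max(100, cfg$baseline_area + cfg$beta_area * d_area +
              rnorm(1, 0, cfg$sd_area)) else NA_real_
      circ <- if (has_frame)
        min(1, max(0.01, cfg$baseline_circ - cfg$beta_circ * d_circ +
                     rnorm(1, 0, cfg$sd_circ))) else NA_real_
      v_exp <- max(5, cfg$baseline_vel +
                     cfg$beta_vel * (if (has_frame) d_vel else cell$F_birth) +
                     rnorm(1, 0, cfg$sd_vel))
    }
    perim <- if (has_frame && !is.na(area)) sqrt(4 * pi * area / circ) else NA_real_

    # --- centroid path on the 2-h grid (+ off-grid end frame) --------------
    tc_start <- ceiling(cell$birth / cfg$centroid_interval_h) *
      cfg$centroid_interval_h
    tc <- if (tc_start <= end)
      seq(tc_start, end, by = cfg$centroid_interval_h) else numeric(0)
    times <- sort(unique(c(tc, end)))
    nt <- length(times)
    # expected speed v_exp um/day over 2-h Rayleigh steps:
    # E|step| = sigma * sqrt(pi/2) and 12 steps/day
    sigma2h <- (v_exp / 12) / sqrt(pi / 2)
    if (nt >= 1) {
      dt <- diff(c(cell$birth, times))
      sdv <- sigma2h * sqrt(pmax(dt, 0) / cfg$centroid_interval_h)
      xs <- cell$pos[1] + cumsum(rnorm(nt, 0, sdv))
      ys <- cell$pos[2] + cumsum(rnorm(nt, 0, sdv))
    } else {
      xs <- numeric(0); ys <- numeric(0)
    }
    end_pos <- if (nt >= 1) c(xs[nt], ys[nt]) else cell$pos

    # --- observation rows --------------------------------------------------
    if (nt >= 1) {
      kind <- ifelse(times %in% tf, "fluorescence",
                     ifelse(times %in% tc, "centroid-only", "phase"))
      fluor <- rep(NA_real_, nt)
      fluor[match(tf, times)] <- F_frames
      area_col <- rep(NA_real_, nt)
      perim_col <- rep(NA_real_, nt)
      circ_col <- rep(NA_real_, nt)
      if (has_frame && !is.na(area)) {
        j <- match(tf[length(tf)], times)
        area_col[j] <- area; perim_col[j] <- perim; circ_col[j] <- circ
      }
      obs_acc[[i]] <- list(cell_id = rep(id, nt), time_h = times,
                           x_um = xs, y_um = ys, area_um2 = area_col,
                           perimeter_um = perim_col, circularity = circ_col,
                           fluor = fluor, frame_kind = kind)
    }

    cells_acc[[i]] <- list(
      cell_id = id, cell_type = cell$type, condition = "co-culture",
      generation = cell$gen, parent_id = cell$parent,
      birth_time_h = if (cell$gen == 0L) NA_real_ else cell$birth,
      end_time_h = end, fate = fate)
    truth_acc[[i]] <- list(
      cell_id = id, cell_type = cell$type, generation = cell$gen,
      propensity = prop, driver_area = d_area, driver_circularity = d_circ,
      driver_velocity = d_vel, divided = fate == "divided")

    # --- daughters ---------------------------------------------------------
    if (fate == "divided") {
      shared <- rnorm(1, 0, sqrt(cfg$sister_propensity_cor) *
                        cfg$propensity_inherit_sd)
      indiv_sd <- sqrt(1 - cfg$sister_propensity_cor) *
        cfg$propensity_inherit_sd
      H_end <- cell$H_birth + (F_end - cell$F_birth)
      offs <- matrix(rnorm(4, 0, 5), 2)
      for (k in 1:2) {
        frac <- if (k == 1) cfg$split_frac else 1 - cfg$split_frac
        push(list(type = cell$type, gen = cell$gen + 1L, parent = id,
                  birth = end, F_birth = frac * F_end, H_birth = H_end,
                  logprop = if (is_donor) -Inf else
                    cell$logprop + shared + rnorm(1, 0, indiv_sd),
                  pos = end_pos + offs[, k]))
      }
    }
  }

  cells <- as.data.frame(do.call(rbind, lapply(cells_acc, function(r)
    r[c("cell_id", "cell_type", "condition", "generation", "parent_id",
        "birth_time_h", "end_time_h", "fate")])), stringsAsFactors = FALSE)
  for (nm in names(cells)) cells[[nm]] <- unlist(cells[[nm]], use.names = FALSE)
  obs_acc <- obs_acc[!vapply(obs_acc, is.null, logical(1))]
  obs <- data.frame(
    cell_id = unlist(lapply(obs_acc, `[[`, "cell_id")),
    time_h = unlist(lapply(obs_acc, `[[`, "time_h")),
    x_um = unlist(lapply(obs_acc, `[[`, "x_um")),
    y_um = unlist(lapply(obs_acc, `[[`, "y_um")),
    area_um2 = unlist(lapply(obs_acc, `[[`, "area_um2")),
    perimeter_um = unlist(lapply(obs_acc, `[[`, "perimeter_um")),
    circularity = unlist(lapply(obs_acc, `[[`, "circularity")),
    fluor = unlist(lapply(obs_acc, `[[`, "fluor")),
    frame_kind = unlist(lapply(obs_acc, `[[`, "frame_kind")),
    stringsAsFactors = FALSE)
  truth <- as.data.frame(do.call(rbind, lapply(truth_acc, function(r)
    r[c("cell_id", "cell_type", "generation", "propensity", "driver_area",
        "driver_circularity", "driver_velocity", "divided")])),
    stringsAsFactors = FALSE)
  for (nm in names(truth)) truth[[nm]] <- unlist(truth[[nm]], use.names = FALSE)

  forest <- lineage_forest(cfg$experiment_id, cells, obs, cfg$duration_days)
  list(forest = forest, truth = truth)
}

#' Default batch of seven simulated experiments
#'
#' Mirrors the study layout: seven co-culture experiments labelled "a" to
#' "g" with durations 4, 2, 3.6, 4, 4, 5 and 4 days respectively.
#'
#' @param seed Base seed; experiment i uses `seed + i`.
#' @param n_start_acceptors Starting acceptor count per experiment.
#' @param ... Further arguments passed to [simulation_config()].
#' @return Named list of [simulate_experiment()] results.
#' @export
simulate_experiment_batch <- function(seed = 1L, n_start_acceptors = 100L,
                                      ...) {
  durations <- c(a = 4, b = 2, c = 3.6, d = 4, e = 4, f = 5, g = 4)
  out <- list()
  for (i in seq_along(durations)) {
    lab <- names(durations)[i]
    cfg <- simulation_config(seed = as.integer(seed + i),
                             experiment_id = lab,
                             n_start_acceptors = n_start_acceptors,
                             duration_days = durations[[i]], ...)
    out[[lab]] <- simulate_experiment(cfg)
  }
  out
}
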