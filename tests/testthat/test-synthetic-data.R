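test_that("identical seeds give identical simulations, different seeds differ", {
  cfg <- simulation_config(seed = 9, n_start_acceptors = 12L,
                           n_start_donors = 6L, duration_days = 3)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$forest$cells, s2$forest$cells)
  expect_identical(s1$forest$obs, s2$forest$obs)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(simulation_config(seed = 10,
                                              n_start_acceptors = 12L,
                                              n_start_donors = 6L,
                                              duration_days = 3))
  expect_false(identical(s1$forest$obs, s3$forest$obs))
})

test_that("zero uptake propensity yields zero acceptor fluorescence", {
  sim <- simulate_experiment(simulation_config(
    seed = 2, n_start_acceptors = 10L, n_start_donors = 0L,
    duration_days = 2, uptake_median_per_day = 0))
  fl <- sim$forest$obs$fluor
  expect_true(all(fl[!is.na(fl)] == 0))
})

test_that("deterministic intermitotic clock enumerates the expected binary tree", {
  # 24 h cycle over 2 days from one starting cell: divisions at 24 and 48 h,
  # generations 0, 1, 2 present, 3 divisions, 4 terminal cells
  sim <- simulate_experiment(simulation_config(
    seed = 1, n_start_acceptors = 1L, n_start_donors = 0L,
    duration_days = 2, intermitotic_median_h = 24, intermitotic_log_sd = 0,
    beta_div = 0, apoptosis_rate_per_day = 0,
    prob_incomplete_division = 0))
  cells <- sim$forest$cells
  expect_setequal(unique(cells$generation), 0:2)
  expect_identical(sum(cells$fate == "divided"), 3L)
  expect_identical(sum(cells$generation == 2L), 4L)
  expect_identical(nrow(cells), 7L)
})

test_that("fluorescence is conserved exactly at simulated divisions", {
  # deterministic 24-h clock puts every division on the 4-h frame grid, so
  # each daughter's first fluorescence frame samples its birth level exactly
  sim <- simulate_experiment(simulation_config(
    seed = 21, n_start_acceptors = 20L, n_start_donors = 0L,
    duration_days = 2, split_frac = 0.3, intermitotic_median_h = 24,
    intermitotic_log_sd = 0, beta_div = 0, apoptosis_rate_per_day = 0,
    prob_incomplete_division = 0))
  forest <- sim$forest
  pairs <- sister_pairs(forest)
  # daughters' starting fluorescence sums to the mother's final level;
  # recover both from the uptake-free instant at birth: the first frame
  # value minus subsequent uptake is not observable, so check the split
  # fractions instead via truth-free bookkeeping at division time
  cells <- forest$cells
  tested <- 0L
  for (i in seq_len(nrow(pairs))) {
    d1 <- cell_obs(forest, pairs$cell_id_1[i])
    d2 <- cell_obs(forest, pairs$cell_id_2[i])
    birth <- cells$birth_time_h[cells$cell_id == pairs$cell_id_1[i]]
    # if both daughters have a fluorescence frame exactly at birth, their
    # values sum to the mother's fluorescence at that same frame time
    f1 <- d1$fluor[d1$time_h == birth & d1$frame_kind == "fluorescence"]
    f2 <- d2$fluor[d2$time_h == birth & d2$frame_kind == "fluorescence"]
    if (length(f1) != 1 || length(f2) != 1 || is.na(f1) || is.na(f2)) next
    expect_equal(min(f1, f2) / (f1 + f2), 0.3, tolerance = 1e-9)
    tested <- tested + 1L
  }
  expect_gt(tested, 0L)
})

test_that("population guard rejects explosive configurations", {
  expect_error(simulation_config(seed = 1, duration_days = 8),
               "duration_days")
  expect_error(simulate_experiment(simulation_config(
    seed = 1, n_start_acceptors = 10000L, n_start_donors = 0L,
    duration_days = 5, intermitotic_median_h = 20)),
    "guard error")
})

test_that("rendered fixtures conserve fluorescence and match shape theory", {
  cells <- data.frame(x = 60, y = 60, a = 30, b = 30, angle = 0,
                      total_fluor = 1000)
  fx <- render_image_fixture(cells, field_px = c(120, 120), noise_sd = 0)
  expect_equal(masked_fluorescence(fx$mask == 1, fx$image), 1000,
               tolerance = 0.5 / 1000)
  meas <- suppressWarnings(measure_mask(fx$mask == 1))
  expect_gt(meas$circularity, 0.85)

  # 4:1 ellipse: Ramanujan perimeter gives circularity well below 0.8
  a <- 60; b <- 15
  h <- ((a - b) / (a + b))^2
  ram <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expected <- 4 * pi * (pi * a * b) / ram^2
  expect_lt(expected, 0.8)
  ell <- render_image_fixture(
    data.frame(x = 81, y = 81, a = a, b = b, angle = 0, total_fluor = 1),
    field_px = c(161, 161))
  meas_e <- measure_mask(ell$mask == 1)
  expect_lt(meas_e$circularity, 0.8)
  expect_equal(meas_e$circularity, expected, tolerance = 0.1)

  # overlap is resolved deterministically with a warning
  two <- data.frame(x = c(50, 60), y = c(60, 60), a = 20, b = 20, angle = 0,
                    total_fluor = c(100, 100))
  expect_warning(fx2 <- render_image_fixture(two, field_px = c(120, 120)),
                 "overlap")
  expect_equal(sum(fx2$image), 200, tolerance = 1e-9)
})

test_that("seeded batches reproduce the study layout", {
  batch <- simulate_experiment_batch(seed = 3, n_start_acceptors = 5L,
                                     n_start_donors = 3L)
  expect_named(batch, letters[1:7])
  expect_equal(batch$b$forest$duration_days, 2)
  expect_equal(batch$f$forest$duration_days, 5)
})
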