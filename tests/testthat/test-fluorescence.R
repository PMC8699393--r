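test_that("normalization fixes the starting-generation reference median at 100", {
  forest <- normalize_fluorescence(make_toy_forest())
  # reference first-frame values 10 and 30 -> median 20 -> factor 5
  expect_equal(attr(forest, "fluor_scale"), 5)
  a0 <- cell_obs(forest, "A")$fluor[1]
  b0 <- cell_obs(forest, "B")$fluor[1]
  expect_equal(median(c(a0, b0)), 100)
})

test_that("normalization is scale-invariant and idempotent", {
  f1 <- make_toy_forest()
  f2 <- f1
  f2$obs$fluor <- f2$obs$fluor * 37.5   # any positive rescaling of raw data
  n1 <- normalize_fluorescence(f1)
  n2 <- normalize_fluorescence(f2)
  expect_equal(n1$obs$fluor, n2$obs$fluor)
  n11 <- normalize_fluorescence(n1)
  expect_equal(n11$obs$fluor, n1$obs$fluor)
})

test_that("normalization errors on empty or degenerate reference sets", {
  forest <- make_toy_forest()
  forest$cells$condition <- "control"
  expect_error(normalize_fluorescence(forest), "normalization error")
  forest2 <- make_toy_forest()
  forest2$obs$fluor[!is.na(forest2$obs$fluor)] <- 0
  expect_error(normalize_fluorescence(forest2), "degenerate")
})

test_that("Fa is the value at the final fluorescence frame", {
  forest <- normalize_fluorescence(make_toy_forest())
  expect_equal(compute_Fa(forest, "A"), 105)   # 21 * 5, frame at 8 h, end 9 h
  expect_equal(compute_Fa(forest, "B"), 160)   # 32 * 5
  expect_equal(compute_Fa(forest, "A2"), 35)   # single frame at 12 h
  # a cell with no fluorescence frame yields a missing-data marker
  forest$obs <- forest$obs[!(forest$obs$cell_id == "A2" &
                             forest$obs$frame_kind == "fluorescence"), ]
  expect_true(is.na(compute_Fa(forest, "A2")))
})

test_that("Fa uses the last grid frame inside the cell's lifetime", {
  # born at 5 h, frames at 8 h only, end at 9 h -> value at 8 h
  cells <- data.frame(cell_id = c("M", "D1", "D2"), cell_type = "SAOS-2",
                      condition = "co-culture", generation = c(0L, 1L, 1L),
                      parent_id = c(NA, "M", "M"), birth_time_h = c(NA, 5, 5),
                      end_time_h = c(5, 9, 9),
                      fate = c("divided", "incomplete", "incomplete"),
                      stringsAsFactors = FALSE)
  ob <- function(id, t, fl = NA_real_, kind = "centroid-only")
    data.frame(cell_id = id, time_h = t, x_um = 0, y_um = 0,
               area_um2 = NA_real_, perimeter_um = NA_real_,
               circularity = NA_real_, fluor = fl, frame_kind = kind,
               stringsAsFactors = FALSE)
  obs <- rbind(ob("M", 0, 40, "fluorescence"), ob("M", 4, 44, "fluorescence"),
               ob("D1", 6), ob("D1", 8, 30, "fluorescence"), ob("D1", 9, kind = "phase"),
               ob("D2", 8, 26, "fluorescence"))
  forest <- lineage_forest("x", cells, obs, 0.5)
  expect_identical(nrow(validate_lineage_forest(forest)), 0L)
  forest <- normalize_fluorescence(forest)
  expect_equal(compute_Fa(forest, "D1"), 30 * 100 / 40)
})

test_that("Fmc adds half the mother's Fa from generation 1 on", {
  expect_equal(compute_Fmc(50, 200, 1L), 150)
  expect_equal(compute_Fmc(80, NULL, 0L), 80)
  expect_equal(compute_Fmc(12, 0, 1L), 12)
  expect_error(compute_Fmc(50, NA, 1L), "lineage-data error")
})

test_that("rates divide by observation time in days", {
  expect_equal(compute_rates(120, 150, 2)$Fa_rate, 60)
  expect_equal(compute_rates(0, 0, 1)$Fa_rate, 0)
  expect_equal(compute_rates(90, 90, 36 / 24)$Fa_rate, 60)
  expect_error(compute_rates(10, 10, 0), "parameter error")
})

test_that("accounts table reproduces the hand-computed toy values", {
  forest <- normalize_fluorescence(make_toy_forest())
  acc <- fluorescence_accounts(forest)
  get <- function(id, col) acc[acc$cell_id == id, col]
  expect_equal(get("A", "Fa"), 105)
  expect_equal(get("A1", "Fmc"), 30 + 105 / 2)
  expect_equal(get("A2", "Fmc"), 35 + 105 / 2)
  expect_equal(get("A", "Fmc"), 105)             # generation 0: Fmc = Fa
  expect_equal(get("A1", "observation_days"), 6.5 / 24)
  expect_equal(get("A1", "Fa_rate"), 30 / (6.5 / 24))
})

test_that("mother fluorescence is conserved across every simulated division", {
  sim <- simulate_experiment(simulation_config(
    seed = 3, n_start_acceptors = 25L, n_start_donors = 0L,
    duration_days = 4))
  forest <- normalize_fluorescence(sim$forest)
  acc <- fluorescence_accounts(forest)
  pairs <- sister_pairs(forest)
  tested <- 0L
  for (i in seq_len(nrow(pairs))) {
    m <- acc[acc$cell_id == pairs$mother_id[i], ]
    d1 <- acc[acc$cell_id == pairs$cell_id_1[i], ]
    d2 <- acc[acc$cell_id == pairs$cell_id_2[i], ]
    if (any(is.na(c(m$Fa, d1$Fa, d1$Fmc, d2$Fa, d2$Fmc)))) next
    expect_equal((d1$Fmc - d1$Fa) + (d2$Fmc - d2$Fa), m$Fa)
    tested <- tested + 1L
  }
  expect_gt(tested, 3L)
  # Fmc equals Fa for the whole starting generation
  g0 <- acc[acc$generation == 0L & !is.na(acc$Fa), ]
  expect_equal(g0$Fmc, g0$Fa)
})
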