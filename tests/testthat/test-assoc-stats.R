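test_that("kendall tau-b handles perfect concordance and discordance", {
  expect_equal(kendall_tau(1:4, c(2, 4, 6, 8))$tau, 1)
  expect_equal(kendall_tau(1:4, c(8, 6, 4, 2))$tau, -1)
  expect_error(kendall_tau(1:3, 1:4), "equal length")
  expect_warning(res <- kendall_tau(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(res$tau))
})

test_that("kendall tau-b equals the brute-force pair-counting oracle with ties", {
  res <- kendall_tau(c(1, 2, 2, 3, 4), c(1, 3, 2, 2, 4))
  expect_equal(res$tau, brute_force_tau(c(1, 2, 2, 3, 4), c(1, 3, 2, 2, 4)),
               tolerance = 1e-12)
  set.seed(101)
  for (i in 1:40) {
    n <- sample(2:50, 1)
    x <- sample(1:8, n, replace = TRUE)    # heavy ties
    y <- if (i %% 2 == 0) sample(1:8, n, replace = TRUE) else rnorm(n)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$tau, brute_force_tau(x, y),
                 tolerance = 1e-12)
  }
})

test_that("kendall tau-b agrees with the reference implementation in stats", {
  set.seed(202)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- x + sample(0:4, n, replace = TRUE)
    res <- kendall_tau(x, y)
    expect_equal(res$tau, unname(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
    ref_p <- suppressWarnings(
      cor.test(x, y, method = "kendall", continuity = TRUE)$p.value)
    expect_equal(res$p_value, ref_p, tolerance = 1e-8)
  }
})

test_that("tau is invariant under strictly monotone transforms", {
  set.seed(33)
  x <- rnorm(30); y <- rnorm(30) + 0.5 * x
  t0 <- kendall_tau(x, y)$tau
  expect_equal(kendall_tau(exp(x), y)$tau, t0)
  expect_equal(kendall_tau(x, y^3 + 2 * y)$tau, t0)
})

test_that("generation-grouped correlations recover a noise-free monotone coupling", {
  sim <- simulate_experiment(simulation_config(
    seed = 11, n_start_acceptors = 30L, n_start_donors = 0L,
    duration_days = 3, sd_area = 0, beta_area = 2,
    persistence = list(area = "reset", circularity = "reset",
                       velocity = "reset")))
  forest <- normalize_fluorescence(sim$forest)
  acc <- fluorescence_accounts(forest)
  cors <- correlate_by_generations(forest, acc, "area", "Fa")
  expect_true(all(cors$tau[!is.na(cors$tau)] == 1))
  # "all" equals tau on the concatenation by definition
  ptab <- cell_phenotypes(forest)
  d <- merge(acc, ptab[, c("cell_id", "area")], by = "cell_id")
  d <- d[is.finite(d$Fa) & is.finite(d$area), ]
  expect_equal(cors$tau[cors$grouping == "all"],
               kendall_tau(d$Fa, d$area)$tau)
  expect_equal(cors$n[cors$grouping == "all"], nrow(d))
})

test_that("permuted phenotype labels give near-zero correlation", {
  set.seed(44)
  n <- 500
  fa <- rlnorm(n, log(100), 1)
  area <- 1000 + 2 * fa + rnorm(n, 0, 100)
  area_perm <- sample(area)
  expect_gt(kendall_tau(fa, area)$tau, 0.5)
  expect_lt(abs(kendall_tau(fa, area_perm)$tau), 0.1)
})

test_that("sister-pair differences order by Fa and recover couplings", {
  sim <- simulate_experiment(simulation_config(
    seed = 12, n_start_acceptors = 40L, n_start_donors = 0L,
    duration_days = 4, sd_area = 0, beta_area = 2,
    persistence = list(area = "reset", circularity = "reset",
                       velocity = "reset")))
  forest <- normalize_fluorescence(sim$forest)
  acc <- fluorescence_accounts(forest)
  res <- sister_pair_differences(forest, acc, "area")
  expect_false(res$insufficient)
  expect_true(all(res$pairs$dFa >= 0))
  # area is a noiseless increasing function of the cell's own fluorescence,
  # so the higher-Fa sister always has the larger area
  expect_true(all(res$pairs$dphenotype[res$pairs$dFa > 0] >= 0))
  expect_equal(res$correlations$tau[res$correlations$grouping == "all"], 1)
})

test_that("sister analysis reports insufficient data below 3 pairs", {
  forest <- make_toy_forest()
  forest <- normalize_fluorescence(forest)
  acc <- fluorescence_accounts(forest)
  res <- sister_pair_differences(forest, acc, "velocity")
  expect_true(res$insufficient)
})

test_that("dividing vs non-dividing comparison computes pFa from group medians", {
  # construct accounts with known rates: dividing {4,6}, non-dividing {1,2,3}
  acc <- data.frame(
    cell_id = paste0("c", 1:5), generation = 0L,
    fate = c("divided", "divided", "incomplete", "incomplete", "incomplete"),
    Fa = 1, Fmc = 1, observation_days = 1,
    Fa_rate = c(4, 6, 1, 2, 3), Fmc_rate = c(4, 6, 1, 2, 3),
    stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = acc$cell_id, cell_type = "SAOS-2",
                      condition = "co-culture", generation = 0L,
                      parent_id = NA_character_, birth_time_h = NA_real_,
                      end_time_h = 48, fate = acc$fate, stringsAsFactors = FALSE)
  forest <- lineage_forest("m", cells, make_toy_forest()$obs[0, ], 2)
  cmp <- compare_dividing_vs_nondividing(forest, acc,
                                         min_window_policy = "none")
  expect_equal(cmp$pFa, 2.5)
  expect_equal(cmp$median_Fa_rate_dividing, 5)
  expect_equal(cmp$median_Fa_rate_nondividing, 2)
  # identical distributions give a ratio of exactly 1
  acc2 <- acc
  acc2$Fa_rate <- c(1, 2, 1, 2, 1.5); acc2$Fmc_rate <- acc2$Fa_rate
  acc2$fate <- c("divided", "divided", "incomplete", "incomplete", "divided")
  cmp2 <- compare_dividing_vs_nondividing(forest, acc2,
                                          min_window_policy = "none")
  expect_equal(cmp2$pFa, 1)
  # scale invariance of the ratio
  acc3 <- acc; acc3$Fa_rate <- acc3$Fa_rate * 17; acc3$Fmc_rate <- acc3$Fmc_rate * 17
  cmp3 <- compare_dividing_vs_nondividing(forest, acc3,
                                          min_window_policy = "none")
  expect_equal(cmp3$pFa, cmp$pFa)
})

test_that("published per-experiment mitosis medians give the printed ratio", {
  # dividing median 66.7, non-dividing 29.9 as printed for one experiment
  expect_equal(round(66.7 / 29.9, 2), 2.23, tolerance = 0.005)
})

test_that("cross-experiment summaries reproduce printed medians and symmetry", {
  t1 <- published_tables("area")
  expect_equal(cross_experiment_summary(t1$tau_fa)$median, 0.54)
  expect_equal(cross_experiment_summary(t1$tau_fmc)$median, 0.45)
  s <- cross_experiment_summary(c(-1, 0, 1))
  expect_equal(s$p_value, 1)
  expect_error(cross_experiment_summary(c(0.1, 0.2)), "at least 3")
})
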