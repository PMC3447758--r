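world_u <- tiny_world(n_rows = 12, n_cols = 12, coarse_block = 3,
                      gradient = 1, noise_sd = 0.4, base = 13, seed = 17)
reps_u <- tiny_replicates(world_u, years = 6, growth_prob = 0.5,
                          jump_rate = 0.6, seed = 21)

test_that("a price sweep with identical settings gives identical impacts", {
  sw <- run_single_parameter(world_u, reps_u, scenario_spec(),
                             "price", c(50.49, 50.49))
  expect_equal(sw$impact_eur[1], sw$impact_eur[2])
})

test_that("the price sweep scales exactly proportionally", {
  sw <- run_single_parameter(world_u, reps_u, scenario_spec(),
                             "price", c(50.49, 67.7))
  expect_equal(sw$impact_eur[2], sw$impact_eur[1] * 67.7 / 50.49)
})

test_that("the threshold sweep is non-increasing in the threshold", {
  sw <- run_single_parameter(world_u, reps_u, scenario_spec(),
                             "threshold", c(18, 19, 20))
  expect_true(all(diff(sw$impact_eur) <= 0))
})

test_that("the mortality sweep is ordered minimum <= default <= maximum", {
  sw <- run_single_parameter(world_u, reps_u, scenario_spec(),
                             "mortality", c("minimum", "default", "maximum"))
  expect_true(all(diff(sw$impact_eur) >= 0))
})

test_that("unknown sweep parameters are rejected", {
  expect_error(run_single_parameter(world_u, reps_u, scenario_spec(),
                                    "humidity", c(1, 2)),
               "unknown parameter")
})

test_that("worst case dominates the base case which dominates the best case", {
  ex <- run_extreme_cases(world_u, reps_u, scenario_spec())
  expect_gte(ex$worst_Meur, ex$base_Meur)
  expect_gte(ex$base_Meur, ex$best_Meur)
  expect_true(all(ex$table$worst_Meur >= ex$table$best_Meur))
  expect_true(all(ex$table$difference_pct >= -1e-9))
})

test_that("worst case dominates every single-parameter setting", {
  ex <- run_extreme_cases(world_u, reps_u, scenario_spec())
  sweeps <- rbind(
    run_single_parameter(world_u, reps_u, scenario_spec(), "spread",
                         c(5, 50, 95)),
    run_single_parameter(world_u, reps_u, scenario_spec(), "threshold",
                         c(18, 19, 20)),
    run_single_parameter(world_u, reps_u, scenario_spec(), "mortality",
                         c("minimum", "default", "maximum")),
    run_single_parameter(world_u, reps_u, scenario_spec(), "price",
                         c(50.49, 67.7))
  )
  expect_true(all(ex$worst_Meur >= sweeps$impact_Meur))
  expect_true(all(ex$best_Meur <= sweeps$impact_Meur))
})

test_that("relative extreme-case impacts equal impact over regional asset value", {
  # 2-region toy world checked by hand
  w2 <- tiny_world(n_rows = 4, n_cols = 4, coarse_block = 2, n_regions = 2,
                   gradient = 0, noise_sd = 0, base = 25, seed = 1)
  r2 <- simulate_spread(w2, entry_cell = c(2, 1), years = 1,
                        growth_prob = 1, jump_rate = 0, n_replicates = 2,
                        seed = 1)
  ex <- run_extreme_cases(w2, r2, scenario_spec())
  stock_val <- tapply(w2$stock$stock_m3, w2$stock$region_id, sum) * 67.7
  expect_equal(ex$table$worst_pct,
               as.numeric(100 * ex$table$worst_Meur * 1e6 / stock_val))
})

test_that("removing a layer never decreases the impact", {
  for (seed in 1:10) {
    w <- tiny_world(gradient = 1, noise_sd = 0.5, base = 13 + seed %% 3,
                    seed = seed)
    r <- tiny_replicates(w, years = 4, growth_prob = 0.5, jump_rate = 0.5,
                         seed = seed + 100)
    base <- evaluate_scenario(w, r, scenario_spec())$total_eur
    no_temp <- run_layer_removal(w, r, scenario_spec(), "no_temperature")$total_eur
    no_spread <- run_layer_removal(w, r, scenario_spec(), "no_spread")$total_eur
    expect_gte(no_temp, base)
    expect_gte(no_spread, base)
  }
})

test_that("in a cold world only the temperature-free mode finds impact", {
  w_cold <- tiny_world(gradient = 0, noise_sd = 0, base = 10, seed = 2)
  r_cold <- tiny_replicates(w_cold, years = 4, seed = 3)
  base <- evaluate_scenario(w_cold, r_cold, scenario_spec())$total_eur
  no_temp <- run_layer_removal(w_cold, r_cold, scenario_spec(),
                               "no_temperature")$total_eur
  expect_equal(base, 0)
  expect_gt(no_temp, 0)
})

test_that("with non-binding constraints both removal modes equal the base", {
  w_hot <- tiny_world(gradient = 0, noise_sd = 0, base = 30, seed = 2)
  # fully invaded world: deterministic saturating spread
  r_hot <- simulate_spread(w_hot, entry_cell = c(2, 2), years = 10,
                           growth_prob = 1, jump_rate = 0,
                           n_replicates = 2, seed = 1)
  base <- evaluate_scenario(w_hot, r_hot, scenario_spec())$total_eur
  no_temp <- run_layer_removal(w_hot, r_hot, scenario_spec(),
                               "no_temperature")$total_eur
  no_spread <- run_layer_removal(w_hot, r_hot, scenario_spec(),
                                 "no_spread")$total_eur
  expect_equal(no_temp, base)
  expect_equal(no_spread, base)
})

test_that("fine-resolution totals are consistent with their per-region table", {
  spec_f <- scenario_spec(resolution = "fine")
  ev <- evaluate_scenario(world_u, reps_u, spec_f)
  expect_s3_class(ev$table, "direct_impact_table")
  expect_equal(ev$total_eur, sum(ev$table$impact_eur))
})
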