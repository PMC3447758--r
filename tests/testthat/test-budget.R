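test_that("the polygon partial budget matches hand arithmetic", {
  mort <- mortality_table("default")
  # all factors 1: 1.0 mortality on 100 m3 at 50 EUR/m3
  di <- direct_impact(1, one_class_stock(100), mort, price = 50)
  expect_equal(di$value, 5000)
  expect_equal(di$volume, 100)
  # indicator annihilates regardless of stock
  expect_equal(direct_impact(0, one_class_stock(1e9), mort, 50)$value, 0)
  # 0.5 exposure, single class with m = 0.8, 1000 m3, 50 EUR/m3
  s <- one_class_stock(1000, age = "young", susceptibility = "intermediate")
  expect_equal(direct_impact(0.5, s, mort, 50)$value, 0.5 * 0.8 * 1000 * 50)
})

test_that("invalid budget inputs are rejected", {
  mort <- mortality_table()
  expect_error(direct_impact(1, one_class_stock(100), mort, price = 0), "price")
  expect_error(direct_impact(1, one_class_stock(-5), mort, 50), "stock")
  expect_error(direct_impact(1.2, one_class_stock(5), mort, 50), "exposure")
})

test_that("mortality presets hold the literature rates and order correctly", {
  d <- mortality_table("default")
  expect_equal(as.numeric(d["young", ]), c(1.00, 0.80, 0.50))
  expect_equal(as.numeric(d["old", ]), c(0.90, 0.70, 0.40))
  mn <- mortality_table("minimum")
  expect_equal(as.numeric(mn["young", ]), c(0.60, 0.60, 0.40))
  expect_equal(as.numeric(mn["old", ]), c(0.50, 0.50, 0.40))
  mx <- mortality_table("maximum")
  expect_equal(as.numeric(mx["young", ]), c(1.00, 1.00, 0.50))
  expect_equal(as.numeric(mx["old", ]), c(0.90, 0.90, 0.50))
  expect_error(mortality_table(matrix(2, 2, 3)), "0, 1")
})

test_that("totals sum regional impacts and an empty table totals zero", {
  expect_equal(total_impact(c(30, 6106, 20645, 1084)), 27865)
  empty <- data.frame(impact_eur = numeric(0))
  expect_equal(total_impact(empty), 0)
})

test_that("direct impact is linear in price and in every stock entry", {
  w <- tiny_world(gradient = 1, noise_sd = 0, base = 14, seed = 3)
  occ <- matrix(FALSE, 4, 4); occ[3:4, 1:2] <- TRUE
  t1 <- direct_impact_table(w, occ, price = 50.49)
  t2 <- direct_impact_table(w, occ, price = 100.98)
  expect_equal(t2$impact_eur, 2 * t1$impact_eur)
  # doubling all stock doubles the impact
  w2 <- w; w2$stock$stock_m3 <- 2 * w$stock$stock_m3
  t3 <- direct_impact_table(w2, occ, price = 50.49)
  expect_equal(t3$impact_eur, 2 * t1$impact_eur)
  expect_equal(scale_by_price(total_impact(t1), 100.98, 50.49),
               total_impact(t2))
})

test_that("impact is monotone in exposure, mortality and (inversely) threshold", {
  mort <- mortality_table()
  s <- one_class_stock(1000)
  vals <- vapply(seq(0, 1, 0.25), function(r)
    direct_impact(r, s, mort, 50)$value, numeric(1))
  expect_true(all(diff(vals) >= 0))

  w <- tiny_world(gradient = 1, noise_sd = 0.3, base = 14, seed = 8)
  occ <- matrix(FALSE, 4, 4); occ[3:4, ] <- TRUE
  totals_th <- vapply(c(18, 19, 20, 22), function(th)
    total_impact(direct_impact_table(w, occ, threshold = th,
                                     resolution = "fine")), numeric(1))
  expect_true(all(diff(totals_th) <= 0))

  for (res in c("coarse", "fine")) {
    by_preset <- vapply(c("minimum", "default", "maximum"), function(p)
      total_impact(direct_impact_table(w, occ, mortality_table(p),
                                       resolution = res)), numeric(1))
    expect_true(all(diff(by_preset) >= 0))
  }
})

test_that("coarse and fine pipelines agree when block = 1 and regions are thermally uniform", {
  # 2-row regions, temperature constant within each region band
  w <- tiny_world(n_rows = 8, n_cols = 8, coarse_block = 1, n_regions = 4,
                  gradient = 0, noise_sd = 0, base = 20, seed = 2)
  # region bands get distinct uniform temperatures straddling the threshold
  for (i in 1:4)
    w$temperature[w$region == i] <- c(18, 19.5, 21, 23)[i]
  set.seed(31)
  occ <- matrix(runif(64) < 0.4, 8, 8)
  tc <- direct_impact_table(w, occ, resolution = "coarse")
  tf <- direct_impact_table(w, occ, resolution = "fine")
  expect_equal(tf$impact_eur, tc$impact_eur, tolerance = 1e-12)
})

test_that("the impact series is cumulative, with marginal as first difference", {
  w <- tiny_world(gradient = 1, noise_sd = 0, base = 14, seed = 3)
  # static occupancy over 3 years
  occ0 <- matrix(FALSE, 4, 4); occ0[4, 1] <- TRUE
  static <- array(occ0, dim = c(4, 4, 3))
  ser <- impact_series(static, w, years = 2008:2010)
  expect_equal(ser$marginal_eur, c(ser$cumulative_eur[1], 0, 0))
  expect_true(all(diff(ser$cumulative_eur) >= 0))
  # empty occupancy: all zeros
  ser0 <- impact_series(array(FALSE, c(4, 4, 3)), w)
  expect_true(all(ser0$cumulative_eur == 0))
  expect_true(all(ser0$marginal_eur == 0))
})

test_that("a year-two invasion of a new region adds exactly that region's value", {
  w <- tiny_world(gradient = 1, noise_sd = 0, base = 14, seed = 3)
  occ <- array(FALSE, c(4, 4, 2))
  occ[4, 1, 1:2] <- TRUE
  occ[4, 4, 2] <- TRUE                         # second cell appears in year 2
  ser <- impact_series(occ, w)
  t1 <- total_impact(direct_impact_table(w, occ[, , 1]))
  t2 <- total_impact(direct_impact_table(w, occ[, , 2]))
  expect_equal(ser$cumulative_eur, c(t1, t2))
  expect_equal(ser$marginal_eur[2], t2 - t1)
  expect_gte(ser$marginal_eur[2], 0)
})

test_that("non-monotone occupancy is rejected", {
  w <- tiny_world()
  occ <- array(FALSE, c(4, 4, 2))
  occ[1, 1, 1] <- TRUE                          # disappears in year 2
  expect_error(impact_series(occ, w), "monotone")
})

test_that("price rescaling is proportional, identity at equal prices", {
  expect_equal(scale_by_price(100, 25, 50), 50)
  expect_equal(scale_by_price(123.4, 7, 7), 123.4)
  expect_error(scale_by_price(1, -1, 5), "> 0")
})
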