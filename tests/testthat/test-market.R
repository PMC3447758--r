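mkt <- roundwood_market()

test_that("calibration reproduces every baseline quantity exactly", {
  b <- mkt$baseline
  expect_equal(mkt$mu, -4.01)
  expect_equal(market_demand(mkt, b$P0), b$D0)
  expect_equal(market_supply(mkt, b$P0), b$S0)
  expect_equal(market_net_imports(mkt, b$P0), b$D0 - b$S0)
  expect_equal(unname(coef(mkt)["mu"]), b$P0 - b$WP0)
})

test_that("a balanced-trade baseline cannot be calibrated", {
  expect_error(roundwood_market(roundwood_baseline(production = 249101,
                                                   consumption = 249101)),
               "degenerate")
})

test_that("the zero shock is a fixed point reproducing the baseline", {
  st <- solve_equilibrium(mkt, supply_shock(0))
  b <- mkt$baseline
  expect_equal(st$P, b$P0)
  expect_equal(st$D, b$D0)
  expect_equal(st$S, b$S0)
  expect_lt(st$residual, 1e-9)
})

test_that("the solver matches a fine grid-search oracle", {
  shock <- supply_shock(0.0329)
  st <- solve_equilibrium(mkt, shock)
  expect_lt(st$residual, 1e-9)
  # brute-force oracle: minimise |clearing| over a 0.001-step price grid
  b <- mkt$baseline
  grid <- seq(b$P0, b$P0 + 5, by = 0.001)
  resid <- abs(market_supply(mkt, grid) * (1 - shock$x) +
                 market_net_imports(mkt, grid) - market_demand(mkt, grid))
  p_oracle <- grid[which.min(resid)]
  expect_lt(abs(st$P - p_oracle), 0.001)
  expect_gt(st$P, 51.9)
  expect_lt(st$P, 52.3)
})

test_that("the clearing residual changes sign exactly once on the bracket", {
  b <- mkt$baseline
  shock <- supply_shock(0.0329)
  grid <- seq(b$P0 / 2, 4 * b$P0, length.out = 1000)
  g <- market_supply(mkt, grid) * (1 - shock$x) +
    market_net_imports(mkt, grid) - market_demand(mkt, grid)
  expect_equal(sum(diff(sign(g)) != 0), 1)
})

test_that("price rises and demand falls monotonically with the shock", {
  xs <- seq(0, 0.05, by = 0.01)
  states <- lapply(xs, function(x) solve_equilibrium(mkt, supply_shock(x)))
  P <- vapply(states, `[[`, numeric(1), "P")
  D <- vapply(states, `[[`, numeric(1), "D")
  expect_true(all(diff(P) > 0))
  expect_true(all(diff(D) < 0))
})

test_that("every solved equilibrium clears the market", {
  for (x in c(0.01, 0.0329, 0.2)) {
    st <- solve_equilibrium(mkt, supply_shock(x))
    expect_lt(abs(st$S + st$imports - st$D) / st$D, 1e-9)
    expect_equal(st$WP, st$P - mkt$mu)
  }
})

test_that("consumer surplus closed form matches numerical integration", {
  p0 <- mkt$baseline$P0
  for (p1 in c(p0, p0 + 1.44, p0 + 2.40, p0 - 3)) {
    d_cs <- consumer_surplus_change(mkt, p0, p1)
    if (p1 == p0) {
      expect_equal(d_cs, 0)
      next
    }
    # trapezoid oracle on 1e4 panels
    ps <- seq(p0, p1, length.out = 1e4 + 1)
    dem <- market_demand(mkt, ps)
    num <- -sum((dem[-1] + dem[-length(dem)]) / 2 * diff(ps)) / 1000
    expect_equal(d_cs, num, tolerance = 1e-6)
  }
})

test_that("log-form consumer surplus at unit elasticity matches integration", {
  m1 <- roundwood_market(roundwood_baseline(demand_elasticity = -1))
  p0 <- m1$baseline$P0; p1 <- p0 + 2
  d_cs <- consumer_surplus_change(m1, p0, p1)
  ps <- seq(p0, p1, length.out = 1e4 + 1)
  dem <- market_demand(m1, ps)
  num <- -sum((dem[-1] + dem[-length(dem)]) / 2 * diff(ps)) / 1000
  expect_equal(d_cs, num, tolerance = 1e-6)
})

test_that("producer surplus closed form matches integrating the shifted curve", {
  shock <- supply_shock(0.0329)
  st <- solve_equilibrium(mkt, shock)
  d_ps <- producer_surplus_change(mkt, st)
  # oracle: PS is the area between the price line and the inverse supply
  # curve, i.e. integral_0^P S(p) dp for a curve through the origin
  b <- mkt$baseline
  shifted <- function(p) market_supply(mkt, p) * (1 - shock$x)
  ps_int <- function(curve, P) {
    ps <- seq(1e-9, P, length.out = 2e5 + 1)
    q <- curve(ps)
    sum((q[-1] + q[-length(q)]) / 2 * diff(ps))
  }
  num <- (ps_int(shifted, st$P) -
            ps_int(function(p) market_supply(mkt, p), b$P0)) / 1000
  expect_equal(d_ps, num, tolerance = 1e-6)
})

test_that("welfare is the exact sum of its parts and zero at no shock", {
  w <- welfare_change(-357, 139)
  expect_identical(w$total, -357 + 139)
  expect_equal(welfare_change(-597, 228)$total, -369)
  st0 <- solve_equilibrium(mkt, supply_shock(0))
  w0 <- equilibrium_welfare(mkt, st0)
  expect_equal(w0$total, 0)
})

test_that("the flow rule converts accumulated losses into shocks linearly", {
  expect_equal(shock_from_cumulative_loss(0, 50.49)$x, 0)
  s1 <- shock_from_cumulative_loss(22375, 50.49)
  expect_equal(s1$x, 0.018 * (22375 * 1000 / 50.49) / 242528)
  expect_equal(s1$x, 0.0329, tolerance = 0.002)
  s2 <- shock_from_cumulative_loss(2 * 22375, 50.49)
  expect_equal(s2$x, 2 * s1$x)
  expect_error(shock_from_cumulative_loss(1e9, 50.49), ">= 100%")
})

test_that("shock decomposition must be consistent and nu requires it", {
  s <- supply_shock(z = 0.5, h = 0.2)
  expect_equal(s$x, 0.1)
  expect_error(supply_shock(0.3, z = 0.5, h = 0.2), "inconsistent")
  expect_error(supply_shock(0.1, nu = 0.05), "decomposition")
  # decomposed shock with nu = 0 equals the aggregate shock
  st_agg <- solve_equilibrium(mkt, supply_shock(0.1))
  st_dec <- solve_equilibrium(mkt, supply_shock(z = 0.5, h = 0.2))
  expect_equal(st_dec$P, st_agg$P)
  expect_equal(st_dec$SA + st_dec$SN, st_dec$S)
})

test_that("welfare loss magnitude grows with the shock", {
  xs <- c(0.005, 0.01, 0.02, 0.0329, 0.05)
  w <- vapply(xs, function(x) {
    st <- solve_equilibrium(mkt, supply_shock(x))
    equilibrium_welfare(mkt, st)$total
  }, numeric(1))
  expect_true(all(diff(abs(w)) > 0))
  expect_true(all(w < 0))
})

test_that("the yearly welfare series matches one-shot solves and is monotone", {
  cum <- c(0, 2000, 8000, 15000, 22375) * 1e6        # EUR
  impact <- data.frame(year = 2026:2030, cumulative_eur = cum)
  series <- annual_welfare_series(impact, mkt)
  expect_equal(nrow(series), 5)
  expect_equal(series$welfare_Meur[1], 0)
  # single-year consistency
  st <- solve_equilibrium(mkt, shock_from_cumulative_loss(22375, 50.49))
  expect_equal(series$welfare_Meur[5], equilibrium_welfare(mkt, st)$total)
  expect_true(all(diff(abs(series$welfare_Meur)) >= 0))
  # all-zero series gives all-zero welfare
  zero <- data.frame(year = 1:3, cumulative_eur = c(0, 0, 0))
  expect_true(all(annual_welfare_series(zero, mkt)$welfare_Meur == 0))
  bad <- data.frame(year = 1:2, cumulative_eur = c(5, 1))
  expect_error(annual_welfare_series(bad, mkt), "non-decreasing")
})

test_that("the outcome table accepts published price/supply overrides", {
  tb <- market_welfare_table(mkt, price_change = 1.44, supply_change = -1890)
  got <- setNames(tb$absolute, tb$quantity)
  expect_equal(unname(got["price_eur_per_m3"]), 1.44)
  expect_equal(unname(got["supply_thousand_m3"]), -1890)
  expect_equal(unname(got["total_welfare_Meur"]),
               unname(got["consumer_surplus_Meur"] +
                        got["producer_surplus_Meur"]))
  # zero shock: all change columns zero
  tb0 <- market_welfare_table(mkt, supply_shock(0))
  expect_true(all(abs(tb0$absolute) < 1e-6))
  expect_error(market_welfare_table(mkt, price_change = 1), "together")
})
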