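#' Baseline of the EU industrial round-wood market
#'
#' The observed pre-invasion market state and elasticities to which the
#' partial-equilibrium model is calibrated. Defaults are the EU conifer
#' industrial round-wood baseline: production 242,528 and consumption
#' 249,101 thousand m3, producer price 50.49 and world price 54.5 EUR/m3,
#' supply elasticity 0.8, demand elasticity -0.11, excess-supply (import)
#' elasticity 6.07, and a yearly harvest flow of 1.8% of standing stock.
#'
#' @param production Baseline EU supply S0, thousand m3.
#' @param consumption Baseline EU demand D0, thousand m3.
#' @param producer_price Baseline EU price P0, EUR/m3.
#' @param world_price Baseline world price WP0, EUR/m3.
#' @param supply_elasticity theta (> 0).
#' @param demand_elasticity eta (< 0).
#' @param trade_elasticity omega (> 0), elasticity of excess supply from
#'   the rest of the world with respect to the world price.
#' @param flow_fraction Yearly removals as a fraction of standing stock
#'   (the rule converting an accumulated stock loss into a yearly supply
#'   reduction).
#' @return An object of class `market_baseline`.
#' @export
roundwood_baseline <- function(production = 242528, consumption = 249101,
                               producer_price = 50.49, world_price = 54.5,
                               supply_elasticity = 0.8,
                               demand_elasticity = -0.11,
                               trade_elasticity = 6.07,
                               flow_fraction = 0.018) {
  if (production <= 0 || consumption <= 0 || producer_price <= 0 ||
      world_price <= 0)
    stop("quantities and prices must be > 0", call. = FALSE)
  if (supply_elasticity <= 0) stop("supply elasticity must be > 0", call. = FALSE)
  if (demand_elasticity >= 0) stop("demand elasticity must be < 0", call. = FALSE)
  if (trade_elasticity <= 0) stop("trade elasticity must be > 0", call. = FALSE)
  if (flow_fraction <= 0 || flow_fraction >= 1)
    stop("flow_fraction must lie in (0, 1)", call. = FALSE)
  structure(
    list(S0 = production, D0 = consumption, P0 = producer_price,
         WP0 = world_price, theta = supply_elasticity,
         eta = demand_elasticity, omega = trade_elasticity,
         flow_fraction = flow_fraction),
    class = "market_baseline"
  )
}

#' Calibrate the partial-equilibrium round-wood market model
#'
#' Fits the scale parameters of a constant-elasticity (log-linear) system
#' so every curve reproduces the baseline exactly:
#' demand `D(P) = chi * P^eta`, domestic supply `S(P) = beta * P^theta`,
#' EU and world prices linearly related by an additive wedge
#' `P = WP + mu`, and net imports `M(WP) = upsilon * WP^omega`
#' (EU net trade `X = S - D = -M`). Calibration gives
#' `chi = D0 / P0^eta`, `beta = S0 / P0^theta`, `mu = P0 - WP0` and
#' `upsilon = (D0 - S0) / WP0^omega`, the sign of `upsilon` carrying the
#' baseline trade direction.
#'
#' @param baseline A [roundwood_baseline()].
#' @return A fitted model object of class `pe_market` with components
#'   `baseline`, `chi`, `beta`, `upsilon`, `mu`. Use [predict.pe_market()]
#'   / [solve_equilibrium()] to obtain post-shock equilibria and
#'   [coef.pe_market()] for the calibrated scale parameters.
#' @examples
#' mkt <- roundwood_market()
#' coef(mkt)
#' predict(mkt, supply_shock(0.0329))
#' @export
roundwood_market <- function(baseline = roundwood_baseline()) {
  stopifnot(inherits(baseline, "market_baseline"))
  if (baseline$D0 == baseline$S0)
    stop("degenerate trade calibration: baseline consumption equals production",
         call. = FALSE)
  chi <- baseline$D0 / baseline$P0^baseline$eta
  beta <- baseline$S0 / baseline$P0^baseline$theta
  mu <- baseline$P0 - baseline$WP0
  upsilon <- (baseline$D0 - baseline$S0) / baseline$WP0^baseline$omega
  structure(list(baseline = baseline, chi = chi, beta = beta,
                 upsilon = upsilon, mu = mu),
            class = "pe_market")
}

#' @export
coef.pe_market <- function(object, ...) {
  c(chi = object$chi, beta = object$beta, upsilon = object$upsilon,
    mu = object$mu)
}

#' @export
print.pe_market <- function(x, ...) {
  b <- x$baseline
  cat("Calibrated partial-equilibrium round-wood market\n")
  cat(sprintf("  baseline: S0 = %s, D0 = %s thousand m3, P0 = %.2f, WP0 = %.2f EUR/m3\n",
              format(b$S0, big.mark = ","), format(b$D0, big.mark = ","),
              b$P0, b$WP0))
  cat(sprintf("  elasticities: demand %.2f, supply %.2f, excess supply %.2f\n",
              b$eta, b$theta, b$omega))
  cat(sprintf("  scale parameters: chi = %.6g, beta = %.6g, upsilon = %.6g, mu = %.4g\n",
              x$chi, x$beta, x$upsilon, x$mu))
  invisible(x)
}

#' @export
summary.pe_market <- function(object, ...) {
  base <- solve_equilibrium(object, supply_shock(0))
  structure(list(market = object, baseline_state = base),
            class = "summary.pe_market")
}

#' @export
print.summary.pe_market <- function(x, ...) {
  print(x$market)
  cat(sprintf("  zero-shock check: P = %.4f, clearing residual %.3g (relative)\n",
              x$baseline_state$P, x$baseline_state$residual))
  invisible(x)
}

#' @rdname roundwood_market
#' @param P Price(s) at which to evaluate a curve, EUR/m3.
#' @param market A `pe_market`.
#' @export
market_demand <- function(market, P) market$chi * P^market$baseline$eta

#' @rdname roundwood_market
#' @export
market_supply <- function(market, P) market$beta * P^market$baseline$theta

#' @rdname roundwood_market
#' @export
market_net_imports <- function(market, P)
  market$upsilon * (P - market$mu)^market$baseline$omega

#' A proportional supply shock from pest-killed stock
#'
#' Describes the downward shift of domestic supply. The aggregate
#' proportional loss `x` may optionally be decomposed into the proportion
#' of producers affected `z` and their proportional wood loss `h`
#' (`x = z * h`); `nu` is a proportional production-cost increase for
#' affected producers (0 by default: mitigation costs are out of scope).
#'
#' @param x Aggregate proportional supply loss in `[0, 1)`.
#' @param nu Proportional cost increase for affected producers, `[0, 1)`;
#'   requires `z` and `h` when positive.
#' @param z,h Optional decomposition (`x = z * h` enforced to 1e-9).
#' @return An object of class `supply_shock`.
#' @export
supply_shock <- function(x = 0, nu = 0, z = NULL, h = NULL) {
  if (!is.null(z) && !is.null(h)) {
    if (abs(x) < 1e-15) x <- z * h
    if (abs(x - z * h) > 1e-9)
      stop("inconsistent shock decomposition: x != z * h", call. = FALSE)
  }
  if (x < 0 || x >= 1) stop("x must lie in [0, 1)", call. = FALSE)
  if (nu < 0 || nu >= 1) stop("nu must lie in [0, 1)", call. = FALSE)
  if (nu > 0 && (is.null(z) || is.null(h)))
    stop("nu > 0 requires the (z, h) decomposition", call. = FALSE)
  structure(list(x = x, nu = nu, z = z, h = h), class = "supply_shock")
}

#' Convert an accumulated stock loss into a yearly supply shock
#'
#' Applies the harvest-flow rule: the yearly supply reduction equals the
#' flow fraction (default 1.8%) of the stock volume accumulated as lost
#' up to that year. The lost volume is the cumulative lost value divided
#' by the round-wood price.
#'
#' @param cumulative_value Accumulated direct loss, M EUR.
#' @param price Round-wood price used to convert value to volume, EUR/m3.
#' @param baseline A [roundwood_baseline()].
#' @return A [supply_shock()] with
#'   `x = flow_fraction * (cumulative_value * 1000 / price) / S0`.
#' @examples
#' shock_from_cumulative_loss(22375, 50.49, roundwood_baseline())
#' @export
shock_from_cumulative_loss <- function(cumulative_value, price,
                                       baseline = roundwood_baseline()) {
  stopifnot(inherits(baseline, "market_baseline"))
  if (cumulative_value < 0)
    stop("cumulative loss must be >= 0", call. = FALSE)
  if (price <= 0) stop("price must be > 0", call. = FALSE)
  lost_volume <- cumulative_value * 1000 / price     # thousand m3
  x <- baseline$flow_fraction * lost_volume / baseline$S0
  if (x >= 1)
    stop("supply shock >= 100% of baseline production", call. = FALSE)
  supply_shock(x)
}

# shifted-supply multiplier: S(P) = beta * P^theta * supply_multiplier
supply_multiplier <- function(shock, theta) {
  if (shock$nu > 0) {
    (1 - shock$z) + shock$z * (1 - shock$h) * (1 - shock$nu)^theta
  } else 1 - shock$x
}

#' Solve the post-shock market equilibrium
#'
#' Finds the EU price `P` clearing the market: shifted domestic supply
#' plus net imports (an increasing function of the world price
#' `WP = P - mu`) equals demand. The clearing function is strictly
#' monotone in `P`, so the root in the bracket `[P0/2, 4 P0]` is unique.
#' A zero shock returns the baseline state exactly.
#'
#' @param market A `pe_market`.
#' @param shock A [supply_shock()].
#' @return An object of class `pe_equilibrium`: `P`, `WP`, `D`, `S`
#'   (domestic supply), `SA`/`SN` (affected / non-affected components,
#'   populated when the shock is decomposed), `imports` (net imports),
#'   `X` (net trade S - D), `residual` (relative clearing residual) and
#'   the `shock`.
#' @export
solve_equilibrium <- function(market, shock = supply_shock(0)) {
  stopifnot(inherits(market, "pe_market"), inherits(shock, "supply_shock"))
  b <- market$baseline
  mult <- supply_multiplier(shock, b$theta)

  state_at <- function(P) {
    S <- market$beta * P^b$theta * mult
    D <- market$chi * P^b$eta
    M <- market$upsilon * (P - market$mu)^b$omega
    list(P = P, WP = P - market$mu, S = S, D = D, imports = M, X = S - D,
         residual = abs(S + M - D) / D)
  }

  if (shock$x == 0 && shock$nu == 0) {
    st <- list(P = b$P0, WP = b$WP0, S = b$S0, D = b$D0,
               imports = b$D0 - b$S0, X = b$S0 - b$D0, residual = 0)
  } else {
    clearing <- function(P) {
      market$beta * P^b$theta * mult +
        market$upsilon * (P - market$mu)^b$omega -
        market$chi * P^b$eta
    }
    lo <- b$P0 / 2
    hi <- 4 * b$P0
    if (clearing(lo) * clearing(hi) > 0)
      stop(sprintf(
        "no sign change in bracket [%.2f, %.2f]; residuals %.4g / %.4g",
        lo, hi, clearing(lo), clearing(hi)), call. = FALSE)
    root <- uniroot(clearing, c(lo, hi), tol = 1e-12)
    st <- state_at(root$root)
  }

  SA <- SN <- NA_real_
  if (!is.null(shock$z) && !is.null(shock$h)) {
    SN <- (1 - shock$z) * market$beta * st$P^b$theta
    SA <- st$S - SN
  }
  structure(c(st, list(SA = SA, SN = SN, shock = shock)),
            class = "pe_equilibrium")
}

#' @export
predict.pe_market <- function(object, shock = supply_shock(0), ...) {
  solve_equilibrium(object, shock)
}

#' @export
print.pe_equilibrium <- function(x, ...) {
  cat("Round-wood market equilibrium\n")
  cat(sprintf("  shock x = %.4g, nu = %.4g\n", x$shock$x, x$shock$nu))
  cat(sprintf("  P = %.3f EUR/m3 (WP = %.3f), D = %.0f, S = %.0f, net imports = %.0f thousand m3\n",
              x$P, x$WP, x$D, x$S, x$imports))
  cat(sprintf("  clearing residual %.3g (relative)\n", x$residual))
  invisible(x)
}

#' Consumer-surplus change between two prices
#'
#' The change in consumer surplus along the calibrated demand curve,
#' `-(integral of chi p^eta dp)` from the old to the new price; negative
#' when the price rises. The closed form uses the power antiderivative,
#' switching to the logarithmic form at `eta = -1`. Because the absolute
#' surplus integral diverges for inelastic demand, only changes between
#' two prices are reported.
#'
#' @param market A `pe_market`.
#' @param p_before,p_after Prices, EUR/m3.
#' @return Surplus change in M EUR (quantities are thousand m3, so the
#'   price integral is in thousand EUR and is divided by 1000).
#' @export
consumer_surplus_change <- function(market, p_before, p_after) {
  if (p_before <= 0 || p_after <= 0)
    stop("prices must be > 0", call. = FALSE)
  eta <- market$baseline$eta
  integral <- if (abs(eta + 1) < 1e-12) {
    market$chi * (log(p_after) - log(p_before))
  } else {
    market$chi * (p_after^(1 + eta) - p_before^(1 + eta)) / (1 + eta)
  }
  -integral / 1000
}

#' Producer-surplus change between baseline and a post-shock state
#'
#' For a constant-elasticity supply curve passing through `(P, S)` with
#' elasticity theta, producer surplus is `S * P / (1 + theta)` (the area
#' between price and the inverse supply curve). The change is evaluated
#' between the baseline `(P0, S0)` and the post-shock state, whose
#' domestic supply lies on the shifted curve.
#'
#' @param market A `pe_market`.
#' @param state_after A `pe_equilibrium`, or a list with elements `P` and
#'   `S` (post-shock price and domestic supply, thousand m3).
#' @param shock Optional [supply_shock()] kept for interface symmetry;
#'   the shift is already embodied in `state_after`.
#' @return Surplus change in M EUR.
#' @export
producer_surplus_change <- function(market, state_after, shock = NULL) {
  b <- market$baseline
  ps_after <- state_after$S * state_after$P / (1 + b$theta)
  ps_before <- b$S0 * b$P0 / (1 + b$theta)
  (ps_after - ps_before) / 1000
}

#' Total welfare change
#'
#' @param d_cs,d_ps Consumer and producer surplus changes, M EUR.
#' @return Object of class `welfare_change` with `consumer`, `producer`
#'   and `total = consumer + producer` (M EUR).
#' @export
welfare_change <- function(d_cs, d_ps) {
  structure(list(consumer = d_cs, producer = d_ps, total = d_cs + d_ps),
            class = "welfare_change")
}

#' @export
print.welfare_change <- function(x, ...) {
  cat(sprintf("Welfare change: consumers %+.1f, producers %+.1f, total %+.1f M EUR\n",
              x$consumer, x$producer, x$total))
  invisible(x)
}

#' Welfare change implied by one equilibrium state
#'
#' @param market A `pe_market`.
#' @param state A `pe_equilibrium` from [solve_equilibrium()].
#' @return A [welfare_change()].
#' @export
equilibrium_welfare <- function(market, state) {
  d_cs <- consumer_surplus_change(market, market$baseline$P0, state$P)
  d_ps <- producer_surplus_change(market, state)
  welfare_change(d_cs, d_ps)
}

#' Yearly welfare series from a cumulative direct-impact series
#'
#' For each year, converts the accumulated direct loss into a supply
#' shock via the harvest-flow rule, solves the equilibrium, and computes
#' the welfare change against the no-invasion baseline. With a monotone
#' cumulative series the welfare-loss magnitude is non-decreasing.
#'
#' @param impact An [impact_series()] (or data frame with `year` and
#'   `cumulative_eur`).
#' @param market A `pe_market`.
#' @param price Price converting lost value to volume, EUR/m3; defaults
#'   to the baseline producer price.
#' @return Data frame: year, x, price_eur, consumer_Meur, producer_Meur,
#'   welfare_Meur.
#' @export
annual_welfare_series <- function(impact, market,
                                  price = market$baseline$P0) {
  if (is.unsorted(impact$cumulative_eur))
    stop("cumulative impact series must be non-decreasing", call. = FALSE)
  n <- nrow(impact)
  out <- data.frame(year = impact$year, x = numeric(n),
                    price_eur = numeric(n), consumer_Meur = numeric(n),
                    producer_Meur = numeric(n), welfare_Meur = numeric(n))
  for (i in seq_len(n)) {
    shock <- shock_from_cumulative_loss(impact$cumulative_eur[i] / 1e6,
                                        price, market$baseline)
    st <- solve_equilibrium(market, shock)
    w <- equilibrium_welfare(market, st)
    out$x[i] <- shock$x
    out$price_eur[i] <- st$P
    out$consumer_Meur[i] <- w$consumer
    out$producer_Meur[i] <- w$producer
    out$welfare_Meur[i] <- w$total
  }
  out
}

#' Market outcome table for one shock (absolute and percent changes)
#'
#' Mirrors the standard reporting layout: supply, demand, price, net
#' trade, consumer surplus, producer surplus and total welfare, each as
#' an absolute change from baseline and as a percentage. Either solves
#' the equilibrium for a given shock, or — to reproduce worked examples
#' from published price and supply changes — accepts direct overrides of
#' the post-shock price change and domestic supply change.
#'
#' Percent denominators: baseline quantities for supply/demand/price,
#' baseline net trade magnitude for trade, and the baseline surplus
#' proxies `D0 P0 / (1 + eta)` and `S0 P0 / (1 + theta)` for the surplus
#' rows (the welfare row uses their sum).
#'
#' @param market A `pe_market`.
#' @param shock A [supply_shock()]; ignored when overrides are supplied.
#' @param price_change Override: post-shock price minus baseline, EUR/m3.
#' @param supply_change Override: post-shock domestic supply minus
#'   baseline, thousand m3.
#' @return Data frame with columns quantity, absolute, percent, plus the
#'   post-shock state in attribute `"state"`.
#' @examples
#' mkt <- roundwood_market()
#' market_welfare_table(mkt, price_change = 1.44, supply_change = -1890)
#' @export
market_welfare_table <- function(market, shock = supply_shock(0),
                                 price_change = NULL, supply_change = NULL) {
  b <- market$baseline
  if (!is.null(price_change) || !is.null(supply_change)) {
    if (is.null(price_change) || is.null(supply_change))
      stop("price_change and supply_change overrides must be given together",
           call. = FALSE)
    P1 <- b$P0 + price_change
    S1 <- b$S0 + supply_change
    D1 <- market_demand(market, P1)
    state <- list(P = P1, WP = P1 - market$mu, S = S1, D = D1,
                  imports = D1 - S1, X = S1 - D1)
  } else {
    state <- solve_equilibrium(market, shock)
  }
  d_cs <- consumer_surplus_change(market, b$P0, state$P)
  d_ps <- producer_surplus_change(market, state)
  X0 <- b$S0 - b$D0
  cs_base <- b$D0 * b$P0 / (1 + b$eta) / 1000
  ps_base <- b$S0 * b$P0 / (1 + b$theta) / 1000
  abs_change <- c(state$S - b$S0, state$D - b$D0, state$P - b$P0,
                  state$X - X0, d_cs, d_ps, d_cs + d_ps)
  pct <- 100 * abs_change /
    c(b$S0, b$D0, b$P0, abs(X0), cs_base, ps_base, cs_base + ps_base)
  out <- data.frame(
    quantity = c("supply_thousand_m3", "demand_thousand_m3",
                 "price_eur_per_m3", "net_trade_thousand_m3",
                 "consumer_surplus_Meur", "producer_surplus_Meur",
                 "total_welfare_Meur"),
    absolute = abs_change,
    percent = pct
  )
  attr(out, "state") <- state
  out
}
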