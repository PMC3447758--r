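#' Scenario specification for the direct-impact assessment
#'
#' Collects the assumptions that the uncertainty analyses vary: the
#' spread percentile, the disease-expression temperature threshold, the
#' mortality preset, the round-wood price, the two layer flags, and the
#' spatial resolution.
#'
#' @param q Spread percentile in `[0, 100]` (5 / 50 / 95 are the
#'   conventional settings).
#' @param threshold Temperature threshold, degC (18 / 19 / 20 studied).
#' @param mortality Mortality preset name or 2 x 3 matrix (see
#'   [mortality_table()]).
#' @param price Round-wood price, EUR/m3.
#' @param use_temperature,use_spread Layer flags for the data-layer
#'   removal analysis.
#' @param resolution `"coarse"` or `"fine"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(q = 50, threshold = 20, mortality = "default",
                          price = 50.49, use_temperature = TRUE,
                          use_spread = TRUE,
                          resolution = c("coarse", "fine")) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (price <= 0) stop("price must be > 0", call. = FALSE)
  structure(list(q = q, threshold = threshold, mortality = mortality,
                 price = price, use_temperature = use_temperature,
                 use_spread = use_spread,
                 resolution = match.arg(resolution)),
            class = "scenario_spec")
}

#' Evaluate one scenario's total direct impact
#'
#' @param world A `pwn_world`.
#' @param reps A `spread_replicates` set.
#' @param spec A [scenario_spec()].
#' @return List with `total_eur`, `total_Meur` and the per-region
#'   `table` ([direct_impact_table()]).
#' @export
evaluate_scenario <- function(world, reps, spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  series <- select_percentile_replicate(reps, spec$q)
  occ <- series$occupancy[, , dim(series$occupancy)[3]]
  tab <- direct_impact_table(world, occ,
                             mortality = mortality_table(spec$mortality),
                             price = spec$price, threshold = spec$threshold,
                             resolution = spec$resolution,
                             use_temperature = spec$use_temperature,
                             use_spread = spec$use_spread)
  list(total_eur = total_impact(tab), total_Meur = total_impact(tab) / 1e6,
       table = tab)
}

modify_spec <- function(spec, parameter, setting) {
  switch(parameter,
         spread    = { spec$q <- setting; spec },
         threshold = { spec$threshold <- setting; spec },
         mortality = { spec$mortality <- setting; spec },
         price     = { spec$price <- setting; spec },
         stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE))
}

#' Single-parameter sensitivity sweep
#'
#' Varies exactly one of spread percentile, temperature threshold,
#' mortality preset or price, holding the rest at the base scenario, and
#' reports the total direct impact per setting.
#'
#' @param world A `pwn_world`.
#' @param reps A `spread_replicates` set.
#' @param base_spec Base [scenario_spec()].
#' @param parameter One of `"spread"`, `"threshold"`, `"mortality"`,
#'   `"price"`.
#' @param settings Vector or list of settings for that parameter.
#' @return Data frame: parameter, setting, impact_eur, impact_Meur.
#' @export
run_single_parameter <- function(world, reps, base_spec = scenario_spec(),
                                 parameter, settings) {
  if (!parameter %in% c("spread", "threshold", "mortality", "price"))
    stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  totals <- vapply(settings, function(s)
    evaluate_scenario(world, reps, modify_spec(base_spec, parameter, s))$total_eur,
    numeric(1))
  data.frame(parameter = parameter,
             setting = vapply(settings, function(s) paste(format(s), collapse = "x"),
                              character(1)),
             impact_eur = as.numeric(totals),
             impact_Meur = as.numeric(totals) / 1e6)
}

#' Worst-case / best-case multi-parameter analysis
#'
#' The worst case combines the 95th-percentile spread, the lowest
#' temperature threshold, maximum mortality and the highest price; the
#' best case the symmetric opposites. Reports totals and a per-region
#' table with absolute impacts and impacts relative to each region's
#' total asset value (stock volume valued at the scenario price; the
#' ratio is price-free).
#'
#' @param world A `pwn_world`.
#' @param reps A `spread_replicates` set.
#' @param base_spec Base [scenario_spec()].
#' @param thresholds Worst and best temperature thresholds, degC.
#' @param prices Lowest and highest prices considered, EUR/m3.
#' @return List with `worst_Meur`, `base_Meur`, `best_Meur` and `table`
#'   (region_id, worst_Meur, worst_pct, best_Meur, best_pct,
#'   difference_pct).
#' @export
run_extreme_cases <- function(world, reps, base_spec = scenario_spec(),
                              thresholds = c(worst = 18, best = 20),
                              prices = c(lowest = 50.49, highest = 67.7)) {
  worst_spec <- base_spec
  worst_spec$q <- 95; worst_spec$threshold <- thresholds[["worst"]]
  worst_spec$mortality <- "maximum"; worst_spec$price <- prices[["highest"]]
  best_spec <- base_spec
  best_spec$q <- 5; best_spec$threshold <- thresholds[["best"]]
  best_spec$mortality <- "minimum"; best_spec$price <- prices[["lowest"]]

  worst <- evaluate_scenario(world, reps, worst_spec)
  best <- evaluate_scenario(world, reps, best_spec)
  base <- evaluate_scenario(world, reps, base_spec)

  stock_m3 <- tapply(world$stock$stock_m3, world$stock$region_id, sum)
  asset_worst <- as.numeric(stock_m3) * worst_spec$price
  asset_best <- as.numeric(stock_m3) * best_spec$price
  worst_pct <- ifelse(asset_worst > 0,
                      100 * worst$table$impact_eur / asset_worst, 0)
  best_pct <- ifelse(asset_best > 0,
                     100 * best$table$impact_eur / asset_best, 0)
  tab <- data.frame(
    region_id = worst$table$region_id,
    worst_Meur = worst$table$impact_Meur,
    worst_pct = worst_pct,
    best_Meur = best$table$impact_Meur,
    best_pct = best_pct,
    difference_pct = worst_pct - best_pct
  )
  list(worst_Meur = worst$total_Meur, base_Meur = base$total_Meur,
       best_Meur = best$total_Meur, table = tab)
}

#' Data-layer removal analysis
#'
#' Recomputes the direct impact with one constraining layer removed:
#' `"no_temperature"` assumes disease expression wherever the pest is
#' present (dispersal-limited only); `"no_spread"` assumes the pest is
#' present everywhere, so occurrence is limited by temperature alone.
#' Either relaxation can only enlarge the qualifying set, so the removal
#' impact is at least the fully constrained impact.
#'
#' @param world A `pwn_world`.
#' @param reps A `spread_replicates` set.
#' @param base_spec Base [scenario_spec()].
#' @param mode `"no_temperature"` or `"no_spread"`.
#' @return List with `total_eur`, `total_Meur`, `table`.
#' @export
run_layer_removal <- function(world, reps, base_spec = scenario_spec(),
                              mode = c("no_temperature", "no_spread")) {
  mode <- match.arg(mode)
  spec <- base_spec
  if (mode == "no_temperature") spec$use_temperature <- FALSE
  else spec$use_spread <- FALSE
  evaluate_scenario(world, reps, spec)
}
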