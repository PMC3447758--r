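#' Direct loss for one polygon (partial budget)
#'
#' The value of standing stock killed in one polygon: exposure fraction
#' times mortality times stock, summed over the six vulnerability classes
#' and valued at the round-wood price. At coarse resolution the exposure
#' fraction is `r * d` (proportion infested times the 0/1 disease
#' indicator); at fine resolution it is the region's qualifying-cell
#' fraction. Trees expressing the disease are treated as completely
#' worthless; surviving trees retain full value.
#'
#' @param exposure_fraction Fraction of the polygon's stock exposed
#'   (`r * d` or qualifying fraction), in `[0, 1]`.
#' @param stock Data frame with columns age_class, susceptibility,
#'   stock_m3 (the polygon's standing stock).
#' @param mortality A [mortality_table()].
#' @param price Round-wood price, EUR per m3 (`> 0`).
#' @return List with `value` (EUR) and `volume` (m3 killed).
#' @examples
#' s <- data.frame(age_class = "young", susceptibility = "susceptible",
#'                 stock_m3 = 100)
#' direct_impact(1, s, mortality_table("default"), price = 50)
#' @export
direct_impact <- function(exposure_fraction, stock, mortality, price) {
  if (!is.numeric(price) || price <= 0)
    stop("price must be > 0", call. = FALSE)
  if (any(stock$stock_m3 < 0))
    stop("standing stock must be >= 0", call. = FALSE)
  if (exposure_fraction < 0 || exposure_fraction > 1)
    stop("exposure fraction must lie in [0, 1]", call. = FALSE)
  m <- mortality_for_stock(stock, mortality)
  volume <- exposure_fraction * sum(m * stock$stock_m3)
  list(value = price * volume, volume = volume)
}

#' Regional direct-impact table for one occupancy snapshot
#'
#' Applies the partial budget to every region at the chosen resolution.
#' The layer flags support the data-layer-removal analysis: with
#' `use_temperature = FALSE` the disease indicator is forced to 1 wherever
#' the pest is present; with `use_spread = FALSE` presence is assumed
#' everywhere and only temperature limits expression.
#'
#' @param world A `pwn_world`.
#' @param occupancy_coarse Logical coarse occupancy matrix (final-year
#'   snapshot, typically).
#' @param mortality A [mortality_table()].
#' @param price Round-wood price, EUR/m3.
#' @param threshold Temperature threshold, degC.
#' @param resolution `"coarse"` (region-level indicator) or `"fine"`
#'   (1-cell-level qualifying fraction).
#' @param use_temperature,use_spread Layer flags (see Details).
#' @return Data frame of class `direct_impact_table`: region_id,
#'   proportion_infested (exposure fraction actually applied),
#'   impact_eur, impact_Meur, volume_m3, qualifying_km2,
#'   impact_eur_per_km2 (NA where no area qualifies).
#' @export
direct_impact_table <- function(world, occupancy_coarse,
                                mortality = mortality_table("default"),
                                price = 50.49, threshold = 20,
                                resolution = c("coarse", "fine"),
                                use_temperature = TRUE, use_spread = TRUE) {
  stopifnot(inherits(world, "pwn_world"))
  resolution <- match.arg(resolution)
  if (!use_spread) {
    occupancy_coarse <- matrix(TRUE, nrow(occupancy_coarse),
                               ncol(occupancy_coarse))
  }
  expo <- region_exposure(world, occupancy_coarse, threshold)
  if (!use_temperature) {
    expo$d <- ifelse(expo$r > 0, 1L, expo$d)
    # fine: qualifying = presence only
    block <- world$grid$coarse_block
    occ_fine <- expand_coarse(occupancy_coarse, block)
    expo$n_qualifying <- vapply(seq_len(world$n_regions), function(i)
      sum(occ_fine[world$region == i]), numeric(1))
    expo$qualifying_fraction <- ifelse(expo$n_cells > 0,
                                       expo$n_qualifying / expo$n_cells, 0)
  }
  frac <- if (resolution == "coarse") expo$r * expo$d
          else expo$qualifying_fraction

  n <- world$n_regions
  value <- numeric(n); volume <- numeric(n)
  for (i in seq_len(n)) {
    s <- world$stock[world$stock$region_id == i, , drop = FALSE]
    di <- direct_impact(frac[i], s, mortality, price)
    value[i] <- di$value; volume[i] <- di$volume
  }
  area <- world$grid$cell_area
  qualifying_km2 <- if (resolution == "coarse") {
    expo$n_cells * area * frac
  } else {
    expo$n_qualifying * area
  }
  out <- data.frame(
    region_id = expo$region_id,
    proportion_infested = frac,
    impact_eur = value,
    impact_Meur = value / 1e6,
    volume_m3 = volume,
    qualifying_km2 = qualifying_km2,
    impact_eur_per_km2 = ifelse(qualifying_km2 > 0, value / qualifying_km2,
                                NA_real_)
  )
  class(out) <- c("direct_impact_table", "data.frame")
  attr(out, "resolution") <- resolution
  attr(out, "price") <- price
  attr(out, "threshold") <- threshold
  out
}

#' Total direct impact over regions
#'
#' @param records A `direct_impact_table` (or any data frame with an
#'   `impact_eur` or `impact_Meur` column), or a numeric vector of
#'   regional impacts. An empty input totals 0.
#' @param unit `"eur"` or `"Meur"` for data-frame input.
#' @return The summed impact (same unit as the input column chosen).
#' @export
total_impact <- function(records, unit = c("eur", "Meur")) {
  unit <- match.arg(unit)
  if (is.numeric(records)) return(sum(records))
  if (is.data.frame(records)) {
    col <- if (unit == "eur" && "impact_eur" %in% names(records)) "impact_eur"
           else if ("impact_Meur" %in% names(records)) "impact_Meur"
           else "impact_eur"
    if (nrow(records) == 0L) return(0)
    return(sum(records[[col]]))
  }
  stop("records must be a data frame or numeric vector", call. = FALSE)
}

#' Cumulative and marginal direct-impact series
#'
#' Applies the partial budget to every yearly occupancy snapshot of one
#' spread replicate. Because occupancy is cumulative and the standing
#' stock is held fixed (no regrowth over the horizon), the yearly totals
#' are themselves the cumulative loss; the marginal series is its first
#' difference, with the introduction year's marginal equal to its
#' cumulative value. No discounting is applied.
#'
#' @param series A `spread_series` (one replicate) or a logical array
#'   `[rows, cols, years]` of coarse occupancy.
#' @param world A `pwn_world`.
#' @param mortality A [mortality_table()].
#' @param price Round-wood price, EUR/m3.
#' @param threshold Temperature threshold, degC.
#' @param resolution `"coarse"` or `"fine"`.
#' @param years Calendar years labelling the slices (taken from `series`
#'   when it is a `spread_series`).
#' @return Data frame of class `impact_series`: year, cumulative_eur,
#'   marginal_eur.
#' @export
impact_series <- function(series, world,
                          mortality = mortality_table("default"),
                          price = 50.49, threshold = 20,
                          resolution = c("coarse", "fine"),
                          years = NULL) {
  resolution <- match.arg(resolution)
  if (inherits(series, "spread_series")) {
    if (is.null(years)) years <- series$years
    occ <- series$occupancy
  } else occ <- series
  stopifnot(length(dim(occ)) == 3L)
  nt <- dim(occ)[3]
  if (is.null(years)) years <- seq_len(nt)
  for (t in seq_len(nt - 1L))
    if (any(occ[, , t] & !occ[, , t + 1L]))
      stop("occupancy is not monotone in time", call. = FALSE)
  cumulative <- vapply(seq_len(nt), function(t)
    total_impact(direct_impact_table(world, occ[, , t], mortality, price,
                                     threshold, resolution)),
    numeric(1))
  marginal <- c(cumulative[1], diff(cumulative))
  out <- data.frame(year = years, cumulative_eur = cumulative,
                    marginal_eur = marginal)
  class(out) <- c("impact_series", "data.frame")
  out
}

#' @export
plot.impact_series <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$year, x$cumulative_eur / 1e6, type = "l", xlab = "year",
       ylab = "cumulative direct impact (M EUR)", ...)
  plot(x$year, x$marginal_eur / 1e6, type = "h", xlab = "year",
       ylab = "marginal direct impact (M EUR)", ...)
  invisible(x)
}

#' Rescale a direct impact to a different round-wood price
#'
#' The partial budget is linear in price, so impacts transfer between
#' price assumptions by simple proportion.
#'
#' @param total Impact value computed at `old_price`.
#' @param new_price,old_price Prices in EUR/m3 (`> 0`).
#' @return `total * new_price / old_price`.
#' @examples
#' scale_by_price(27865, 67.7, 50.49)  # Table-style M EUR rescaling
#' @export
scale_by_price <- function(total, new_price, old_price) {
  if (new_price <= 0 || old_price <= 0)
    stop("prices must be > 0", call. = FALSE)
  total * new_price / old_price
}
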