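#' Published regional direct-impact reference table
#'
#' The published cumulative direct impacts of 22 years of uncontrolled
#' spread, per region and resolution, shipped as a built-in parameter set
#' for additive consistency checks (the regional values must sum to the
#' published EU totals of 27,865 M EUR coarse and 22,375 M EUR fine) and
#' for worked examples. Reproducing the absolute regional values requires
#' the proprietary host-stock layer and is out of scope.
#'
#' @return Data frame: region, coarse_pct, coarse_Meur, fine_pct,
#'   fine_Meur, fine_eur_per_km2.
#' @examples
#' sum(reference_impacts()$coarse_Meur)  # 27865
#' @export
reference_impacts <- function() {
  data.frame(
    region = c("Italy", "Portugal", "Spain", "Languedoc-Roussillon",
               "Bourgogne", "Poitou-Charentes", "Aquitaine",
               "Midi-Pyrenees", "Limousin", "Rhone-Alpes", "Auvergne",
               "Provence-Alpes Cote d'Azur"),
    coarse_pct = c(0.15, 97.49, 95.15, 84.65, 0, 0, 0, 0, 0, 0, 0, 0),
    coarse_Meur = c(30, 6106, 20645, 1084, 0, 0, 0, 0, 0, 0, 0, 0),
    fine_pct = c(0.15, 82.44, 67.52, 50.32, 0.06, 0.09, 19.86, 22.18,
                 1.71, 14.71, 0.19, 15.63),
    fine_Meur = c(30, 5164, 14649, 644, 1, 1, 1219, 289, 15, 215, 3, 145),
    fine_eur_per_km2 = c(43136, 46895, 28530, 28831, 16079, 21381, 90611,
                         17749, 30124, 19626, 31792, 18217)
  )
}

#' Published post-shock market changes (worked-example inputs)
#'
#' The published 2030 equilibrium price and domestic supply changes under
#' the coarse- and fine-resolution supply shifts, used as override inputs
#' to [market_welfare_table()] for the surplus worked examples.
#'
#' @return Data frame: resolution, price_change_eur (EUR/m3),
#'   supply_change_thousand_m3.
#' @export
reference_market_changes <- function() {
  data.frame(
    resolution = c("coarse", "fine"),
    price_change_eur = c(2.40, 1.44),
    supply_change_thousand_m3 = c(-3240, -1890)
  )
}

#' Published asset base of susceptible conifer stock
#'
#' @return List with `susceptible_million_m3` (13,665),
#'   `total_million_m3` (24,594) and `price_eur_per_m3` (50.49), the
#'   denominators for expressing direct impacts as a fraction of the
#'   at-risk asset value.
#' @export
reference_asset_base <- function() {
  list(susceptible_million_m3 = 13665, total_million_m3 = 24594,
       price_eur_per_m3 = 50.49)
}
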