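HOST_CLASSES <- data.frame(
  age_class      = rep(c("young", "old"), each = 3L),
  susceptibility = rep(c("susceptible", "intermediate", "resistant"), 2L),
  stringsAsFactors = FALSE
)

class_labels <- function() {
  paste(HOST_CLASSES$age_class, HOST_CLASSES$susceptibility, sep = ".")
}

#' Configuration for a synthetic assessment world
#'
#' Bundles everything needed to generate the three data layers the
#' assessment consumes: a mean-summer-temperature fine grid with a
#' south-to-north cooling gradient, a map of contiguous administrative
#' regions, and a regional host standing-stock table split over the six
#' vulnerability classes (age at most 20 yr / older than 20 yr, crossed
#' with susceptible / intermediate / resistant species).
#'
#' Defaults emulate the structure of the real European inputs: total
#' conifer standing stock 24,594 million m3 of which roughly 56% is in
#' susceptible species, a temperature field straddling the 20 degC disease
#' threshold, and pest entry in the warm south-west corner.
#'
#' @param grid A [grid_spec()].
#' @param n_regions Number of regions; regions are contiguous rectangular
#'   tiles of fine cells.
#' @param temperature_gradient Warming in degC per fine row moving south
#'   (row 1 is the northernmost row).
#' @param temperature_noise_sd Standard deviation (degC) of i.i.d. Gaussian
#'   cell-level noise added to the latitudinal trend.
#' @param temperature_base Mean temperature (degC) of the northernmost row.
#' @param stock_total_target Total standing stock over all regions and
#'   classes, in m3.
#' @param class_mix Six non-negative fractions summing to 1, the share of
#'   stock in each vulnerability class, ordered as
#'   young.susceptible, young.intermediate, young.resistant,
#'   old.susceptible, old.intermediate, old.resistant.
#' @param stock_north_bias Exponential weighting of regional stock toward
#'   the north (`weight ~ exp(bias * northness)`): European conifer stock
#'   is concentrated in the cool north while the invasion enters the warm
#'   south, and the default of 2 reproduces that contrast; 0 gives
#'   area-proportional stock.
#' @param entry_cell Coarse-grid (row, col) where the invasion starts;
#'   `NULL` places it in the south-west corner.
#' @param seed Integer seed making the world reproducible.
#' @return An object of class `world_config`.
#' @export
world_config <- function(grid = grid_spec(100, 100, cell_area = 1, coarse_block = 5),
                         n_regions = 16,
                         temperature_gradient = 0.1,
                         temperature_noise_sd = 0.5,
                         temperature_base = 16,
                         stock_total_target = 2.4594e10,
                         class_mix = c(0.26, 0.10, 0.06, 0.30, 0.18, 0.10),
                         stock_north_bias = 2,
                         entry_cell = NULL,
                         seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("n_regions must be >= 1", call. = FALSE)
  if (length(class_mix) != 6L || any(class_mix < 0))
    stop("class_mix must be 6 non-negative fractions", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1 (tolerance 1e-9)", call. = FALSE)
  if (!is.numeric(stock_total_target) || stock_total_target < 0)
    stop("stock_total_target must be >= 0", call. = FALSE)
  cd <- coarse_dims(grid)
  if (is.null(entry_cell)) entry_cell <- c(cd[1], 1L)
  entry_cell <- as.integer(entry_cell)
  if (length(entry_cell) != 2L || any(entry_cell < 1L) ||
      entry_cell[1] > cd[1] || entry_cell[2] > cd[2])
    stop("entry_cell outside the coarse grid", call. = FALSE)
  structure(
    list(grid = grid, n_regions = n_regions,
         temperature_gradient = temperature_gradient,
         temperature_noise_sd = temperature_noise_sd,
         temperature_base = temperature_base,
         stock_total_target = stock_total_target,
         class_mix = setNames(as.numeric(class_mix), class_labels()),
         stock_north_bias = stock_north_bias,
         entry_cell = entry_cell,
         seed = as.integer(seed)),
    class = "world_config"
  )
}

# near-even integer partition of n into k bands
band_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# tile the fine grid into n_regions contiguous rectangles, row-major ids
region_tiling <- function(grid, n_regions) {
  divs <- which(n_regions %% seq_len(n_regions) == 0L)
  rr <- max(divs[divs <= sqrt(n_regions)])
  cc <- n_regions %/% rr
  if (rr > grid$n_rows || cc > grid$n_cols)
    stop("n_regions too large for the grid", call. = FALSE)
  row_band <- rep(seq_len(rr), times = band_sizes(grid$n_rows, rr))
  col_band <- rep(seq_len(cc), times = band_sizes(grid$n_cols, cc))
  outer(row_band, col_band, function(r, c) (r - 1L) * cc + c)
}

#' Generate a synthetic world (temperature, regions, host stock)
#'
#' Builds the three data layers downstream stages consume. The temperature
#' layer is a deterministic south-to-north gradient plus seeded Gaussian
#' noise; regions are contiguous rectangular tiles; regional stock is
#' proportional to region size times a seeded log-normal factor, split over
#' the six vulnerability classes by `class_mix` and rescaled so the grand
#' total equals `stock_total_target` exactly.
#'
#' @param config A [world_config()].
#' @return An object of class `pwn_world`: list with elements `grid`,
#'   `temperature` (fine matrix, degC), `region` (fine integer matrix),
#'   `stock` (data frame: region_id, age_class, susceptibility, stock_m3),
#'   `n_regions` and `config`.
#' @examples
#' w <- generate_world(world_config(grid_spec(20, 20, coarse_block = 5),
#'                                  n_regions = 4, seed = 42))
#' w
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  grid <- config$grid
  set.seed(config$seed)

  trend <- config$temperature_base +
    config$temperature_gradient * (seq_len(grid$n_rows) - 1)
  noise <- matrix(rnorm(grid$n_rows * grid$n_cols, sd = config$temperature_noise_sd),
                  grid$n_rows, grid$n_cols)
  temperature <- matrix(trend, grid$n_rows, grid$n_cols) + noise

  if (all(temperature > 20))
    message("generate_world: all-hot world (every cell above 20 degC)")
  if (all(temperature < 20))
    message("generate_world: all-cold world (every cell below 20 degC)")

  region <- region_tiling(grid, config$n_regions)

  cells <- tabulate(region, nbins = config$n_regions)
  # northness in [0, 1]: 1 for a region at the top (north) edge
  mean_row <- vapply(seq_len(config$n_regions), function(i)
    mean(row(region)[region == i]), numeric(1))
  northness <- if (grid$n_rows > 1) 1 - (mean_row - 1) / (grid$n_rows - 1)
               else rep(0, config$n_regions)
  w <- cells * exp(config$stock_north_bias * northness) *
    rlnorm(config$n_regions, meanlog = 0, sdlog = 0.5)
  region_stock <- if (sum(w) > 0) config$stock_total_target * w / sum(w)
                  else rep(0, config$n_regions)
  stock <- data.frame(
    region_id      = rep(seq_len(config$n_regions), each = 6L),
    age_class      = rep(HOST_CLASSES$age_class, config$n_regions),
    susceptibility = rep(HOST_CLASSES$susceptibility, config$n_regions),
    stock_m3       = as.numeric(vapply(seq_len(config$n_regions),
                       function(i) region_stock[i] * config$class_mix,
                       numeric(6L))),
    stringsAsFactors = FALSE
  )

  structure(
    list(grid = grid, temperature = temperature, region = region,
         stock = stock, n_regions = config$n_regions, config = config),
    class = "pwn_world"
  )
}

#' @export
print.pwn_world <- function(x, ...) {
  cat(sprintf("<pwn_world> %d x %d fine grid, %d regions\n",
              x$grid$n_rows, x$grid$n_cols, x$n_regions))
  cat(sprintf("  temperature: %.1f to %.1f degC (mean %.1f)\n",
              min(x$temperature), max(x$temperature), mean(x$temperature)))
  cat(sprintf("  standing stock: %.4g m3 over 6 vulnerability classes\n",
              sum(x$stock$stock_m3)))
  invisible(x)
}

#' Write the world's layers to disk
#'
#' Temperature goes out as an Esri ASCII raster, the region map as an
#' integer raster, and the stock table as CSV with columns
#' region_id, age_class, susceptibility, stock_m3.
#'
#' @param world A `pwn_world`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "pwn_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "temperature.asc")
  f2 <- file.path(dir, "regions.asc")
  f3 <- file.path(dir, "stock.csv")
  cs <- sqrt(world$grid$cell_area) * 1000
  write_asc(round(world$temperature, 4), f1, cellsize = cs)
  write_asc(world$region, f2, cellsize = cs)
  write.csv(world$stock, f3, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
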