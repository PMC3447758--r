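#' Region-mean summer temperature (coarse integration)
#'
#' Aggregates the fine temperature grid to one mean summer temperature per
#' region, the value the coarse (region-level) disease indicator is based
#' on.
#'
#' @param temp_fine Fine temperature matrix (degC).
#' @param region_map Fine integer matrix of region ids (same dimensions).
#' @return Numeric vector of means, one per region id `1..max(region_map)`.
#' @export
upscale_temperature <- function(temp_fine, region_map) {
  if (!all(dim(temp_fine) == dim(region_map)))
    stop("temperature grid and region map have different dimensions",
         call. = FALSE)
  n <- max(region_map)
  means <- vapply(seq_len(n), function(i) mean(temp_fine[region_map == i]),
                  numeric(1))
  setNames(means, seq_len(n))
}

# assign each coarse cell to the region owning most of its fine cells
# (ties -> lowest region id); returns a coarse integer matrix
coarse_region_map <- function(region_map, coarse_block) {
  nr <- nrow(region_map) %/% coarse_block
  nc <- ncol(region_map) %/% coarse_block
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1L) * coarse_block + 1L):(i * coarse_block)
    for (j in seq_len(nc)) {
      cols <- ((j - 1L) * coarse_block + 1L):(j * coarse_block)
      tb <- tabulate(region_map[rows, cols])
      out[i, j] <- which.max(tb)
    }
  }
  out
}

#' Region proportion infested (coarse integration)
#'
#' The proportion of a region's coarse (spread-model) cells that are
#' occupied by the pest. Coarse cells straddling a region boundary are
#' assigned to the region holding the majority of their fine cells (ties
#' to the lowest region id); a region containing no coarse cell gets 0.
#'
#' @param occupancy_coarse Logical coarse occupancy matrix.
#' @param region_map Fine integer matrix of region ids.
#' @param coarse_block Fine cells per coarse-cell side.
#' @return Numeric vector `r` in `[0, 1]`, one per region.
#' @export
upscale_spread <- function(occupancy_coarse, region_map, coarse_block) {
  if (nrow(occupancy_coarse) * coarse_block != nrow(region_map) ||
      ncol(occupancy_coarse) * coarse_block != ncol(region_map))
    stop("coarse occupancy is not aligned to the region map under coarse_block",
         call. = FALSE)
  n <- max(region_map)
  crm <- coarse_region_map(region_map, coarse_block)
  r <- numeric(n)
  for (i in seq_len(n)) {
    cells <- crm == i
    r[i] <- if (any(cells)) mean(occupancy_coarse[cells]) else 0
  }
  setNames(r, seq_len(n))
}

#' Disease-expression indicator from mean temperature
#'
#' Pine wilt disease is expressed only where mean summer temperature is
#' strictly higher than the threshold; equality means no expression.
#'
#' @param mean_temp Mean summer temperature(s), degC.
#' @param threshold Expression threshold, degC (default 20).
#' @return Integer 0/1 vector of the same length.
#' @export
pwd_indicator <- function(mean_temp, threshold = 20) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  as.integer(mean_temp > threshold)
}

#' Fine cells where disease can be expressed
#'
#' A fine cell qualifies iff its parent coarse cell is occupied by the
#' pest (presence in a coarse cell implies presence in every fine cell
#' within it) AND its own temperature is strictly above the threshold.
#'
#' @param occupancy_coarse Logical coarse occupancy matrix.
#' @param temp_fine Fine temperature matrix.
#' @param threshold Temperature threshold, degC.
#' @param coarse_block Fine cells per coarse-cell side.
#' @return Logical fine matrix.
#' @export
qualifying_cells <- function(occupancy_coarse, temp_fine, threshold = 20,
                             coarse_block = nrow(temp_fine) %/% nrow(occupancy_coarse)) {
  if (nrow(occupancy_coarse) * coarse_block != nrow(temp_fine) ||
      ncol(occupancy_coarse) * coarse_block != ncol(temp_fine))
    stop("coarse occupancy is not congruent with the fine grid under coarse_block",
         call. = FALSE)
  expand_coarse(occupancy_coarse, coarse_block) & (temp_fine > threshold)
}

#' Spread a regional impact evenly over its qualifying cells
#'
#' Implements the homogeneous-distribution assumption used to map
#' region-level production value to cells: each qualifying cell receives
#' an equal share, non-qualifying cells receive 0, and one cell absorbs
#' the floating-point remainder so the cell values sum to the regional
#' value exactly.
#'
#' @param region_impact_value Regional impact (EUR), `>= 0`.
#' @param qualifying Logical matrix (or vector) marking qualifying cells.
#' @return Numeric array of per-cell values, same shape as `qualifying`.
#' @export
downscale_impact <- function(region_impact_value, qualifying) {
  if (region_impact_value < 0)
    stop("region impact must be >= 0", call. = FALSE)
  out <- array(0, dim = if (is.null(dim(qualifying))) length(qualifying)
                        else dim(qualifying))
  n <- sum(qualifying)
  if (region_impact_value == 0) return(out)
  if (n == 0)
    stop("positive regional impact but no qualifying cell", call. = FALSE)
  per <- region_impact_value / n
  out[qualifying] <- per
  last <- which(qualifying)[n]
  out[last] <- region_impact_value - per * (n - 1)
  out
}

#' Per-region exposure summary for one occupancy snapshot
#'
#' Combines the three layers into the quantities the partial budget needs:
#' the coarse proportion infested `r`, the region disease indicator `d`
#' (from the region-mean temperature), and the fine qualifying fraction
#' (share of the region's fine cells that are both under an occupied
#' coarse cell and above the threshold).
#'
#' @param world A `pwn_world`.
#' @param occupancy_coarse Logical coarse occupancy matrix.
#' @param threshold Temperature threshold, degC.
#' @return Data frame: region_id, r, d, qualifying_fraction, mean_temp,
#'   n_cells (fine cells in region), n_qualifying.
#' @export
region_exposure <- function(world, occupancy_coarse, threshold = 20) {
  stopifnot(inherits(world, "pwn_world"))
  block <- world$grid$coarse_block
  mean_temp <- upscale_temperature(world$temperature, world$region)
  r <- upscale_spread(occupancy_coarse, world$region, block)
  d <- pwd_indicator(mean_temp, threshold)
  qual <- qualifying_cells(occupancy_coarse, world$temperature, threshold,
                           block)
  n <- world$n_regions
  n_cells <- tabulate(world$region, nbins = n)
  n_qual <- vapply(seq_len(n), function(i) sum(qual[world$region == i]),
                   numeric(1))
  data.frame(
    region_id = seq_len(n),
    r = as.numeric(r),
    d = d,
    qualifying_fraction = ifelse(n_cells > 0, n_qual / n_cells, 0),
    mean_temp = as.numeric(mean_temp),
    n_cells = n_cells,
    n_qualifying = n_qual
  )
}
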