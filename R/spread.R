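# occupied-neighbourhood dilation: TRUE wherever any occupied cell lies
# within Chebyshev distance <= radius
chebyshev_dilate <- function(occ, radius) {
  if (radius < 1L) return(occ)
  nr <- nrow(occ); nc <- ncol(occ)
  out <- matrix(FALSE, nr, nc)
  for (dr in -radius:radius) {
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    ro <- rs - dr
    for (dc in -radius:radius) {
      cs <- max(1L, 1L + dc):min(nc, nc + dc)
      co <- cs - dc
      out[rs, cs] <- out[rs, cs] | occ[ro, co]
    }
  }
  out
}

#' Simulate stochastic range expansion on the coarse grid
#'
#' A generic monotone presence/absence spread process standing in for a
#' mechanistic dispersal model: each year, every unoccupied cell within
#' `growth_radius` (Chebyshev distance) of an occupied cell becomes
#' occupied with probability `growth_prob`, and `rpois(1, jump_rate)`
#' long-distance jumps land on uniformly random cells. Occupancy is
#' cumulative: a cell once occupied stays occupied.
#'
#' @param world A `pwn_world` (or a bare [grid_spec()]).
#' @param entry_cell Coarse (row, col) of the introduction; defaults to the
#'   world's configured entry cell.
#' @param years Number of years of spread after the introduction year; the
#'   returned series has `years + 1` time points (year 0 = entry only).
#' @param growth_radius Chebyshev radius (coarse cells) of local growth
#'   per year.
#' @param growth_prob Probability that a cell in the growth ring becomes
#'   occupied in a given year; 1 gives deterministic frontier growth.
#' @param jump_rate Mean number of long-distance jump foci per year.
#' @param n_replicates Number of independent replicate simulations.
#' @param seed Optional seed applied before simulation.
#' @param start_year Calendar year of the introduction.
#' @return An object of class `spread_replicates`: list with `occupancy`
#'   (list of logical arrays `[rows, cols, years + 1]`), `years` (calendar
#'   years), `entry_cell`, `invaded_count_final` (per replicate) and the
#'   simulation parameters.
#' @examples
#' g <- grid_spec(20, 20, coarse_block = 5)
#' reps <- simulate_spread(g, entry_cell = c(4, 1), years = 3,
#'                         n_replicates = 5, seed = 7)
#' reps
#' @export
simulate_spread <- function(world, entry_cell = NULL, years = 22,
                            growth_radius = 1, growth_prob = 1,
                            jump_rate = 0.5, n_replicates = 200,
                            seed = NULL, start_year = 2008) {
  grid <- if (inherits(world, "pwn_world")) world$grid else world
  stopifnot(inherits(grid, "grid_spec"))
  cd <- coarse_dims(grid)
  if (is.null(entry_cell)) {
    entry_cell <- if (inherits(world, "pwn_world")) world$config$entry_cell
                  else c(cd[1], 1L)
  }
  entry_cell <- as.integer(entry_cell)
  if (length(entry_cell) != 2L || any(entry_cell < 1L) ||
      entry_cell[1] > cd[1] || entry_cell[2] > cd[2])
    stop("entry_cell outside the coarse grid", call. = FALSE)
  years <- as.integer(years)
  n_replicates <- as.integer(n_replicates)
  if (years < 0L) stop("years must be >= 0", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (growth_prob < 0 || growth_prob > 1)
    stop("growth_prob must be in [0, 1]", call. = FALSE)
  if (jump_rate < 0) stop("jump_rate must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_cells <- cd[1] * cd[2]
  occupancy <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    occ <- array(FALSE, dim = c(cd[1], cd[2], years + 1L))
    cur <- matrix(FALSE, cd[1], cd[2])
    cur[entry_cell[1], entry_cell[2]] <- TRUE
    occ[, , 1L] <- cur
    if (years > 0L) for (t in seq_len(years)) {
      ring <- chebyshev_dilate(cur, growth_radius) & !cur
      if (any(ring)) {
        idx <- which(ring)
        take <- if (growth_prob >= 1) idx
                else idx[runif(length(idx)) < growth_prob]
        cur[take] <- TRUE
      }
      if (jump_rate > 0) {
        n_jump <- rpois(1L, jump_rate)
        if (n_jump > 0L)
          cur[sample.int(n_cells, min(n_jump, n_cells))] <- TRUE
      }
      occ[, , t + 1L] <- cur
    }
    occupancy[[rep_i]] <- occ
  }

  structure(
    list(occupancy = occupancy,
         years = start_year + 0:years,
         entry_cell = entry_cell,
         invaded_count_final = vapply(occupancy,
                                      function(a) sum(a[, , dim(a)[3]]),
                                      numeric(1)),
         params = list(growth_radius = growth_radius,
                       growth_prob = growth_prob, jump_rate = jump_rate,
                       seed = seed),
         grid = grid),
    class = "spread_replicates"
  )
}

#' @export
print.spread_replicates <- function(x, ...) {
  cnt <- x$invaded_count_final
  cat(sprintf("<spread_replicates> %d replicates, years %d-%d, coarse %d x %d\n",
              length(x$occupancy), min(x$years), max(x$years),
              dim(x$occupancy[[1]])[1], dim(x$occupancy[[1]])[2]))
  cat(sprintf("  final invaded cells: median %g (range %g-%g)\n",
              stats::median(cnt), min(cnt), max(cnt)))
  invisible(x)
}

#' Select the replicate at a given percentile of final invaded area
#'
#' Replicates are ranked by their count of invaded coarse cells in the
#' final year; the nearest-rank (ceiling) percentile is returned, with
#' ties broken in favour of the lowest replicate index. The 5th, 50th and
#' 95th percentiles are the conventional pessimistic/central/optimistic
#' spread scenarios.
#'
#' @param set A `spread_replicates` object.
#' @param q Percentile in `[0, 100]`.
#' @return An object of class `spread_series`: list with `occupancy` (one
#'   logical array), `years`, `replicate` (index chosen) and
#'   `invaded_count_final`.
#' @export
select_percentile_replicate <- function(set, q) {
  stopifnot(inherits(set, "spread_replicates"))
  n <- length(set$occupancy)
  if (n < 1L) stop("empty replicate set", call. = FALSE)
  if (q < 0 || q > 100) stop("q must be in [0, 100]", call. = FALSE)
  counts <- set$invaded_count_final
  k <- min(n, max(1L, as.integer(ceiling(q / 100 * n))))
  val <- sort(counts)[k]
  idx <- which(counts == val)[1L]
  structure(
    list(occupancy = set$occupancy[[idx]], years = set$years,
         replicate = idx, invaded_count_final = counts[idx],
         grid = set$grid),
    class = "spread_series"
  )
}

#' @export
print.spread_series <- function(x, ...) {
  cat(sprintf("<spread_series> replicate %d, years %d-%d, %g cells invaded at end\n",
              x$replicate, min(x$years), max(x$years),
              x$invaded_count_final))
  invisible(x)
}
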