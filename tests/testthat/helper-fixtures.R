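# small seeded worlds and replicate sets used across test files

tiny_world <- function(n_rows = 12, n_cols = 12, coarse_block = 3,
                       n_regions = 4, gradient = 0.5, noise_sd = 0,
                       base = 16, seed = 11, north_bias = 0, ...) {
  generate_world(world_config(
    grid = grid_spec(n_rows, n_cols, cell_area = 1,
                     coarse_block = coarse_block),
    n_regions = n_regions,
    temperature_gradient = gradient,
    temperature_noise_sd = noise_sd,
    temperature_base = base,
    stock_total_target = 6e6,
    stock_north_bias = north_bias,
    seed = seed, ...))
}

tiny_replicates <- function(world, years = 5, n_replicates = 20,
                            growth_prob = 0.6, jump_rate = 0.4, seed = 5) {
  simulate_spread(world, years = years, growth_prob = growth_prob,
                  jump_rate = jump_rate, n_replicates = n_replicates,
                  seed = seed)
}

# replicate set with prescribed final invaded counts (1 x n_cells grid rows)
fake_replicate_set <- function(counts, n_cells = max(counts)) {
  occupancy <- lapply(counts, function(k) {
    a <- array(FALSE, dim = c(1L, n_cells, 1L))
    if (k > 0) a[1L, seq_len(k), 1L] <- TRUE
    a
  })
  structure(list(occupancy = occupancy, years = 2008L,
                 entry_cell = c(1L, 1L),
                 invaded_count_final = as.numeric(counts),
                 params = list(), grid = grid_spec(1, n_cells)),
            class = "spread_replicates")
}

# single-class stock table for hand arithmetic
one_class_stock <- function(stock_m3 = 100, age = "young",
                            susceptibility = "susceptible") {
  data.frame(region_id = 1L, age_class = age,
             susceptibility = susceptibility, stock_m3 = stock_m3,
             stringsAsFactors = FALSE)
}
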