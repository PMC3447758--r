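#' Define the two-resolution grid geometry
#'
#' The assessment works on two nested regular grids: a fine grid (nominally
#' 1 km2 cells) carrying temperature and downscaled impacts, and a coarse
#' grid (the spread-model resolution) carrying pest presence/absence. Each
#' coarse cell is a `coarse_block` x `coarse_block` block of fine cells, so
#' both fine dimensions must be divisible by `coarse_block`.
#'
#' @param n_rows,n_cols Fine-grid dimensions. Row 1 is the northernmost row;
#'   cells are indexed (row, col).
#' @param cell_area Area of one fine cell in km2.
#' @param coarse_block Number of fine cells per side of one coarse cell.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(12, 12, coarse_block = 3)
#' @export
grid_spec <- function(n_rows, n_cols, cell_area = 1, coarse_block = 1) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  coarse_block <- as.integer(coarse_block)
  if (n_rows < 1L || n_cols < 1L || coarse_block < 1L)
    stop("n_rows, n_cols and coarse_block must all be >= 1", call. = FALSE)
  if (!is.numeric(cell_area) || cell_area <= 0)
    stop("cell_area must be > 0", call. = FALSE)
  if (n_rows %% coarse_block != 0L || n_cols %% coarse_block != 0L)
    stop("n_rows and n_cols must be divisible by coarse_block",
         call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_area = cell_area,
         coarse_block = coarse_block),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> fine %d x %d (%g km2/cell), coarse %d x %d (block %d)\n",
              x$n_rows, x$n_cols, x$cell_area,
              x$n_rows %/% x$coarse_block, x$n_cols %/% x$coarse_block,
              x$coarse_block))
  invisible(x)
}

coarse_dims <- function(grid) {
  c(grid$n_rows %/% grid$coarse_block, grid$n_cols %/% grid$coarse_block)
}

# replicate each coarse value over its block of fine cells
expand_coarse <- function(coarse_mat, coarse_block) {
  coarse_mat[rep(seq_len(nrow(coarse_mat)), each = coarse_block),
             rep(seq_len(ncol(coarse_mat)), each = coarse_block),
             drop = FALSE]
}

#' Write a matrix as an Esri ASCII raster
#'
#' Rows are written north to south, matching the package convention that
#' row 1 of a grid matrix is the northernmost row.
#'
#' @param mat Numeric (or logical, written as 0/1) matrix.
#' @param path Output file path (conventionally `.asc`).
#' @param cellsize Cell size in the raster's coordinate units.
#' @param xllcorner,yllcorner Coordinates of the lower-left corner.
#' @param nodata_value Value standing for missing cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(mat, path, cellsize = 1000, xllcorner = 0,
                      yllcorner = 0, nodata_value = -9999) {
  if (is.logical(mat)) mat <- mat + 0
  mat[is.na(mat)] <- nodata_value
  header <- c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.10g", xllcorner),
    sprintf("yllcorner %.10g", yllcorner),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata_value)
  )
  body <- apply(mat, 1L, function(row) paste(format(row, trim = TRUE,
                                                    scientific = FALSE),
                                             collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an Esri ASCII raster into a matrix
#'
#' @param path Path to an `.asc` file written in the standard six-line
#'   header format.
#' @return A numeric matrix with the header stored in attribute `"header"`;
#'   NODATA cells become `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows))
    stop("not an Esri ASCII raster: missing ncols/nrows header", call. = FALSE)
  vals <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("raster body does not match declared dimensions", call. = FALSE)
  mat <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) mat[mat == hdr$nodata_value] <- NA
  attr(mat, "header") <- hdr
  mat
}
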