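#' Tile grid for mosaic imaging
#'
#' A fully populated rectangular grid of phase-image tiles, as produced by a
#' mosaic scan of one tissue core (default geometry: a 10 x 10 grid of
#' 1388 x 1040-pixel fields of view).  Tiles must share shape, pixel size
#' and wavelength.
#'
#' @param tiles list of [phase_image()] tiles.
#' @param positions integer matrix with one `(row, col)` grid position per
#'   tile, 1-based.
#' @param grid_shape integer vector `c(grid_rows, grid_cols)`.
#' @param overlap overlap between adjacent tiles, pixels (>= 0).
#' @return a `tile_grid` object.
#' @export
tile_grid <- function(tiles, positions, grid_shape, overlap = 0) {
  if (!is.list(tiles) || !all(vapply(tiles, is_phase_image, logical(1))))
    stop_parameter("`tiles` must be a list of phase_image objects")
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || nrow(positions) != length(tiles))
    stop_parameter("`positions` must be an n_tiles x 2 matrix of (row, col)")
  if (length(grid_shape) != 2L || any(grid_shape < 1))
    stop_parameter("`grid_shape` must be two positive integers")
  grid_shape <- as.integer(grid_shape)
  shp <- dim(tiles[[1]]$values)
  ps <- tiles[[1]]$pixel_size
  for (t in tiles) {
    if (!identical(dim(t$values), shp))
      stop_data("all tiles must share the same shape")
    if (t$pixel_size != ps)
      stop_data("all tiles must share the same pixel size")
  }
  check_number(overlap, "overlap", lower = 0, upper = min(shp) - 1)
  key <- paste(positions[, 1], positions[, 2])
  want <- as.vector(outer(seq_len(grid_shape[1]), seq_len(grid_shape[2]),
                          paste))
  missing <- setdiff(want, key)
  if (length(missing) > 0)
    stop_data(sprintf("grid is not fully populated; missing position(s): %s",
                      paste(missing, collapse = ", ")),
              missing_positions = missing)
  if (anyDuplicated(key))
    stop_data("duplicate tile positions in grid")
  structure(list(tiles = tiles, positions = positions,
                 grid_shape = grid_shape, tile_shape = shp,
                 overlap = as.integer(overlap)),
            class = "tile_grid")
}

#' Stitch a tile grid into one phase image
#'
#' Tiles are placed at their nominal grid offsets (tile pitch = tile size
#' minus overlap; no registration) and overlapping pixels are averaged.
#' The output is `grid * tile - (grid - 1) * overlap` pixels per axis, so a
#' 10 x 10 grid of 1388 x 1040 tiles with zero overlap yields a
#' 10400 x 13880-pixel canvas (rows x columns).
#'
#' @param grid a [tile_grid()].
#' @return a [phase_image()].
#' @export
stitch_tiles <- function(grid) {
  if (!inherits(grid, "tile_grid")) stop_parameter("`grid` must be a tile_grid")
  th <- grid$tile_shape[1]; tw <- grid$tile_shape[2]
  ov <- grid$overlap
  nr <- grid$grid_shape[1] * th - (grid$grid_shape[1] - 1L) * ov
  nc <- grid$grid_shape[2] * tw - (grid$grid_shape[2] - 1L) * ov
  acc <- matrix(0, nr, nc)
  wt <- matrix(0, nr, nc)
  for (i in seq_along(grid$tiles)) {
    r0 <- (grid$positions[i, 1] - 1L) * (th - ov)
    c0 <- (grid$positions[i, 2] - 1L) * (tw - ov)
    rows <- (r0 + 1L):(r0 + th); cols <- (c0 + 1L):(c0 + tw)
    acc[rows, cols] <- acc[rows, cols] + grid$tiles[[i]]$values
    wt[rows, cols] <- wt[rows, cols] + 1
  }
  phase_image(acc / wt, pixel_size = grid$tiles[[1]]$pixel_size,
              wavelength = grid$tiles[[1]]$wavelength)
}

#' Centered crop of a phase image
#'
#' Crops to exactly `size x size` pixels about the image center.  When the
#' remainder to remove along an axis is odd, the crop keeps one extra pixel
#' of margin on the trailing (bottom/right) side, i.e. the window starts at
#' `floor((n - size)/2) + 1`.
#'
#' @param img a [phase_image()].
#' @param size crop edge, pixels; both image dimensions must be >= `size`.
#' @return a [phase_image()] of `size x size` pixels.
#' @export
crop_core <- function(img, size) {
  if (!is_phase_image(img)) stop_parameter("`img` must be a phase_image")
  check_number(size, "size", lower = 1)
  size <- as.integer(size)
  nr <- nrow(img$values); nc <- ncol(img$values)
  if (nr < size || nc < size)
    stop_data(sprintf("image (%dx%d) is smaller than crop size %d",
                      nr, nc, size))
  r0 <- (nr - size) %/% 2L
  c0 <- (nc - size) %/% 2L
  phase_image(img$values[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size),
                         drop = FALSE],
              pixel_size = img$pixel_size, wavelength = img$wavelength)
}
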