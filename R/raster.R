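#' Geographic grid specification
#'
#' Defines a regular longitude/latitude grid (WGS84 degrees). Rows index
#' latitude from south to north, columns index longitude from west to east;
#' `origin_lon`/`origin_lat` give the south-west corner of the grid (not a
#' cell centre).
#'
#' @param n_rows,n_cols grid dimensions (>= 2 for landscapes, >= 1 here).
#' @param cell_size_deg cell edge in degrees; default 2.5 arc minutes.
#' @param origin_lon,origin_lat south-west corner in degrees.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_deg = 2.5 / 60,
                      origin_lon = 0, origin_lat = 0) {
  if (n_rows < 1 || n_cols < 1)
    stop("grid dimensions must be positive", call. = FALSE)
  if (cell_size_deg <= 0)
    stop("cell_size_deg must be > 0", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_deg = cell_size_deg,
         origin_lon = origin_lon, origin_lat = origin_lat),
    class = "grid_spec")
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return list with `lon` (length `n_cols`) and `lat` (length `n_rows`)
#'   cell-centre coordinate vectors.
#' @export
grid_centers <- function(grid) {
  list(
    lon = grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size_deg,
    lat = grid$origin_lat + (seq_len(grid$n_rows) - 0.5) * grid$cell_size_deg)
}

#' Predictor stack: named raster layers on one grid
#'
#' A minimal raster container: each layer is an `n_rows x n_cols` matrix
#' (row 1 = southernmost row) and all layers share one [grid_spec()].
#'
#' @param layers named list of numeric matrices.
#' @param grid a [grid_spec()].
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named", call. = FALSE)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop("layer '", nm, "' does not match the grid dimensions",
           call. = FALSE)
  }
  structure(list(layers = layers, grid = grid), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layer(s) on a %d x %d grid (%.4f deg)\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              x$grid$cell_size_deg))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Number of layers in a stack
#' @param stack a [predictor_stack()].
#' @return integer count.
#' @export
n_layers <- function(stack) length(stack$layers)

#' Map lon/lat points to grid cell indices
#'
#' @param grid a [grid_spec()].
#' @param lon,lat coordinate vectors (degrees).
#' @return data.frame with `row`, `col` (NA for points off the grid).
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size_deg) + 1
  row <- floor((lat - grid$origin_lat) / grid$cell_size_deg) + 1
  # points exactly on the top/right edge belong to the last cell
  col[lon == grid$origin_lon + grid$n_cols * grid$cell_size_deg] <- grid$n_cols
  row[lat == grid$origin_lat + grid$n_rows * grid$cell_size_deg] <- grid$n_rows
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract predictor values at point locations
#'
#' Values are taken from the cell containing each point (no interpolation).
#'
#' @param stack a [predictor_stack()].
#' @param lon,lat coordinates (degrees).
#' @return data.frame, one column per layer; NA rows for off-grid points.
#' @export
extract_values <- function(stack, lon, lat) {
  idx <- cell_index(stack$grid, lon, lat)
  lin <- cbind(idx$row, idx$col)
  out <- lapply(stack$layers, function(m) {
    v <- rep(NA_real_, nrow(idx))
    ok <- !is.na(idx$row)
    v[ok] <- m[lin[ok, , drop = FALSE]]
    v
  })
  as.data.frame(out)
}

#' Resample a predictor stack onto a target grid
#'
#' Continuous layers should use bilinear interpolation, categorical or
#' fractional layers nearest-neighbour. Interpolation works on cell-centre
#' coordinates; target cells whose centres fall outside the source
#' cell-centre hull get NA (bilinear) or the nearest source cell (nearest,
#' still NA when outside the source extent entirely).
#'
#' @param stack a [predictor_stack()].
#' @param target a [grid_spec()].
#' @param method "bilinear" or "nearest"; recycled over layers.
#' @return a [predictor_stack()] on `target`.
#' @export
resample_to_grid <- function(stack, target, method = "bilinear") {
  stopifnot(inherits(target, "grid_spec"))
  method <- match.arg(method, c("bilinear", "nearest"))
  src <- grid_centers(stack$grid)
  tgt <- grid_centers(target)
  src_lon_rng <- range(src$lon); src_lat_rng <- range(src$lat)
  if (min(tgt$lon) > src_lon_rng[2] + stack$grid$cell_size_deg ||
      max(tgt$lon) < src_lon_rng[1] - stack$grid$cell_size_deg ||
      min(tgt$lat) > src_lat_rng[2] + stack$grid$cell_size_deg ||
      max(tgt$lat) < src_lat_rng[1] - stack$grid$cell_size_deg)
    stop("source and target grids do not overlap", call. = FALSE)

  out <- lapply(stack$layers, function(m) {
    if (method == "bilinear") {
      # pracma::interp2 expects Z with rows matching y; our rows are latitude
      res <- matrix(NA_real_, target$n_rows, target$n_cols)
      inx <- tgt$lon >= src_lon_rng[1] & tgt$lon <= src_lon_rng[2]
      iny <- tgt$lat >= src_lat_rng[1] & tgt$lat <= src_lat_rng[2]
      if (any(inx) && any(iny)) {
        gx <- tgt$lon[inx]; gy <- tgt$lat[iny]
        pts <- expand.grid(y = gy, x = gx)
        z <- pracma::interp2(x = src$lon, y = src$lat, Z = m,
                             xp = pts$x, yp = pts$y, method = "linear")
        res[iny, inx] <- matrix(z, nrow = sum(iny), ncol = sum(inx))
      }
      res
    } else {
      ri <- sapply(tgt$lat, function(y) which.min(abs(src$lat - y)))
      ci <- sapply(tgt$lon, function(x) which.min(abs(src$lon - x)))
      res <- m[ri, ci, drop = FALSE]
      res[, tgt$lon < src_lon_rng[1] - stack$grid$cell_size_deg / 2 |
            tgt$lon > src_lon_rng[2] + stack$grid$cell_size_deg / 2] <- NA
      res[tgt$lat < src_lat_rng[1] - stack$grid$cell_size_deg / 2 |
            tgt$lat > src_lat_rng[2] + stack$grid$cell_size_deg / 2, ] <- NA
      res
    }
  })
  predictor_stack(out, target)
}

#' Area of grid cells in a latitude row
#'
#' Spherical-zone formula: `A = R^2 * dlambda * (sin(phi_top) - sin(phi_bot))`
#' with R = 6371 km, so cell area shrinks towards the poles.
#'
#' @param grid a [grid_spec()].
#' @param row row index (1 = southernmost) or vector of indices.
#' @return area per cell in km^2, one value per row index.
#' @export
cell_area_km2 <- function(grid, row) {
  R <- 6371
  phi_bot <- (grid$origin_lat + (row - 1) * grid$cell_size_deg) * pi / 180
  phi_top <- (grid$origin_lat + row * grid$cell_size_deg) * pi / 180
  dl <- grid$cell_size_deg * pi / 180
  R^2 * dl * (sin(phi_top) - sin(phi_bot))
}

#' Write / read a raster layer as gridded CSV text
#'
#' Plain-text exchange format: a header line with the grid spec followed by
#' the matrix in row-major order (row 1 = southernmost).
#'
#' @param layer matrix to write.
#' @param grid a [grid_spec()].
#' @param path file path.
#' @return `write_layer_csv` returns `path` invisibly; `read_layer_csv`
#'   returns a list with `layer` and `grid`.
#' @export
write_layer_csv <- function(layer, grid, path) {
  hdr <- sprintf("# n_rows=%d n_cols=%d cell_size_deg=%.10g origin_lon=%.10g origin_lat=%.10g",
                 grid$n_rows, grid$n_cols, grid$cell_size_deg,
                 grid$origin_lon, grid$origin_lat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(layer, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_layer_csv
#' @export
read_layer_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.eE]+", hdr))[[1]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 1))
  dimnames(m) <- NULL
  grid <- grid_spec(vals["n_rows"], vals["n_cols"], vals["cell_size_deg"],
                    vals["origin_lon"], vals["origin_lat"])
  list(layer = m, grid = grid)
}
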