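#' Range decomposition container
#'
#' Holds the overlay areas (km^2) of two binary potential-range maps:
#' expansion RE (introduced only), stability RS (both), unfilling RU
#' (native only), with the composed ranges PRI = RE + RS (introduced) and
#' PRN = RS + RU (native).
#'
#' @param RE,RS,RU areas in km^2 (>= 0).
#' @param class_raster optional per-cell class matrix ("expansion",
#'   "stability", "unfilling", "absent").
#' @return object of class `range_decomposition`.
#' @export
range_decomposition <- function(RE, RS, RU, class_raster = NULL) {
  if (any(c(RE, RS, RU) < 0))
    stop("areas must be >= 0", call. = FALSE)
  structure(list(RE = RE, RS = RS, RU = RU,
                 PRI = RE + RS, PRN = RS + RU,
                 class_raster = class_raster),
            class = "range_decomposition")
}

#' @export
print.range_decomposition <- function(x, ...) {
  cat(sprintf("range decomposition (km^2): RE=%.4g RS=%.4g RU=%.4g | PRI=%.4g PRN=%.4g\n",
              x$RE, x$RS, x$RU, x$PRI, x$PRN))
  invisible(x)
}

#' Overlay two binary range maps into RE/RS/RU
#'
#' Per cell: introduced-only = expansion, both = stability, native-only =
#' unfilling, neither = absent. Areas are aggregated with latitude-weighted
#' cell areas ([cell_area_km2()]), so high-latitude cells count less.
#'
#' @param native,introduced logical (or 0/1) matrices on the same grid.
#' @param grid the shared [grid_spec()].
#' @return a [range_decomposition()] with the per-cell class raster.
#' @export
decompose_ranges <- function(native, introduced, grid) {
  if (!all(dim(native) == dim(introduced)))
    stop("range maps are on different grids", call. = FALSE)
  if (!all(dim(native) == c(grid$n_rows, grid$n_cols)))
    stop("range maps do not match the grid spec", call. = FALSE)
  nat <- native > 0
  int <- introduced > 0
  cls <- matrix("absent", nrow(nat), ncol(nat))
  cls[int & !nat] <- "expansion"
  cls[int & nat] <- "stability"
  cls[!int & nat] <- "unfilling"
  area_row <- cell_area_km2(grid, seq_len(grid$n_rows))
  area <- matrix(area_row, grid$n_rows, grid$n_cols)
  range_decomposition(RE = sum(area[cls == "expansion"]),
                      RS = sum(area[cls == "stability"]),
                      RU = sum(area[cls == "unfilling"]),
                      class_raster = cls)
}

#' Range ratio index
#'
#' `RRI = PRI / PRN`; RRI > 1 means the introduced potential range is
#' larger than the native one.
#'
#' @param d a [range_decomposition()].
#' @return RRI.
#' @export
range_ratio_index <- function(d) {
  if (d$PRN == 0) stop("PRN is zero; RRI undefined", call. = FALSE)
  d$PRI / d$PRN
}

#' Range similarity index
#'
#' `RSI = 2 * RS / (PRI + PRN)`, in `[0, 1]`; RSI > 0.5 means the two
#' potential ranges occupy similar positions.
#'
#' @param d a [range_decomposition()].
#' @return RSI.
#' @export
range_similarity_index <- function(d) {
  if (d$PRI + d$PRN == 0)
    stop("both ranges are empty; RSI undefined", call. = FALSE)
  2 * d$RS / (d$PRI + d$PRN)
}

#' Invasion rate ratio between two species
#'
#' Compares per-year range expansion: `(RE_a / duration_a) /
#' (RE_b / duration_b)`. Invasion-history durations are explicit
#' parameters because published histories are ranges, not points.
#'
#' @param RE_a,RE_b range expansions (km^2).
#' @param duration_a,duration_b invasion durations (years, > 0).
#' @return rate ratio (species a relative to species b).
#' @export
invasion_rate_ratio <- function(RE_a, duration_a, RE_b, duration_b) {
  if (duration_a <= 0 || duration_b <= 0)
    stop("durations must be > 0", call. = FALSE)
  (RE_a / duration_a) / (RE_b / duration_b)
}
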