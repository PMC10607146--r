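#' Load occurrence records from CSV
#'
#' Expects at least `lon` and `lat` columns (degrees, WGS84); optional
#' `uncertainty_km`, `source` and `population` columns are carried through
#' and filled with defaults when absent. Rows with unparsable or
#' out-of-bounds coordinates are dropped with a message.
#'
#' @param path CSV file path.
#' @return occurrence data.frame (`lon`, `lat`, `uncertainty_km`, `source`,
#'   `population`).
#' @export
load_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(raw)))
    stop("occurrence CSV must have 'lon' and 'lat' columns", call. = FALSE)
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  ok <- !is.na(lon) & !is.na(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  if (any(!ok))
    message("load_occurrences: dropped ", sum(!ok),
            " record(s) with missing or out-of-bounds coordinates")
  unc <- if ("uncertainty_km" %in% names(raw))
    suppressWarnings(as.numeric(raw$uncertainty_km)) else NA_real_
  src <- if ("source" %in% names(raw)) as.character(raw$source) else ""
  pop <- if ("population" %in% names(raw))
    as.character(raw$population) else "unassigned"
  out <- data.frame(lon = lon, lat = lat,
                    uncertainty_km = rep_len(unc, length(lon)),
                    source = rep_len(src, length(lon)),
                    population = rep_len(pop, length(lon)),
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter records by coordinate uncertainty
#'
#' Removes records whose reported coordinate uncertainty exceeds `max_km`
#' (strictly: "over" the threshold). Records with missing uncertainty are
#' retained — an absent metadata field cannot exceed a threshold — and the
#' retained-missing count is reported so users can audit.
#'
#' @param occ occurrence data.frame.
#' @param max_km uncertainty threshold in km (> 0); default 5.
#' @return filtered occurrence data.frame.
#' @export
filter_uncertainty <- function(occ, max_km = 5) {
  if (max_km <= 0) stop("max_km must be > 0", call. = FALSE)
  missing_unc <- is.na(occ$uncertainty_km)
  keep <- missing_unc | occ$uncertainty_km <= max_km
  if (any(missing_unc & keep))
    message("filter_uncertainty: retained ", sum(missing_unc),
            " record(s) with missing uncertainty")
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove duplicate records
#'
#' One record is kept per rounded (lon, lat, population) key; coordinates
#' are rounded to `precision_decimals` places (4 decimals is roughly 11 m at
#' the equator). The first record in input order wins.
#'
#' @param occ occurrence data.frame.
#' @param precision_decimals rounding precision for the duplicate key.
#' @return deduplicated occurrence data.frame.
#' @export
deduplicate <- function(occ, precision_decimals = 4) {
  key <- paste(round(occ$lon, precision_decimals),
               round(occ$lat, precision_decimals),
               occ$population, sep = "|")
  out <- occ[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (via geosphere).
#'
#' @param a,b points as `c(lon, lat)` vectors or two-column matrices
#'   (degrees).
#' @return distance(s) in km.
#' @export
great_circle_km <- function(a, b) {
  geosphere::distHaversine(a, b, r = 6371)
}

#' Spatially rarefy occurrence records
#'
#' Greedy thinning: records are visited in a (optionally seed-shuffled)
#' order and kept iff they lie at least `radius_km` (great-circle) from
#' every previously kept record. The output therefore has no pair of
#' records closer than `radius_km`. Deterministic for a fixed seed.
#'
#' @param occ occurrence data.frame.
#' @param radius_km minimum allowed pairwise distance (km, > 0); default 5.
#' @param seed integer seed for the visiting order.
#' @param shuffle visit records in seed-shuffled order (default) or input
#'   order.
#' @return thinned occurrence data.frame (subset of the input rows).
#' @export
spatial_thin <- function(occ, radius_km = 5, seed = 1L, shuffle = TRUE) {
  if (radius_km <= 0) stop("radius_km must be > 0", call. = FALSE)
  n <- nrow(occ)
  if (n <= 1) return(occ)
  ord <- if (shuffle) {
    set.seed(seed)
    sample.int(n)
  } else seq_len(n)
  pts <- cbind(occ$lon, occ$lat)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 ||
        min(great_circle_km(pts[kept, , drop = FALSE],
                            pts[i, ])) >= radius_km)
      kept <- c(kept, i)
  }
  out <- occ[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ray-casting point-in-polygon, boundary-inclusive.
# poly: data.frame/matrix with lon, lat columns (closed or open ring).
point_in_polygon <- function(lon, lat, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  if (px[1] != px[length(px)] || py[1] != py[length(py)]) {
    px <- c(px, px[1]); py <- c(py, py[1])
  }
  n <- length(px) - 1
  res <- logical(length(lon))
  for (p in seq_along(lon)) {
    x <- lon[p]; y <- lat[p]
    inside <- FALSE
    on_edge <- FALSE
    for (i in seq_len(n)) {
      x1 <- px[i]; y1 <- py[i]; x2 <- px[i + 1]; y2 <- py[i + 1]
      # boundary check: collinear and within the segment bounding box
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) {
        on_edge <- TRUE
        break
      }
      if ((y1 > y) != (y2 > y) &&
          x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
        inside <- !inside
    }
    res[p] <- inside || on_edge
  }
  res
}

#' Split records into native and introduced populations
#'
#' Point-in-polygon assignment against the native-region polygons
#' (boundary-inclusive). Records already labelled `native` or `introduced`
#' keep their label; a warning reports any conflict between an existing
#' label and the polygon assignment.
#'
#' @param occ occurrence data.frame.
#' @param native_polygons one polygon (two-column lon/lat data.frame or
#'   matrix) or a list of polygons.
#' @return list with `native` and `introduced` occurrence data.frames.
#' @export
split_populations <- function(occ, native_polygons) {
  if (!is.list(native_polygons) || is.data.frame(native_polygons))
    native_polygons <- list(native_polygons)
  for (poly in native_polygons) {
    m <- as.matrix(poly)
    if (ncol(m) < 2 || nrow(m) < 3 || any(!is.finite(m)))
      stop("invalid polygon geometry", call. = FALSE)
  }
  inside <- rep(FALSE, nrow(occ))
  for (poly in native_polygons)
    inside <- inside | point_in_polygon(occ$lon, occ$lat, as.matrix(poly))
  assigned <- ifelse(inside, "native", "introduced")
  pre <- occ$population %in% c("native", "introduced")
  conflict <- pre & occ$population != assigned
  if (any(conflict))
    warning(sum(conflict), " pre-labelled record(s) disagree with the ",
            "polygon assignment; keeping the existing label", call. = FALSE)
  label <- ifelse(pre, occ$population, assigned)
  occ$population <- label
  list(native = {
    x <- occ[label == "native", , drop = FALSE]; rownames(x) <- NULL; x
  }, introduced = {
    x <- occ[label == "introduced", , drop = FALSE]; rownames(x) <- NULL; x
  })
}

#' Standard occurrence cleaning pipeline
#'
#' Deduplicate, filter by coordinate uncertainty, then spatially rarefy —
#' in that order. Rarefaction is applied per population when the set has
#' both labels (native and introduced thinned separately).
#'
#' @param occ occurrence data.frame.
#' @param max_km uncertainty threshold (km).
#' @param radius_km thinning radius (km).
#' @param seed seed for the thinning order.
#' @return cleaned occurrence data.frame.
#' @export
clean_occurrences <- function(occ, max_km = 5, radius_km = 5, seed = 1L) {
  occ <- deduplicate(occ)
  occ <- filter_uncertainty(occ, max_km)
  pops <- unique(occ$population)
  if (length(pops) > 1) {
    parts <- lapply(seq_along(pops), function(i)
      spatial_thin(occ[occ$population == pops[i], , drop = FALSE],
                   radius_km, seed = seed + i))
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  } else {
    spatial_thin(occ, radius_km, seed = seed)
  }
}
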