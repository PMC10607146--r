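#' Landscape simulation configuration
#'
#' @param n_rows,n_cols grid cells (>= 2 each).
#' @param cell_size_deg cell edge in degrees (default 2.5 arc minutes).
#' @param origin_lon,origin_lat south-west corner (degrees).
#' @param n_gradient_layers number of environmental layers to simulate.
#' @param noise_sd standard deviation of the spatially autocorrelated noise
#'   added to each gradient, in layer units (>= 0).
#' @param autocorrelation_range moving-average smoothing radius in cells.
#' @param seed integer RNG seed.
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 100, n_cols = 100,
                             cell_size_deg = 2.5 / 60,
                             origin_lon = 0, origin_lat = 0,
                             n_gradient_layers = 3,
                             noise_sd = 0.5, autocorrelation_range = 3,
                             seed = 1L) {
  if (n_rows < 2 || n_cols < 2)
    stop("landscape must be at least 2 x 2", call. = FALSE)
  if (cell_size_deg <= 0) stop("cell_size_deg must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_gradient_layers < 1) stop("need >= 1 layer", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_deg = cell_size_deg, origin_lon = origin_lon,
         origin_lat = origin_lat,
         n_gradient_layers = as.integer(n_gradient_layers),
         noise_sd = noise_sd,
         autocorrelation_range = as.integer(autocorrelation_range),
         seed = as.integer(seed)),
    class = "landscape_config")
}

#' Virtual niche: Gaussian response surface parameters
#'
#' The virtual species responds to each environmental layer with an
#' independent Gaussian curve: optimum `mu[k]`, width `sigma[k]`.
#'
#' @param mu numeric vector of optima (layer units).
#' @param sigma numeric vector of niche widths (> 0, same length as `mu`).
#' @param prevalence_scale peak suitability in (0, 1].
#' @return object of class `virtual_niche`.
#' @export
virtual_niche <- function(mu, sigma, prevalence_scale = 1) {
  if (length(mu) != length(sigma))
    stop("mu and sigma must have equal length", call. = FALSE)
  if (any(sigma <= 0)) stop("all sigma must be > 0", call. = FALSE)
  if (prevalence_scale <= 0 || prevalence_scale > 1)
    stop("prevalence_scale must be in (0, 1]", call. = FALSE)
  structure(list(mu = mu, sigma = sigma,
                 prevalence_scale = prevalence_scale),
            class = "virtual_niche")
}

# moving-average smoothing of a white-noise field; the smoothed field is
# rescaled so its marginal sd equals the requested noise_sd
smooth_noise <- function(n_rows, n_cols, noise_sd, range_cells) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells >= 1) {
    k <- 2L * range_cells + 1L
    # separable box filter with edge renormalisation
    run <- function(m) {
      cs <- apply(m, 2, function(col) {
        c0 <- cumsum(col)
        lo <- pmax(seq_along(col) - range_cells, 1L)
        hi <- pmin(seq_along(col) + range_cells, length(col))
        (c0[hi] - c(0, c0)[lo]) / (hi - lo + 1L)
      })
      cs
    }
    w <- run(w)
    w <- t(run(t(w)))
  }
  s <- stats::sd(as.vector(w))
  if (s > 0) w <- w / s
  w * noise_sd
}

#' Generate a synthetic environmental landscape
#'
#' Each layer is a deterministic linear gradient in the row/col indices plus
#' spatially autocorrelated noise (moving-average-smoothed Gaussian white
#' noise over `autocorrelation_range` cells). Layer 1 increases west to east,
#' layer 2 south to north, further layers alternate diagonal orientations, so
#' that layers are not mutually redundant. Gradients span 10 layer units
#' across the grid.
#'
#' @param config a [landscape_config()].
#' @return a [predictor_stack()] with layers `env1`, `env2`, ...
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  grid <- grid_spec(config$n_rows, config$n_cols, config$cell_size_deg,
                    config$origin_lon, config$origin_lat)
  set.seed(config$seed)
  rows <- matrix(seq_len(config$n_rows), config$n_rows, config$n_cols)
  cols <- matrix(seq_len(config$n_cols), config$n_rows, config$n_cols,
                 byrow = TRUE)
  rfrac <- (rows - 1) / max(config$n_rows - 1, 1)
  cfrac <- (cols - 1) / max(config$n_cols - 1, 1)
  span <- 10
  layers <- vector("list", config$n_gradient_layers)
  for (k in seq_len(config$n_gradient_layers)) {
    base <- switch(((k - 1) %% 4) + 1,
                   span * cfrac,                    # west -> east
                   span * rfrac,                    # south -> north
                   span * (cfrac + rfrac) / 2,      # SW -> NE diagonal
                   span * (cfrac + 1 - rfrac) / 2)  # NW -> SE diagonal
    layers[[k]] <- base + smooth_noise(config$n_rows, config$n_cols,
                                       config$noise_sd,
                                       config$autocorrelation_range)
  }
  names(layers) <- paste0("env", seq_along(layers))
  predictor_stack(layers, grid)
}

#' Generate a synthetic monthly climate
#'
#' Per cell, monthly mean temperature follows a sinusoid around the annual
#' mean with the coldest month in January (northern-hemisphere convention):
#' `tmean_m = mean - A * cos(2*pi*(m-1)/12)`, where `A` is
#' `seasonal_amplitude` (half the annual range). `tmax`/`tmin` are the mean
#' plus/minus a fixed diurnal half-range. Annual precipitation is spread
#' across months proportionally to the 12 `prec_pattern` weights.
#'
#' @param config a [landscape_config()] (supplies the grid).
#' @param seasonal_amplitude half annual temperature range (deg C).
#' @param annual_mean_field matrix of per-cell annual mean temperature
#'   (deg C), or a scalar.
#' @param prec_pattern 12 nonnegative monthly precipitation weights.
#' @param annual_prec total annual precipitation (mm), matrix or scalar.
#' @param diurnal_half_range half of the daily temperature range (deg C).
#' @return object of class `monthly_climate`: lists `tmin`, `tmax`, `prec`
#'   of 12 matrices each plus the [grid_spec()].
#' @export
generate_monthly_climate <- function(config, seasonal_amplitude,
                                     annual_mean_field,
                                     prec_pattern = rep(1, 12),
                                     annual_prec = 1200,
                                     diurnal_half_range = 5) {
  stopifnot(inherits(config, "landscape_config"))
  if (length(prec_pattern) != 12)
    stop("prec_pattern must have 12 weights", call. = FALSE)
  if (any(prec_pattern < 0))
    stop("precipitation weights must be >= 0", call. = FALSE)
  if (sum(prec_pattern) <= 0)
    stop("precipitation weights must not all be zero", call. = FALSE)
  grid <- grid_spec(config$n_rows, config$n_cols, config$cell_size_deg,
                    config$origin_lon, config$origin_lat)
  as_field <- function(x)
    if (is.matrix(x)) x else matrix(x, grid$n_rows, grid$n_cols)
  amean <- as_field(annual_mean_field)
  aprec <- as_field(annual_prec)
  w <- prec_pattern / sum(prec_pattern)
  tmin <- tmax <- prec <- vector("list", 12)
  for (m in 1:12) {
    tmean <- amean - seasonal_amplitude * cos(2 * pi * (m - 1) / 12)
    tmin[[m]] <- tmean - diurnal_half_range
    tmax[[m]] <- tmean + diurnal_half_range
    prec[[m]] <- aprec * w[m]
  }
  monthly_climate(tmin, tmax, prec, grid)
}

#' Suitability surface of a virtual niche over a landscape
#'
#' Independent Gaussian responses per layer:
#' `s = prevalence_scale * exp(-0.5 * sum_k ((e_k - mu_k)/sigma_k)^2)`.
#'
#' @param stack a [predictor_stack()], layer count matching `length(niche$mu)`.
#' @param niche a [virtual_niche()].
#' @return suitability matrix in `[0, prevalence_scale]`.
#' @export
suitability_surface <- function(stack, niche) {
  stopifnot(inherits(stack, "predictor_stack"),
            inherits(niche, "virtual_niche"))
  if (n_layers(stack) != length(niche$mu))
    stop("stack has ", n_layers(stack), " layers but niche expects ",
         length(niche$mu), call. = FALSE)
  q <- 0
  for (k in seq_along(niche$mu))
    q <- q + ((stack$layers[[k]] - niche$mu[k]) / niche$sigma[k])^2
  niche$prevalence_scale * exp(-0.5 * q)
}

#' Sample occurrence records from a suitability surface
#'
#' Cells are drawn with replacement with probability proportional to
#' suitability; each record is placed uniformly at random within its cell
#' (jitter), so duplicates and near-duplicates arise naturally.
#'
#' @param suitability matrix in `[0, 1]`.
#' @param grid the matching [grid_spec()].
#' @param n number of records.
#' @param seed integer RNG seed.
#' @param population population label for the records.
#' @return occurrence data.frame (`lon`, `lat`, `uncertainty_km`, `source`,
#'   `population`).
#' @export
sample_occurrences <- function(suitability, grid, n, seed = 1L,
                               population = "unassigned") {
  if (all(suitability <= 0))
    stop("suitability is zero everywhere; cannot sample", call. = FALSE)
  set.seed(seed)
  p <- as.vector(suitability)
  p[p < 0] <- 0
  cells <- sample.int(length(p), n, replace = TRUE, prob = p)
  row <- (cells - 1) %% grid$n_rows + 1
  col <- (cells - 1) %/% grid$n_rows + 1
  lon <- grid$origin_lon + (col - 1 + stats::runif(n)) * grid$cell_size_deg
  lat <- grid$origin_lat + (row - 1 + stats::runif(n)) * grid$cell_size_deg
  data.frame(lon = lon, lat = lat, uncertainty_km = NA_real_,
             source = "synthetic", population = population,
             stringsAsFactors = FALSE)
}

#' Ground-truth COUE decomposition of two virtual niches
#'
#' Binarizes each population's true suitability at `cutoff * max(s)` and
#' counts cells: expansion E = introduced-only / introduced, stability
#' S = 1 - E, unfilling U = native-only / native. This is the geometric
#' ground truth that the kernel-density COUE estimates should recover.
#'
#' @param native,introduced [virtual_niche()] objects.
#' @param stack a [predictor_stack()].
#' @param occupancy_cutoff fraction of the maximum suitability in (0, 1).
#' @return list with `E`, `S`, `U`.
#' @export
true_coue <- function(native, introduced, stack, occupancy_cutoff = 0.05) {
  if (occupancy_cutoff <= 0 || occupancy_cutoff >= 1)
    stop("occupancy_cutoff must be in (0, 1)", call. = FALSE)
  sn <- suitability_surface(stack, native)
  si <- suitability_surface(stack, introduced)
  bn <- sn >= occupancy_cutoff * max(sn)
  bi <- si >= occupancy_cutoff * max(si)
  E <- sum(bi & !bn) / sum(bi)
  U <- sum(bn & !bi) / sum(bn)
  list(E = E, S = 1 - E, U = U)
}

#' Virtual species configuration: paired native and introduced niches
#'
#' @param native,introduced [virtual_niche()] objects.
#' @param n_native,n_introduced occurrence counts (>= 1).
#' @param seed integer RNG seed.
#' @return object of class `virtual_species_config`.
#' @export
virtual_species_config <- function(native, introduced,
                                   n_native = 400, n_introduced = 2000,
                                   seed = 1L) {
  stopifnot(inherits(native, "virtual_niche"),
            inherits(introduced, "virtual_niche"))
  if (n_native < 1 || n_introduced < 1)
    stop("occurrence counts must be >= 1", call. = FALSE)
  structure(list(native = native, introduced = introduced,
                 n_native = as.integer(n_native),
                 n_introduced = as.integer(n_introduced),
                 seed = as.integer(seed)),
            class = "virtual_species_config")
}

#' Simulate a virtual species study
#'
#' Convenience wrapper: generates occurrences for the native and introduced
#' niches over one landscape and returns them with the truth.
#'
#' @param stack a [predictor_stack()].
#' @param config a [virtual_species_config()].
#' @param occupancy_cutoff passed to [true_coue()].
#' @return list with `native`, `introduced` occurrence data.frames and
#'   `truth` (the [true_coue()] list).
#' @export
simulate_virtual_species <- function(stack, config, occupancy_cutoff = 0.05) {
  stopifnot(inherits(config, "virtual_species_config"))
  sn <- suitability_surface(stack, config$native)
  si <- suitability_surface(stack, config$introduced)
  occ_n <- sample_occurrences(sn, stack$grid, config$n_native,
                              seed = config$seed, population = "native")
  occ_i <- sample_occurrences(si, stack$grid, config$n_introduced,
                              seed = config$seed + 1L,
                              population = "introduced")
  list(native = occ_n, introduced = occ_i,
       truth = true_coue(config$native, config$introduced, stack,
                         occupancy_cutoff))
}
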