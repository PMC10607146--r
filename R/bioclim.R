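#' Monthly climate container
#'
#' Twelve aligned monthly rasters each for minimum temperature, maximum
#' temperature (deg C) and precipitation (mm) on one grid.
#'
#' @param tmin,tmax,prec lists of 12 matrices each.
#' @param grid a [grid_spec()].
#' @return object of class `monthly_climate`.
#' @export
monthly_climate <- function(tmin, tmax, prec, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(tmin) != 12 || length(tmax) != 12 || length(prec) != 12)
    stop("tmin, tmax and prec must each have 12 monthly layers",
         call. = FALSE)
  dims <- c(grid$n_rows, grid$n_cols)
  for (m in 1:12) {
    if (!all(dim(tmin[[m]]) == dims) || !all(dim(tmax[[m]]) == dims) ||
        !all(dim(prec[[m]]) == dims))
      stop("monthly layers must all match the grid dimensions",
           call. = FALSE)
    if (any(tmax[[m]] < tmin[[m]], na.rm = TRUE))
      stop("tmax < tmin in month ", m, call. = FALSE)
    if (any(prec[[m]] < 0, na.rm = TRUE))
      stop("negative precipitation in month ", m, call. = FALSE)
  }
  structure(list(tmin = tmin, tmax = tmax, prec = prec, grid = grid),
            class = "monthly_climate")
}

#' Compute the 19 bioclimatic variables
#'
#' Standard WorldClim/biovars definitions from 12-month minimum/maximum
#' temperature and precipitation grids. Monthly mean temperature is
#' `(tmin + tmax)/2` unless `tmean` is supplied. Quarters are all 12 cyclic
#' consecutive 3-month windows (Dec-Jan-Feb allowed); ties between windows
#' are broken by the earliest starting month. Standard deviations (Bio4,
#' Bio15) use the sample (n-1) convention; Bio15 uses the `1 + mean`
#' denominator so all-dry cells stay finite.
#'
#' Units: temperatures deg C, precipitation mm, Bio3 percent, Bio4 deg C x
#' 100, Bio15 percent. Cells with zero annual temperature range get NA Bio3.
#'
#' @param clim a [monthly_climate()].
#' @param tmean optional list of 12 monthly mean-temperature matrices.
#' @return a [predictor_stack()] with layers `bio1` ... `bio19`.
#' @export
compute_bioclim <- function(clim, tmean = NULL) {
  stopifnot(inherits(clim, "monthly_climate"))
  grid <- clim$grid
  nr <- grid$n_rows; nc <- grid$n_cols
  ncell <- nr * nc
  # months as columns of ncell x 12 matrices
  tmin <- vapply(clim$tmin, as.vector, numeric(ncell))
  tmax <- vapply(clim$tmax, as.vector, numeric(ncell))
  prec <- vapply(clim$prec, as.vector, numeric(ncell))
  tavg <- if (is.null(tmean)) (tmin + tmax) / 2
          else vapply(tmean, as.vector, numeric(ncell))

  row_sd <- function(m) apply(m, 1, stats::sd)
  bio1 <- rowMeans(tavg)
  bio2 <- rowMeans(tmax - tmin)
  bio4 <- row_sd(tavg) * 100
  bio5 <- apply(tmax, 1, max)
  bio6 <- apply(tmin, 1, min)
  bio7 <- bio5 - bio6
  bio3 <- ifelse(bio7 == 0, NA_real_, 100 * bio2 / bio7)
  bio12 <- rowSums(prec)
  bio13 <- apply(prec, 1, max)
  bio14 <- apply(prec, 1, min)
  bio15 <- 100 * row_sd(prec) / (1 + rowMeans(prec))

  # cyclic quarters: window w = months (w, w+1, w+2) mod 12
  qsum_p <- matrix(0, ncell, 12)
  qmean_t <- matrix(0, ncell, 12)
  for (w in 1:12) {
    idx <- ((w - 1):(w + 1)) %% 12 + 1
    qsum_p[, w] <- rowSums(prec[, idx, drop = FALSE])
    qmean_t[, w] <- rowMeans(tavg[, idx, drop = FALSE])
  }
  first_max <- function(m) max.col(m, ties.method = "first")
  first_min <- function(m) max.col(-m, ties.method = "first")
  pick <- function(m, w) m[cbind(seq_len(ncell), w)]

  wet <- first_max(qsum_p); dry <- first_min(qsum_p)
  warm <- first_max(qmean_t); cold <- first_min(qmean_t)
  bio8 <- pick(qmean_t, wet)
  bio9 <- pick(qmean_t, dry)
  bio10 <- pick(qmean_t, warm)
  bio11 <- pick(qmean_t, cold)
  bio16 <- pick(qsum_p, wet)
  bio17 <- pick(qsum_p, dry)
  bio18 <- pick(qsum_p, warm)
  bio19 <- pick(qsum_p, cold)

  vals <- list(bio1, bio2, bio3, bio4, bio5, bio6, bio7, bio8, bio9, bio10,
               bio11, bio12, bio13, bio14, bio15, bio16, bio17, bio18, bio19)
  layers <- lapply(vals, matrix, nrow = nr, ncol = nc)
  names(layers) <- paste0("bio", 1:19)
  predictor_stack(layers, grid)
}
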