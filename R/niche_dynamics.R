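#' PCA of the environmental background
#'
#' Predictors are standardized over the pooled background (zero mean, unit
#' variance, i.e. the correlation-matrix PCA) and the top two axes define
#' the niche space. Constant predictors are dropped with a warning.
#'
#' @param background_env data.frame of predictor values at pooled
#'   native + introduced background cells (>= 3 rows, >= 3 predictors
#'   recommended).
#' @return object of class `env_pca` with `$rotation`, `$center`, `$scale`,
#'   `$explained` (variance fractions of the two axes).
#' @export
pca_env <- function(background_env) {
  keep <- vapply(background_env, function(v) stats::sd(v) > 0, TRUE)
  if (any(!keep))
    warning("dropping constant predictor(s): ",
            paste(names(background_env)[!keep], collapse = ", "),
            call. = FALSE)
  background_env <- background_env[keep]
  if (ncol(background_env) < 2)
    stop("need at least 2 non-constant predictors", call. = FALSE)
  p <- stats::prcomp(background_env, center = TRUE, scale. = TRUE)
  structure(list(rotation = p$rotation[, 1:2, drop = FALSE],
                 center = p$center, scale = p$scale,
                 explained = (p$sdev^2 / sum(p$sdev^2))[1:2],
                 predictors = names(background_env)),
            class = "env_pca")
}

#' Project environmental values onto the PCA axes
#'
#' @param pca an [pca_env()] result.
#' @param env data.frame with the PCA's predictor columns.
#' @return n x 2 matrix of scores.
#' @export
project_env <- function(pca, env) {
  m <- scale(as.matrix(env[pca$predictors]), pca$center, pca$scale)
  m %*% pca$rotation
}

# Gaussian product-kernel density of points evaluated at grid cell centres.
# Returns an R x R matrix (rows = x cells, cols = y cells), unnormalized.
kernel_density_grid <- function(pts, gx, gy, bw) {
  dx <- outer(gx, pts[, 1], function(g, p) stats::dnorm(g - p, sd = bw[1]))
  dy <- outer(gy, pts[, 2], function(g, p) stats::dnorm(g - p, sd = bw[2]))
  (dx %*% t(dy)) / nrow(pts)
}

#' Kernel-smoothed occurrence and background density in niche space
#'
#' Gaussian product-kernel densities of the occurrence scores and of the
#' background scores, evaluated at the centres of an `R x R` grid spanning
#' the supplied limits (by default the occurrence/background bounding box).
#' Both densities are renormalized to sum to one. The occupancy surface
#' `z_uncor` is occurrence density divided by its maximum, zeroed where the
#' background density is zero. Bandwidths default to the normal-reference
#' (Silverman) rule per axis on the occurrence scores.
#'
#' @param occ_scores n x 2 matrix of occurrence PCA scores (n >= 5).
#' @param background_scores m x 2 matrix of background PCA scores.
#' Because a Gaussian kernel is positive everywhere, raw density never
#' vanishes; occupancy needs a support cutoff. Cells whose occupancy falls
#' below `z_thresh` times the maximum are treated as unoccupied (zeroed in
#' `z_uncor`), and background cells below the same fraction of the maximum
#' background density are treated as unavailable. The default 0.05 mirrors
#' the 5%-of-maximum suitability cutoff used to delimit the true niche of a
#' virtual species, and is what makes the COUE expansion/unfilling
#' fractions well defined on a kernel-smoothed grid.
#'
#' @param R cells per axis; default 100.
#' @param limits list with `x` and `y` ranges; default: pooled bounding box
#'   of `background_scores` (pass the pooled background of both populations
#'   so grids are comparable).
#' @param bandwidth optional length-2 numeric bandwidth.
#' @param z_thresh occupancy support cutoff as a fraction of the maximum
#'   occurrence density; default 0.05.
#' @return object of class `env_space_grid` with `x`, `y`, `z_occ`, `z_env`,
#'   `z_uncor`, `bandwidth`.
#' @export
density_grid <- function(occ_scores, background_scores, R = 100,
                         limits = NULL, bandwidth = NULL,
                         z_thresh = 0.05) {
  occ_scores <- as.matrix(occ_scores)
  background_scores <- as.matrix(background_scores)
  if (nrow(occ_scores) < 5)
    stop("need at least 5 occurrence points", call. = FALSE)
  if (is.null(limits))
    limits <- list(x = range(background_scores[, 1]),
                   y = range(background_scores[, 2]))
  gx <- seq(limits$x[1], limits$x[2], length.out = R)
  gy <- seq(limits$y[1], limits$y[2], length.out = R)
  # floor bandwidths at half a grid-cell spacing so degenerate point sets
  # (e.g. all records in one spot) still yield a usable density
  floor_bw <- c(max(diff(gx)[1] / 2, 1e-12), max(diff(gy)[1] / 2, 1e-12))
  safe_bw <- function(b) ifelse(is.finite(b) & b > floor_bw, b, floor_bw)
  bw <- safe_bw(bandwidth %||% c(stats::bw.nrd0(occ_scores[, 1]),
                                 stats::bw.nrd0(occ_scores[, 2])))
  z_occ <- kernel_density_grid(occ_scores, gx, gy, bw)
  bw_env <- safe_bw(bandwidth %||%
                      c(stats::bw.nrd0(background_scores[, 1]),
                        stats::bw.nrd0(background_scores[, 2])))
  z_env <- kernel_density_grid(background_scores, gx, gy, bw_env)
  # support cutoff: the Gaussian kernel is positive everywhere, so
  # "available" and "occupied" need a numerical support definition
  z_env[z_env < max(z_env) * z_thresh] <- 0
  z_occ <- z_occ / sum(z_occ)
  z_env <- z_env / sum(z_env)
  z_uncor <- z_occ / max(z_occ)
  z_uncor[z_uncor < z_thresh] <- 0
  z_uncor[z_env <= 0] <- 0
  structure(list(x = gx, y = gy, z_occ = z_occ, z_env = z_env,
                 z_uncor = z_uncor, bandwidth = bw),
            class = "env_space_grid")
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` with each occupancy grid normalized to
#' sum to one; symmetric, in `[0, 1]`.
#'
#' @param z1,z2 occupancy grids (matrices of equal shape).
#' @return D in `[0, 1]`.
#' @export
schoener_D <- function(z1, z2) {
  if (!all(dim(z1) == dim(z2)))
    stop("occupancy grids have different shapes", call. = FALSE)
  z1 <- z1 / sum(z1)
  z2 <- z2 / sum(z2)
  1 - 0.5 * sum(abs(z1 - z2))
}

#' COUE decomposition container
#'
#' @param E,S,U expansion, stability, unfilling fractions; `E + S` must
#'   equal 1 and all lie in `[0, 1]`.
#' @return object of class `coue_decomposition`.
#' @export
coue_decomposition <- function(E, S, U) {
  if (any(c(E, S, U) < -1e-9) || any(c(E, S, U) > 1 + 1e-9))
    stop("E, S, U must lie in [0, 1]", call. = FALSE)
  if (abs(E + S - 1) > 1e-9)
    stop("E + S must equal 1", call. = FALSE)
  structure(list(E = E, S = S, U = U), class = "coue_decomposition")
}

#' COUE indices from two occupancy grids
#'
#' Expansion E is the introduced density mass lying in cells unoccupied by
#' the native population, as a fraction of total introduced mass;
#' S = 1 - E; unfilling U is the native mass in cells unoccupied by the
#' introduced population, as a fraction of total native mass. With
#' `analog_only = TRUE` (default) the computation is restricted to analog
#' environments: cells where both backgrounds have positive density.
#'
#' @param g_native,g_introduced [density_grid()] results on the same grid.
#' @param analog_only restrict to shared (analog) environments.
#' @return a [coue_decomposition()].
#' @export
coue_indices <- function(g_native, g_introduced, analog_only = TRUE) {
  zn <- g_native$z_uncor
  zi <- g_introduced$z_uncor
  if (!all(dim(zn) == dim(zi)))
    stop("grids have different shapes", call. = FALSE)
  mask <- if (analog_only)
    g_native$z_env > 0 & g_introduced$z_env > 0
  else matrix(TRUE, nrow(zn), ncol(zn))
  # density mass is counted over each population's occupied cells only
  wn <- g_native$z_occ * (zn > 0) * mask
  wi <- g_introduced$z_occ * (zi > 0) * mask
  if (sum(wn) == 0 || sum(wi) == 0)
    stop("empty occupancy after masking", call. = FALSE)
  E <- sum(wi[zn == 0]) / sum(wi)
  U <- sum(wn[zi == 0]) / sum(wn)
  coue_decomposition(E = E, S = 1 - E, U = U)
}

#' Niche breadth ratio
#'
#' With the introduced niche breadth normalized to IB = S + E = 1 and the
#' native breadth NB = S + U in the same units, `BR = IB / NB = 1/(S + U)`;
#' BR > 1 means the introduced niche is wider.
#'
#' @param d a [coue_decomposition()] (or list with `E`, `S`, `U`).
#' @return BR.
#' @export
breadth_ratio <- function(d) {
  if (d$S + d$U == 0) stop("S + U is zero; BR undefined", call. = FALSE)
  (d$S + d$E) / (d$S + d$U)
}

#' Niche similarity index
#'
#' `SI = 2S / (IB + NB) = 2S / (1 + S + U)`; SI > 0.5 indicates similar
#' niche positions.
#'
#' @param d a [coue_decomposition()] (or list with `E`, `S`, `U`).
#' @return SI in `[0, 1]`.
#' @export
niche_similarity_index <- function(d) {
  2 * d$S / ((d$S + d$E) + (d$S + d$U))
}

#' Niche conservatism verdict
#'
#' The niche is called not conserved only when the introduced population
#' both shifted position (SI < 0.5) and widened its breadth (BR > 1).
#'
#' @param BR breadth ratio.
#' @param SI niche similarity index.
#' @return "conserved" or "not_conserved".
#' @export
conservatism_verdict <- function(BR, SI) {
  if (!is.finite(BR) || !is.finite(SI))
    stop("BR and SI must be finite", call. = FALSE)
  if (SI < 0.5 && BR > 1) "not_conserved" else "conserved"
}

#' Niche equivalency permutation test
#'
#' Null: the two occurrence sets are random draws from the pooled set.
#' Occurrences are pooled and re-split preserving group sizes; D is
#' recomputed each time. One-sided p for the "lower equivalency than
#' random" alternative: `p = (1 + #\{D_null <= D_obs\}) / (n_perm + 1)`.
#'
#' @param scores1,scores2 occurrence PCA score matrices.
#' @param background_scores pooled background scores (fixes the grid).
#' @param R grid resolution; default 100.
#' @param n_perm permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list with `D_obs`, `p`, `D_null`.
#' @export
equivalency_test <- function(scores1, scores2, background_scores, R = 100,
                             n_perm = 99, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  scores1 <- as.matrix(scores1); scores2 <- as.matrix(scores2)
  limits <- list(x = range(background_scores[, 1]),
                 y = range(background_scores[, 2]))
  zg <- function(s) density_grid(s, background_scores, R, limits)$z_uncor
  D_obs <- schoener_D(zg(scores1), zg(scores2))
  pool <- rbind(scores1, scores2)
  n1 <- nrow(scores1)
  set.seed(seed)
  D_null <- vapply(seq_len(n_perm), function(k) {
    idx <- sample(nrow(pool), n1)
    schoener_D(zg(pool[idx, , drop = FALSE]),
               zg(pool[-idx, , drop = FALSE]))
  }, 0)
  list(D_obs = D_obs, p = (1 + sum(D_null <= D_obs)) / (n_perm + 1),
       D_null = D_null)
}

#' Niche similarity permutation test
#'
#' Null: niche 2 sits at a random position within its own available
#' environment. Each permutation translates the second population's scores
#' so their centroid lands on a uniform random point inside background 2's
#' bounding box, then recomputes D against niche 1. One-sided p for the
#' "more similar than random" alternative:
#' `p = (1 + #\{D_null >= D_obs\}) / (n_perm + 1)`.
#'
#' @param scores1,scores2 occurrence PCA score matrices.
#' @param background2_scores background scores available to population 2.
#' @param background_scores pooled background scores fixing the grid
#'   (defaults to `background2_scores`).
#' @param R grid resolution; default 100.
#' @param n_perm permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list with `D_obs`, `p`, `D_null`.
#' @export
similarity_test <- function(scores1, scores2, background2_scores,
                            background_scores = background2_scores,
                            R = 100, n_perm = 99, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  scores1 <- as.matrix(scores1); scores2 <- as.matrix(scores2)
  bx <- range(background2_scores[, 1])
  by <- range(background2_scores[, 2])
  if (diff(bx) == 0 || diff(by) == 0)
    stop("background 2 is too small to shift the niche within",
         call. = FALSE)
  limits <- list(x = range(background_scores[, 1]),
                 y = range(background_scores[, 2]))
  zg <- function(s) density_grid(s, background_scores, R, limits)$z_uncor
  z1 <- zg(scores1)
  D_obs <- schoener_D(z1, zg(scores2))
  ctr <- colMeans(scores2)
  set.seed(seed)
  D_null <- vapply(seq_len(n_perm), function(k) {
    target <- c(stats::runif(1, bx[1], bx[2]), stats::runif(1, by[1], by[2]))
    shifted <- sweep(scores2, 2, ctr - target)
    schoener_D(z1, zg(shifted))
  }, 0)
  list(D_obs = D_obs, p = (1 + sum(D_null >= D_obs)) / (n_perm + 1),
       D_null = D_null)
}

#' End-to-end niche dynamics between two populations
#'
#' Runs the full COUE workflow: correlation-matrix PCA on the pooled
#' background, kernel density grids at `R x R` resolution, COUE indices,
#' Schoener's D, breadth ratio, similarity index and the conservatism
#' verdict; optionally the equivalency and similarity permutation tests.
#'
#' @param occ_env_native,occ_env_introduced data.frames of predictor values
#'   at occurrence records.
#' @param bg_env_native,bg_env_introduced data.frames of predictor values
#'   at background cells of each population's study region.
#' @param R grid resolution; default 100.
#' @param analog_only restrict COUE to analog environments; default TRUE.
#' @param n_perm permutations for the tests (0 = skip tests).
#' @param seed integer RNG seed.
#' @return list: `coue` ([coue_decomposition()]), `D`, `BR`, `SI`,
#'   `verdict`, `pca`, `equivalency`, `similarity`.
#' @export
niche_dynamics <- function(occ_env_native, occ_env_introduced,
                           bg_env_native, bg_env_introduced,
                           R = 100, analog_only = TRUE, n_perm = 0,
                           seed = 1L) {
  pooled_bg <- rbind(bg_env_native, bg_env_introduced)
  pca <- pca_env(pooled_bg)
  s_on <- project_env(pca, occ_env_native)
  s_oi <- project_env(pca, occ_env_introduced)
  s_bn <- project_env(pca, bg_env_native)
  s_bi <- project_env(pca, bg_env_introduced)
  pooled <- rbind(s_bn, s_bi)
  limits <- list(x = range(pooled[, 1]), y = range(pooled[, 2]))
  g_n <- density_grid(s_on, s_bn, R, limits)
  g_i <- density_grid(s_oi, s_bi, R, limits)
  d <- coue_indices(g_n, g_i, analog_only)
  BR <- breadth_ratio(d)
  SI <- niche_similarity_index(d)
  res <- list(coue = d, D = schoener_D(g_n$z_uncor, g_i$z_uncor),
              BR = BR, SI = SI,
              verdict = conservatism_verdict(BR, SI),
              pca = pca, grids = list(native = g_n, introduced = g_i))
  if (n_perm > 0) {
    res$equivalency <- equivalency_test(s_on, s_oi, pooled, R, n_perm, seed)
    res$similarity <- similarity_test(s_on, s_oi, s_bi, pooled, R, n_perm,
                                      seed + 1L)
  }
  res
}
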