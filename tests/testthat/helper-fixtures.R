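# Shared fixture builders. Everything is generated in code; no data files.

# small deterministic landscape with three gradient layers
toy_landscape <- function(n = 40, noise_sd = 0.4, seed = 11L) {
  generate_landscape(landscape_config(
    n_rows = n, n_cols = n, n_gradient_layers = 3,
    noise_sd = noise_sd, autocorrelation_range = 2, seed = seed))
}

# occurrence data.frame from raw coordinates
occ_df <- function(lon, lat, uncertainty_km = NA_real_,
                   population = "unassigned") {
  data.frame(lon = lon, lat = lat,
             uncertainty_km = rep_len(uncertainty_km, length(lon)),
             source = "test", population = rep_len(population, length(lon)),
             stringsAsFactors = FALSE)
}

# constant-valued monthly climate on a tiny grid
constant_climate <- function(tmean = 10, diurnal = 5, prec = 100,
                             n = 3) {
  g <- grid_spec(n, n, cell_size_deg = 0.5)
  m <- function(v) matrix(v, n, n)
  monthly_climate(tmin = replicate(12, m(tmean - diurnal), simplify = FALSE),
                  tmax = replicate(12, m(tmean + diurnal), simplify = FALSE),
                  prec = replicate(12, m(prec), simplify = FALSE),
                  grid = g)
}

# climate whose monthly means are an arbitrary 12-vector (same in all cells)
vector_climate <- function(tmean_by_month, prec_by_month = rep(100, 12),
                           diurnal = 5, n = 2) {
  g <- grid_spec(n, n, cell_size_deg = 0.5)
  m <- function(v) matrix(v, n, n)
  monthly_climate(
    tmin = lapply(tmean_by_month, function(t) m(t - diurnal)),
    tmax = lapply(tmean_by_month, function(t) m(t + diurnal)),
    prec = lapply(prec_by_month, m),
    grid = g)
}

# fully independent scalar-loop bioclim oracle (slow, per cell)
bioclim_oracle_cell <- function(tmin, tmax, prec) {
  tavg <- (tmin + tmax) / 2
  q <- function(v, w) {
    idx <- ((w - 1):(w + 1)) %% 12 + 1
    v[idx]
  }
  qp <- sapply(1:12, function(w) sum(q(prec, w)))
  qt <- sapply(1:12, function(w) mean(q(tavg, w)))
  wet <- which.max(qp); dry <- which.min(qp)
  warm <- which.max(qt); cold <- which.min(qt)
  b5 <- max(tmax); b6 <- min(tmin); b7 <- b5 - b6
  b2 <- mean(tmax - tmin)
  c(bio1 = mean(tavg), bio2 = b2,
    bio3 = if (b7 == 0) NA_real_ else 100 * b2 / b7,
    bio4 = stats::sd(tavg) * 100, bio5 = b5, bio6 = b6, bio7 = b7,
    bio8 = qt[wet], bio9 = qt[dry], bio10 = qt[warm], bio11 = qt[cold],
    bio12 = sum(prec), bio13 = max(prec), bio14 = min(prec),
    bio15 = 100 * stats::sd(prec) / (1 + mean(prec)),
    bio16 = qp[wet], bio17 = qp[dry], bio18 = qp[warm], bio19 = qp[cold])
}

# brute-force AUC: count presence/absence pairs (ties = 1/2)
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force TSS over all observed thresholds
tss_oracle <- function(scores, labels) {
  best <- -Inf
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    best <- max(best, sens + spec - 1)
  }
  best
}

# fake niche-space grid for COUE counting tests
fake_grid <- function(z_occ, z_env = NULL) {
  if (is.null(z_env)) z_env <- matrix(1, nrow(z_occ), ncol(z_occ))
  z_occ <- z_occ / sum(z_occ)
  structure(list(z_occ = z_occ, z_env = z_env / sum(z_env),
                 z_uncor = z_occ / max(z_occ)),
            class = "env_space_grid")
}
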