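#' Permutation variable importance
#'
#' For each predictor, predictions on the original data are compared with
#' predictions after permuting that predictor's column: importance is
#' `1 - cor(pred_original, pred_permuted)` averaged over `n_shuffles`
#' permutations and clamped to `[0, 1]` (a negative correlation counts as
#' full importance). A predictor the model ignores leaves predictions
#' unchanged and scores 0. For an ensemble, member importances are averaged
#' with the ensemble weights.
#'
#' @param model a fitted model from [fit_algorithm()] (anything with a
#'   `predict_suitability` method), or an [build_ensemble()] result.
#' @param data data.frame of predictor values to permute over.
#' @param n_shuffles number of permutations per predictor.
#' @param seed integer RNG seed.
#' @return named numeric vector of importances in `[0, 1]`.
#' @export
variable_importance <- function(model, data, n_shuffles = 3, seed = 1L) {
  if (inherits(model, "ensemble_model")) {
    imps <- lapply(seq_along(model$members), function(i)
      variable_importance(model$members[[i]], data, n_shuffles,
                          seed = seed + i))
    w <- model$weights
    out <- Reduce(`+`, Map(`*`, imps, w))
    return(out / sum(w))
  }
  base_pred <- predict_suitability(model, data)
  out <- stats::setNames(numeric(ncol(data)), names(data))
  if (stats::sd(base_pred) == 0) {
    warning("model predictions are constant; importances set to 0",
            call. = FALSE)
    return(out)
  }
  set.seed(seed)
  for (p in names(data)) {
    vals <- numeric(n_shuffles)
    for (s in seq_len(n_shuffles)) {
      shuf <- data
      shuf[[p]] <- shuf[[p]][sample.int(nrow(data))]
      pp <- predict_suitability(model, shuf)
      r <- if (stats::sd(pp) == 0) {
        # permutation flattened the response: treat as uncorrelated
        0
      } else suppressWarnings(stats::cor(base_pred, pp))
      if (is.na(r)) r <- 0
      vals[s] <- min(1, max(0, 1 - r))
    }
    out[p] <- mean(vals)
  }
  out
}

#' Iteratively prune collinear predictors
#'
#' While any off-diagonal correlation exceeds the threshold in absolute
#' value, the most collinear pair is found and its lower-importance member
#' dropped (importance ties are broken by dropping the lexicographically
#' later name). Deterministic given the correlation matrix and importances.
#'
#' @param corr symmetric correlation matrix with unit diagonal, dimnames =
#'   predictor names.
#' @param importance named numeric vector covering all predictors in `corr`.
#' @param threshold absolute-correlation cutoff; default 0.7.
#' @return character vector of retained predictor names (input order).
#' @export
prune_collinear <- function(corr, importance, threshold = 0.7) {
  nms <- rownames(corr)
  if (is.null(nms) || !all(nms %in% names(importance)))
    stop("correlation matrix and importance names do not match",
         call. = FALSE)
  keep <- nms
  repeat {
    sub <- abs(corr[keep, keep, drop = FALSE])
    diag(sub) <- 0
    if (length(keep) < 2 || max(sub) <= threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    drop <- if (importance[a] < importance[b]) a
            else if (importance[b] < importance[a]) b
            else max(a, b)  # tie: lexicographically later name goes
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Pearson correlation matrix of predictors at modelling cells
#'
#' Correlations are computed on predictor values sampled at presence plus
#' background cells (the modelling domain), not over every grid cell.
#'
#' @param stack a [predictor_stack()].
#' @param lon,lat coordinates of presence + background points.
#' @return correlation matrix.
#' @export
predictor_correlation <- function(stack, lon, lat) {
  vals <- extract_values(stack, lon, lat)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  stats::cor(vals)
}
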