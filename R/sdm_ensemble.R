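#' Sample pseudo-absences and build training tables
#'
#' Pseudo-absence count follows the rule: as many as the presences when
#' there are strictly more than 1000 presences, otherwise 1000. Cells are
#' drawn uniformly from the domain mask excluding cells that contain a
#' presence; each replicate is an independent draw. Presences are taken at
#' their recorded coordinates, pseudo-absences at cell centres.
#'
#' @param presences occurrence data.frame (`lon`, `lat`).
#' @param stack a [predictor_stack()] supplying predictor values.
#' @param domain logical matrix (TRUE = selectable cell) on the stack grid,
#'   or NULL for all cells.
#' @param replicates number of independent pseudo-absence draws; default 3.
#' @param seed integer RNG seed.
#' @return list of `replicates` training tables: data.frames of predictor
#'   columns plus `label` (1 presence / 0 pseudo-absence) and `replicate`.
#' @export
sample_pseudo_absences <- function(presences, stack, domain = NULL,
                                   replicates = 3, seed = 1L) {
  grid <- stack$grid
  if (is.null(domain)) domain <- matrix(TRUE, grid$n_rows, grid$n_cols)
  n_pres <- nrow(presences)
  n_pa <- if (n_pres > 1000) n_pres else 1000
  idx <- cell_index(grid, presences$lon, presences$lat)
  occupied <- matrix(FALSE, grid$n_rows, grid$n_cols)
  ok <- !is.na(idx$row)
  occupied[cbind(idx$row[ok], idx$col[ok])] <- TRUE
  free <- which(domain & !occupied)
  if (length(free) < n_pa)
    stop("domain has only ", length(free), " free cells; ", n_pa,
         " pseudo-absences requested", call. = FALSE)
  pres_env <- extract_values(stack, presences$lon, presences$lat)
  ctr <- grid_centers(grid)
  set.seed(seed)
  lapply(seq_len(replicates), function(r) {
    cells <- sample(free, n_pa)
    row <- (cells - 1) %% grid$n_rows + 1
    col <- (cells - 1) %/% grid$n_rows + 1
    pa_env <- extract_values(stack, ctr$lon[col], ctr$lat[row])
    tab <- rbind(cbind(pres_env, label = 1), cbind(pa_env, label = 0))
    tab$replicate <- r
    tab <- tab[stats::complete.cases(tab), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
}

predictor_columns <- function(train)
  setdiff(names(train), c("label", "replicate"))

#' Names of the supported suitability algorithms
#' @return character vector of registry names.
#' @export
sdm_algorithms <- function()
  c("GLM", "CTA", "ANN", "FDA", "MARS", "GBM", "RF", "MAXENT", "SRE")

#' Fit one suitability algorithm
#'
#' A uniform plugin contract over standard classifier families: every
#' fitted model predicts a suitability score in `[0, 1]` via
#' [predict_suitability()]. Backends: GLM = binomial `glm`; CTA =
#' classification tree (rpart); ANN = single-hidden-layer network (nnet,
#' standardized inputs); FDA = discriminant analysis on a quadratic basis
#' expansion (MASS); MARS = adaptive spline regression via thin-plate
#' smooths (mgcv); GBM = gradient-boosted trees (xgboost); RF = random
#' forest (randomForest); MAXENT = penalized logistic regression on
#' linear + quadratic features, maxnet-style (glmnet); SRE = surface range
#' envelope, implemented natively: score 1 iff every predictor lies inside
#' the presence quantile envelope `[q, 1-q]`.
#'
#' @param name algorithm name, one of [sdm_algorithms()].
#' @param train training table (predictors + `label`).
#' @param hyperparams optional named list (e.g. `sre_quantile`, `ann_size`,
#'   `gbm_nrounds`).
#' @param seed integer RNG seed for stochastic learners.
#' @return object of class `sdm_model`.
#' @export
fit_algorithm <- function(name, train, hyperparams = list(), seed = 1L) {
  if (!name %in% sdm_algorithms())
    stop("unknown algorithm: ", name, call. = FALSE)
  if (length(unique(train$label)) < 2)
    stop("training data has a single class", call. = FALSE)
  preds <- predictor_columns(train)
  x <- train[preds]
  y <- train$label
  set.seed(seed)
  fit <- switch(
    name,
    GLM = stats::glm(y ~ ., data = cbind(x, y = y),
                     family = stats::binomial()),
    CTA = rpart::rpart(y ~ ., data = cbind(x, y = factor(y)),
                       method = "class",
                       control = rpart::rpart.control(xval = 0)),
    ANN = {
      ctr <- vapply(x, mean, 0); scl <- vapply(x, stats::sd, 0)
      scl[scl == 0] <- 1
      xs <- scale(as.matrix(x), ctr, scl)
      size <- hyperparams$ann_size %||% 4
      list(net = nnet::nnet(xs, y, size = size, decay = 0.01,
                            maxit = 300, entropy = TRUE, trace = FALSE),
           center = ctr, scale = scl)
    },
    FDA = {
      xb <- quadratic_basis(x)
      list(lda = MASS::lda(xb, grouping = factor(y)), cols = preds)
    },
    MARS = {
      k <- hyperparams$mars_k %||% 5
      terms <- vapply(preds, function(p) {
        if (length(unique(x[[p]])) > k) sprintf("s(%s, k = %d)", p, k)
        else p
      }, "")
      f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
      mgcv::gam(f, data = cbind(x, y = y), family = stats::binomial(),
                method = "REML")
    },
    GBM = {
      nrounds <- hyperparams$gbm_nrounds %||% 60
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = dtrain, nrounds = nrounds, verbose = 0)
    },
    RF = randomForest::randomForest(x, factor(y),
                                    ntree = hyperparams$rf_ntree %||% 300),
    MAXENT = {
      xb <- quadratic_basis(x)
      ctr <- colMeans(xb); scl <- apply(xb, 2, stats::sd)
      scl[scl == 0] <- 1
      xs <- scale(xb, ctr, scl)
      list(glmnet = glmnet::glmnet(xs, y, family = "binomial",
                                   alpha = 0.5,
                                   lambda = hyperparams$maxent_lambda %||%
                                     0.001),
           center = ctr, scale = scl, cols = preds)
    },
    SRE = {
      q <- hyperparams$sre_quantile %||% 0.025
      pres <- x[y == 1, , drop = FALSE]
      list(lo = vapply(pres, stats::quantile, 0, probs = q, names = FALSE),
           hi = vapply(pres, stats::quantile, 0, probs = 1 - q,
                       names = FALSE))
    })
  structure(list(algorithm = name, fit = fit, predictors = preds),
            class = "sdm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quadratic_basis <- function(x) {
  m <- as.matrix(x)
  cbind(m, m^2)
}

#' Predict suitability scores in [0, 1]
#'
#' @param model an `sdm_model` or `ensemble_model`.
#' @param data data.frame containing the model's predictor columns.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict_suitability <- function(model, data) UseMethod("predict_suitability")

#' @export
predict_suitability.sdm_model <- function(model, data) {
  x <- data[model$predictors]
  fit <- model$fit
  out <- switch(
    model$algorithm,
    GLM = stats::predict(fit, newdata = x, type = "response"),
    CTA = stats::predict(fit, newdata = x, type = "prob")[, "1"],
    ANN = {
      xs <- scale(as.matrix(x), fit$center, fit$scale)
      as.vector(stats::predict(fit$net, xs))
    },
    FDA = stats::predict(fit$lda, quadratic_basis(x))$posterior[, "1"],
    MARS = as.vector(stats::predict(fit, newdata = x, type = "response")),
    GBM = stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(x),
                                                   nthread = 1)),
    RF = stats::predict(fit, x, type = "prob")[, "1"],
    MAXENT = {
      xs <- scale(quadratic_basis(x), fit$center, fit$scale)
      as.vector(stats::predict(fit$glmnet, xs, type = "response"))
    },
    SRE = {
      ok <- rep(TRUE, nrow(x))
      for (j in seq_along(model$predictors))
        ok <- ok & x[[j]] >= fit$lo[j] & x[[j]] <= fit$hi[j]
      as.numeric(ok)
    })
  pmin(1, pmax(0, as.numeric(out)))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUC with ties counted one half: equals the fraction of
#' presence/absence score pairs in which the presence scores higher.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic and its maximizing threshold
#'
#' TSS = max over all distinct score thresholds of sensitivity +
#' specificity - 1, predicting presence at `score >= threshold`. The
#' smallest threshold achieving the maximum is reported.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return list with `tss` and `threshold`.
#' @export
tss_stat <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("TSS needs both classes", call. = FALSE)
  th <- sort(unique(scores))
  best <- -Inf; best_th <- th[1]
  for (t in th) {
    sens <- sum(scores[pos] >= t) / n1
    spec <- sum(scores[!pos] < t) / n0
    v <- sens + spec - 1
    if (v > best + 1e-12) { best <- v; best_th <- t }
  }
  list(tss = best, threshold = best_th)
}

#' Evaluate a fitted model on a test table
#'
#' @param model an `sdm_model` (or anything [predict_suitability()] accepts).
#' @param test test table with predictor columns and `label`.
#' @return one-row data.frame: `algorithm`, `AUC`, `TSS`, `tss_threshold`.
#' @export
evaluate <- function(model, test) {
  if (length(unique(test$label)) < 2)
    stop("test data has a single class", call. = FALSE)
  sc <- predict_suitability(model, test)
  ts <- tss_stat(sc, test$label)
  data.frame(algorithm = if (inherits(model, "sdm_model"))
               model$algorithm else "ensemble",
             AUC = auc_mw(sc, test$label),
             TSS = ts$tss, tss_threshold = ts$threshold,
             stringsAsFactors = FALSE)
}

#' Repeated stratified cross-validation over algorithms and replicates
#'
#' For every pseudo-absence replicate and repeat: a stratified random
#' 70/30 split, models fitted on the 70%, evaluated on the 30%.
#'
#' @param tables list of training tables from [sample_pseudo_absences()].
#' @param algorithms character vector of algorithm names.
#' @param train_fraction training fraction; default 0.7.
#' @param repeats number of random splits; default 5.
#' @param seed integer RNG seed.
#' @param hyperparams passed to [fit_algorithm()].
#' @return data.frame of evaluations with `algorithm`, `replicate`,
#'   `repeat_id`, `AUC`, `TSS`, `tss_threshold`.
#' @export
cross_validate <- function(tables, algorithms, train_fraction = 0.7,
                           repeats = 5, seed = 1L, hyperparams = list()) {
  if (is.data.frame(tables)) tables <- list(tables)
  res <- list()
  for (ri in seq_along(tables)) {
    tab <- tables[[ri]]
    for (rep_id in seq_len(repeats)) {
      split_seed <- seed + 1000L * ri + rep_id
      idx <- stratified_split(tab$label, train_fraction, split_seed)
      train <- tab[idx, , drop = FALSE]
      test <- tab[-idx, , drop = FALSE]
      if (length(unique(train$label)) < 2 ||
          length(unique(test$label)) < 2)
        stop("degenerate split: one side lost a class", call. = FALSE)
      for (alg in algorithms) {
        m <- fit_algorithm(alg, train, hyperparams, seed = split_seed)
        ev <- evaluate(m, test)
        ev$replicate <- unique(tab$replicate)[1]
        ev$repeat_id <- rep_id
        res[[length(res) + 1]] <- ev
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

stratified_split <- function(labels, train_fraction, seed) {
  set.seed(seed)
  idx <- integer(0)
  for (cl in unique(labels)) {
    pool <- which(labels == cl)
    idx <- c(idx, sample(pool, max(1, round(train_fraction * length(pool)))))
  }
  sort(idx)
}

#' Build a TSS-weighted ensemble
#'
#' Evaluations are averaged per algorithm; algorithms pass the inclusion
#' rule when mean AUC > `auc_min` or mean TSS > `tss_min`. Included members
#' get weight proportional to their mean TSS; the ensemble score is the
#' weighted mean of member scores.
#'
#' @param models named list of fitted `sdm_model`s (one per algorithm).
#' @param evaluations data.frame from [cross_validate()].
#' @param auc_min,tss_min inclusion thresholds (defaults 0.8 / 0.6).
#' @return object of class `ensemble_model` with members, weights and the
#'   per-algorithm mean evaluations (`included` flag attached).
#' @export
build_ensemble <- function(models, evaluations, auc_min = 0.8,
                           tss_min = 0.6) {
  agg <- stats::aggregate(evaluations[c("AUC", "TSS")],
                          by = list(algorithm = evaluations$algorithm),
                          FUN = mean)
  agg <- agg[match(names(models), agg$algorithm), ]
  agg$included <- agg$AUC > auc_min | agg$TSS > tss_min
  if (!any(agg$included))
    stop("no qualifying models: every algorithm failed the inclusion rule",
         call. = FALSE)
  w <- ifelse(agg$included, pmax(agg$TSS, 0), 0)
  if (sum(w) == 0)
    stop("no qualifying models: included members have non-positive TSS",
         call. = FALSE)
  w <- w / sum(w)
  structure(list(members = models, weights = w, evaluations = agg),
            class = "ensemble_model")
}

#' @export
predict_suitability.ensemble_model <- function(model, data) {
  out <- numeric(nrow(data))
  for (i in seq_along(model$members))
    if (model$weights[i] > 0)
      out <- out + model$weights[i] *
        predict_suitability(model$members[[i]], data)
  out
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("TSS-weighted ensemble of", sum(x$weights > 0), "member(s)\n")
  print(cbind(x$evaluations, weight = round(x$weights, 3)))
  invisible(x)
}

#' Project ensemble (or single-model) suitability over a stack
#'
#' @param model an `sdm_model` or `ensemble_model`.
#' @param stack a [predictor_stack()].
#' @return suitability matrix on the stack grid.
#' @export
predict_surface <- function(model, stack) {
  grid <- stack$grid
  df <- as.data.frame(lapply(stack$layers, as.vector))
  matrix(predict_suitability(model, df), grid$n_rows, grid$n_cols)
}

#' Maximum sensitivity + specificity threshold
#'
#' The smallest observed score that maximizes sensitivity + specificity
#' when predicting presence at `score >= threshold`; cells at or above it
#' form the binary potential range.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return threshold value.
#' @export
max_sens_spec_threshold <- function(scores, labels) {
  if (length(unique(labels)) < 2)
    stop("threshold selection needs both classes", call. = FALSE)
  if (length(unique(scores)) == 1) {
    warning("all scores identical; degenerate threshold", call. = FALSE)
    return(scores[1])
  }
  tss_stat(scores, labels)$threshold
}

#' Null-model significance test for an SDM
#'
#' Real presences are split 70/30; the 30% is held out. Each null run
#' replaces the training presences with uniformly random domain cells
#' (count = 70% of the real presences), fits the algorithm against the
#' training pseudo-absences, and evaluates AUC on the held-out real
#' presences + held-out pseudo-absences. The p-value uses the
#' `(r + 1) / (n + 1)` rank convention.
#'
#' @param real_auc AUC of the real model, evaluated on the same held-out
#'   test set construction.
#' @param presence_env data.frame of predictor values at real presences.
#' @param absence_env data.frame of predictor values at pseudo-absences.
#' @param domain_env data.frame of predictor values at all candidate
#'   domain cells (null presences are drawn from these rows).
#' @param algorithm algorithm name for the null fits; default "GLM".
#' @param n_null number of null models (>= 1).
#' @param train_fraction fraction used for training; default 0.7.
#' @param seed integer RNG seed.
#' @return list with `p`, `null_auc` vector and `real_auc`.
#' @export
null_model_test <- function(real_auc, presence_env, absence_env,
                            domain_env, algorithm = "GLM", n_null = 19,
                            train_fraction = 0.7, seed = 1L) {
  if (n_null < 1) stop("n_null must be >= 1", call. = FALSE)
  n_pres <- nrow(presence_env)
  n_train_pres <- round(train_fraction * n_pres)
  set.seed(seed)
  test_pres_idx <- setdiff(seq_len(n_pres),
                           sample(n_pres, n_train_pres))
  abs_train_idx <- sample(nrow(absence_env),
                          round(train_fraction * nrow(absence_env)))
  abs_train <- absence_env[abs_train_idx, , drop = FALSE]
  abs_test <- absence_env[-abs_train_idx, , drop = FALSE]
  test <- rbind(cbind(presence_env[test_pres_idx, , drop = FALSE],
                      label = 1),
                cbind(abs_test, label = 0))
  null_auc <- numeric(n_null)
  for (k in seq_len(n_null)) {
    fake <- domain_env[sample(nrow(domain_env), n_train_pres,
                              replace = TRUE), , drop = FALSE]
    train <- rbind(cbind(fake, label = 1), cbind(abs_train, label = 0))
    m <- fit_algorithm(algorithm, train, seed = seed + k)
    null_auc[k] <- auc_mw(predict_suitability(m, test), test$label)
  }
  list(p = (1 + sum(null_auc >= real_auc)) / (n_null + 1),
       null_auc = null_auc, real_auc = real_auc)
}
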