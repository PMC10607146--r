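# stub members with fixed predictions, for ensemble arithmetic
local({
  registerS3method("predict_suitability", "stub_fixed",
                   function(model, data) rep(model$value, nrow(data)),
                   envir = asNamespace("vectorshift"))
})

test_that("pseudo-absence counts follow the over-1000 rule", {
  stk <- toy_landscape(n = 120, noise_sd = 0)
  g <- stk$grid
  rand_occ <- function(n, seed) {
    set.seed(seed)
    occ_df(g$origin_lon + runif(n, 0, g$n_cols * g$cell_size_deg),
           g$origin_lat + runif(n, 0, g$n_rows * g$cell_size_deg))
  }
  # 7239 presences (introduced Ae. aegypti count): equal pseudo-absences
  t1 <- sample_pseudo_absences(rand_occ(7239, 1), stk, replicates = 1,
                               seed = 2)[[1]]
  expect_equal(sum(t1$label == 0), 7239)
  # 367 presences (native count): 1000 pseudo-absences
  t2 <- sample_pseudo_absences(rand_occ(367, 3), stk, replicates = 1,
                               seed = 2)[[1]]
  expect_equal(sum(t2$label == 0), 1000)
  # exactly 1000 presences: still 1000 ("over 1000" is strict)
  t3 <- sample_pseudo_absences(rand_occ(1000, 4), stk, replicates = 1,
                               seed = 2)[[1]]
  expect_equal(sum(t3$label == 0), 1000)
  # replicates differ; insufficient domain errors
  reps <- sample_pseudo_absences(rand_occ(50, 5), stk, replicates = 3,
                                 seed = 7)
  expect_length(reps, 3)
  expect_false(identical(reps[[1]], reps[[2]]))
  tiny <- toy_landscape(n = 10)
  expect_error(sample_pseudo_absences(rand_occ(50, 6), tiny,
                                      domain = matrix(FALSE, 10, 10)),
               "free cells")
})

test_that("SRE is the presence quantile envelope", {
  set.seed(8)
  train <- data.frame(x = c(runif(100, 2, 4), runif(100, 0, 10)),
                      label = rep(c(1, 0), each = 100))
  m0 <- fit_algorithm("SRE", train, hyperparams = list(sre_quantile = 0))
  sc <- predict_suitability(m0, data.frame(x = c(2.5, 1.9, 4.1)))
  expect_equal(sc, c(1, 0, 0))
  # q = 0.025 on 1000 presences covers ~95% of them
  tr2 <- data.frame(x = c(rnorm(1000), runif(1000, -5, 5)),
                    label = rep(c(1, 0), each = 1000))
  m <- fit_algorithm("SRE", tr2, hyperparams = list(sre_quantile = 0.025))
  cover <- mean(predict_suitability(m, tr2[tr2$label == 1, "x", drop = FALSE]))
  expect_gt(cover, 0.92)
  expect_lt(cover, 0.98)
})

test_that("every registry algorithm fits and predicts in [0, 1]", {
  set.seed(12)
  n <- 150
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- as.numeric(runif(n) < stats::plogis(2 * x$a - x$b))
  train <- cbind(x, label = y)
  for (alg in sdm_algorithms()) {
    m <- fit_algorithm(alg, train, seed = 3)
    sc <- predict_suitability(m, x)
    expect_length(sc, n)
    expect_true(all(sc >= 0 & sc <= 1), label = alg)
  }
  expect_error(fit_algorithm("NOPE", train), "unknown")
  expect_error(fit_algorithm("GLM", transform(train, label = 1)),
               "single class")
})

test_that("GLM separates linearly separable toy data perfectly", {
  train <- data.frame(x = c(1:10, 21:30),
                      label = rep(c(0, 1), each = 10))
  m <- suppressWarnings(fit_algorithm("GLM", train))
  expect_equal(evaluate(m, train)$AUC, 1)
})

test_that("AUC and TSS match brute-force oracles", {
  sc <- c(0.9, 0.3, 0.5, 0.2)
  lb <- c(1, 1, 0, 0)
  expect_equal(auc_mw(sc, lb), 0.75)
  expect_equal(auc_pairs_oracle(sc, lb), 0.75)
  expect_equal(tss_stat(sc, lb)$tss, 0.5)
  expect_equal(tss_oracle(sc, lb), 0.5)
  # perfectly separated scores
  expect_equal(auc_mw(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(tss_stat(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$tss, 1)
  # property: rank formula equals pair counting on random <= 50-point sets
  set.seed(21)
  for (trial in 1:25) {
    n <- sample(6:50, 1)
    lbl <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_mw(s, lbl), auc_pairs_oracle(s, lbl))
    expect_equal(tss_stat(s, lbl)$tss, tss_oracle(s, lbl))
  }
  expect_error(auc_mw(1:3, c(1, 1, 1)), "both classes")
})

test_that("cross-validation produces the expected grid of evaluations", {
  set.seed(30)
  n <- 120
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- as.numeric(runif(n) < stats::plogis(2.5 * x$a))
  tabs <- list(cbind(x, label = y, replicate = 1),
               cbind(x, label = y, replicate = 2))
  ev <- cross_validate(tabs, c("GLM", "CTA"), repeats = 3, seed = 5)
  # repeats x replicates x algorithms
  expect_equal(nrow(ev), 3 * 2 * 2)
  expect_setequal(unique(ev$algorithm), c("GLM", "CTA"))
  # determinism: identical seeds give identical splits and scores
  ev2 <- cross_validate(tabs, c("GLM", "CTA"), repeats = 3, seed = 5)
  expect_equal(ev, ev2)
})

test_that("flexible learners beat the envelope on a strong-signal fixture", {
  stk <- toy_landscape(n = 40, noise_sd = 0.3, seed = 14)
  niche <- virtual_niche(c(7, 7, 7), c(1.2, 1.2, 1.2))
  s <- suitability_surface(stk, niche)
  occ <- sample_occurrences(s, stk$grid, 300, seed = 15)
  tab <- sample_pseudo_absences(occ, stk, replicates = 1, seed = 16)[[1]]
  ev <- cross_validate(list(tab), c("RF", "SRE"), repeats = 2, seed = 17)
  expect_gt(mean(ev$AUC[ev$algorithm == "RF"]),
            mean(ev$AUC[ev$algorithm == "SRE"]))
})

test_that("ensemble weighting follows the TSS-proportional rule", {
  mk <- function(v) structure(list(value = v), class = "stub_fixed")
  models <- list(A = mk(0.9), B = mk(0.3))
  evals <- data.frame(algorithm = c("A", "B"),
                      AUC = c(0.9, 0.85), TSS = c(0.8, 0.4))
  ens <- build_ensemble(models, evals)
  expect_equal(ens$weights, c(2 / 3, 1 / 3))
  expect_equal(predict_suitability(ens, data.frame(x = 1)),
               (2 / 3) * 0.9 + (1 / 3) * 0.3)
  # one qualifying member: ensemble is that member
  evals2 <- data.frame(algorithm = c("A", "B"),
                       AUC = c(0.9, 0.79), TSS = c(0.8, 0.59))
  ens2 <- build_ensemble(models, evals2)
  expect_equal(ens2$weights, c(1, 0))
  expect_equal(predict_suitability(ens2, data.frame(x = 1)), 0.9)
  # an excluded member contributes nothing: dropping it changes nothing
  ens3 <- build_ensemble(models["A"], evals2[1, ])
  expect_equal(predict_suitability(ens3, data.frame(x = 1)),
               predict_suitability(ens2, data.frame(x = 1)))
  # no member qualifying is an explicit error
  evals3 <- data.frame(algorithm = c("A", "B"),
                       AUC = c(0.7, 0.6), TSS = c(0.5, 0.4))
  expect_error(build_ensemble(models, evals3), "no qualifying")
})

test_that("max sens+spec threshold picks the smallest maximizing score", {
  expect_equal(max_sens_spec_threshold(c(0.9, 0.8, 0.3, 0.4),
                                       c(1, 1, 0, 0)), 0.8)
  expect_warning(th <- max_sens_spec_threshold(rep(0.5, 4), c(1, 1, 0, 0)),
                 "degenerate")
  expect_equal(th, 0.5)
  # adding an absence scored below all presences changes nothing
  expect_equal(max_sens_spec_threshold(c(0.9, 0.8, 0.3, 0.4, 0.05),
                                       c(1, 1, 0, 0, 0)), 0.8)
  expect_error(max_sens_spec_threshold(1:3, c(1, 1, 1)), "both classes")
})

test_that("null-model p-values follow the rank convention", {
  set.seed(40)
  n <- 200
  stk <- toy_landscape(n = 30, noise_sd = 0.3, seed = 41)
  niche <- virtual_niche(c(7, 7, 7), c(1, 1, 1))
  s <- suitability_surface(stk, niche)
  occ <- sample_occurrences(s, stk$grid, n, seed = 42)
  pres_env <- extract_values(stk, occ$lon, occ$lat)
  set.seed(43)
  free <- expand.grid(r = 1:30, c = 1:30)
  ctr <- grid_centers(stk$grid)
  dom_env <- extract_values(stk, ctr$lon[free$c], ctr$lat[free$r])
  abs_env <- dom_env[sample(nrow(dom_env), n), ]
  # real model AUC on the same 70/30 construction used by the null test
  nt <- null_model_test(real_auc = 0.99, pres_env, abs_env, dom_env,
                        n_null = 9, seed = 44)
  expect_equal(nt$p, (1 + sum(nt$null_auc >= 0.99)) / 10)
  expect_gte(nt$p, 1 / 10)
  expect_lte(nt$p, 1)
  # a real AUC below every null is maximally non-significant
  nt2 <- null_model_test(real_auc = 0, pres_env, abs_env, dom_env,
                         n_null = 9, seed = 44)
  expect_equal(nt2$p, 1)
  expect_error(null_model_test(0.9, pres_env, abs_env, dom_env, n_null = 0),
               "n_null")
})
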