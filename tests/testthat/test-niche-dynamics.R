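test_that("PCA of the background behaves like correlation-matrix PCA", {
  # two perfectly correlated predictors: axis 1 carries all variance
  x <- rnorm(50)
  bg <- data.frame(a = x, b = 2 * x + 3)
  p <- pca_env(bg)
  expect_equal(p$explained[1], 1)
  # projection of the background mean is the origin
  ctr <- data.frame(a = mean(bg$a), b = mean(bg$b))
  expect_equal(unname(project_env(p, ctr)[1, ]), c(0, 0), tolerance = 1e-10)
  # isotropic cloud: the two axes explain roughly equal variance
  set.seed(2)
  iso <- data.frame(a = rnorm(4000), b = rnorm(4000))
  expect_equal(pca_env(iso)$explained[1], 0.5, tolerance = 0.05)
  # constant predictors are dropped with a warning
  expect_warning(p3 <- pca_env(data.frame(a = x, b = -x, c = 1)), "constant")
  expect_equal(p3$predictors, c("a", "b"))
})

test_that("density grids are normalized, deterministic and concentrated", {
  set.seed(3)
  occ <- cbind(rnorm(200), rnorm(200))
  bg <- cbind(runif(2000, -4, 4), runif(2000, -4, 4))
  g <- density_grid(occ, bg, R = 50)
  expect_equal(sum(g$z_occ), 1, tolerance = 1e-9)
  expect_equal(sum(g$z_env), 1, tolerance = 1e-9)
  expect_identical(density_grid(occ, bg, R = 50),
                   density_grid(occ, bg, R = 50))
  # all occurrences at one point: the argmax cell contains the point
  pt <- cbind(rep(1.3, 6), rep(-0.7, 6))
  gp <- density_grid(pt, bg, R = 50)
  am <- which(gp$z_occ == max(gp$z_occ), arr.ind = TRUE)[1, ]
  expect_lt(abs(gp$x[am[1]] - 1.3), diff(gp$x[1:2]))
  expect_lt(abs(gp$y[am[2]] + 0.7), diff(gp$y[1:2]))
  expect_error(density_grid(occ[1:3, ], bg), "at least 5")
})

test_that("Schoener's D obeys its closed form and symmetry", {
  z <- matrix(runif(25), 5, 5)
  expect_equal(schoener_D(z, z), 1)
  a <- matrix(c(1, 0, 0, 0), 2, 2)
  b <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_equal(schoener_D(a, b), 0)
  # hand arithmetic: (0.7, 0.3) vs (0.3, 0.7) -> 1 - 0.5 * 0.8 = 0.6
  expect_equal(schoener_D(matrix(c(0.7, 0.3)), matrix(c(0.3, 0.7))), 0.6)
  z2 <- matrix(runif(25), 5, 5)
  expect_equal(schoener_D(z, z2), schoener_D(z2, z))
  expect_error(schoener_D(z, matrix(1, 2, 2)), "shapes")
})

test_that("COUE indices agree with exhaustive cell counting on toy grids", {
  # identical occupancy: no expansion, no unfilling
  z <- matrix(c(0, 2, 1, 0, 3, 0, 1, 0, 0), 3, 3)
  same <- coue_indices(fake_grid(z), fake_grid(z), analog_only = FALSE)
  expect_equal(same$E, 0); expect_equal(same$S, 1); expect_equal(same$U, 0)
  # fully disjoint occupancies
  zn <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  zi <- matrix(c(0, 0, 0, 0, 0, 1, 1, 0, 0), 3, 3)
  disj <- coue_indices(fake_grid(zn), fake_grid(zi), analog_only = FALSE)
  expect_equal(disj$E, 1); expect_equal(disj$S, 0); expect_equal(disj$U, 1)
  # partial overlap with hand-assigned masses vs an independent counting loop
  zn2 <- matrix(c(4, 2, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  zi2 <- matrix(c(0, 1, 0, 2, 0, 0, 0, 3, 0), 3, 3)
  got <- coue_indices(fake_grid(zn2), fake_grid(zi2), analog_only = FALSE)
  e_mass <- s_mass <- u_mass <- 0
  for (i in 1:3) for (j in 1:3) {
    if (zi2[i, j] > 0 && zn2[i, j] == 0) e_mass <- e_mass + zi2[i, j]
    if (zi2[i, j] > 0 && zn2[i, j] > 0) s_mass <- s_mass + zi2[i, j]
    if (zn2[i, j] > 0 && zi2[i, j] == 0) u_mass <- u_mass + zn2[i, j]
  }
  expect_equal(got$E, e_mass / sum(zi2))
  expect_equal(got$U, u_mass / sum(zn2))
  expect_equal(got$E + got$S, 1)
  expect_error(coue_indices(fake_grid(zn2), fake_grid(matrix(0, 3, 3) + 1e-30),
                            analog_only = FALSE), NA)
})

test_that("analog restriction masks non-shared environments", {
  zocc <- matrix(c(2, 2, 0, 0), 2, 2)
  env_n <- matrix(c(1, 1, 0, 0), 2, 2)  # native background misses col 2
  env_i <- matrix(1, 2, 2)
  zi <- matrix(c(2, 0, 0, 2), 2, 2)
  d_all <- coue_indices(fake_grid(zocc, env_n), fake_grid(zi, env_i),
                        analog_only = FALSE)
  d_analog <- coue_indices(fake_grid(zocc, env_n), fake_grid(zi, env_i),
                           analog_only = TRUE)
  # the introduced-only cell sits outside the native background: expansion
  # counts it under no restriction but not under the analog mask
  expect_gt(d_all$E, d_analog$E)
})

test_that("breadth ratio and similarity index reproduce printed examples", {
  # global Ae. aegypti row: E=0.045, S=0.955, U=0.027
  d1 <- coue_decomposition(E = 0.045, S = 0.955, U = 0.027)
  expect_equal(round(breadth_ratio(d1), 3), 1.018)
  expect_equal(round(niche_similarity_index(d1), 3), 0.964)
  # global Ae. albopictus row: E=0.382, S=0.618, U=0.101
  d2 <- coue_decomposition(E = 0.382, S = 0.618, U = 0.101)
  expect_equal(round(breadth_ratio(d2), 3), 1.391)
  # Europe-introduced Ae. albopictus row: E=0.499, S=0.501, U=0.806
  d3 <- coue_decomposition(E = 0.499, S = 0.501, U = 0.806)
  expect_equal(round(niche_similarity_index(d3), 3), 0.434)
  # identical niches
  d4 <- coue_decomposition(E = 0, S = 1, U = 0)
  expect_equal(breadth_ratio(d4), 1)
  expect_equal(niche_similarity_index(d4), 1)
  expect_error(coue_decomposition(E = 0.5, S = 0.4, U = 0), "E \\+ S")
})

test_that("conservatism verdict requires both conditions", {
  expect_equal(conservatism_verdict(BR = 1.018, SI = 0.964), "conserved")
  expect_equal(conservatism_verdict(BR = 1.5, SI = 0.4), "not_conserved")
  expect_equal(conservatism_verdict(BR = 0.9, SI = 0.4), "conserved")
  expect_equal(conservatism_verdict(BR = 1.5, SI = 0.6), "conserved")
  expect_error(conservatism_verdict(NaN, 0.5), "finite")
})

test_that("equivalency test separates identical from disjoint niches", {
  set.seed(6)
  bg <- cbind(runif(1500, -6, 6), runif(1500, -6, 6))
  # identical sets: D_obs is maximal among resamples; non-significant
  occ <- cbind(rnorm(60), rnorm(60))
  eq_same <- equivalency_test(occ, occ, bg, R = 40, n_perm = 49, seed = 7)
  expect_gt(eq_same$p, 0.5)
  expect_true(all(eq_same$D_null <= eq_same$D_obs + 1e-12))
  # well-separated clusters: lower equivalency than random
  occ1 <- cbind(rnorm(60, -3, 0.4), rnorm(60, -3, 0.4))
  occ2 <- cbind(rnorm(60, 3, 0.4), rnorm(60, 3, 0.4))
  eq_diff <- equivalency_test(occ1, occ2, bg, R = 40, n_perm = 99, seed = 8)
  expect_lte(eq_diff$p, 0.05)
  # p respects the rank bounds
  expect_gte(eq_diff$p, 1 / 100)
  expect_error(equivalency_test(occ1, occ2, bg, n_perm = 0), "n_perm")
})

test_that("similarity test flags centred niches and is seed-stable", {
  set.seed(9)
  bg2 <- cbind(runif(1500, -6, 6), runif(1500, -6, 6))
  occ1 <- cbind(rnorm(80, 0, 0.5), rnorm(80, 0, 0.5))
  occ2 <- cbind(rnorm(80, 0, 0.5), rnorm(80, 0, 0.5))
  st <- similarity_test(occ1, occ2, bg2, R = 40, n_perm = 99, seed = 10)
  expect_lte(st$p, 0.05)
  st2 <- similarity_test(occ1, occ2, bg2, R = 40, n_perm = 99, seed = 10)
  expect_identical(st$p, st2$p)
  # distant niches are not more similar than random
  far <- cbind(rnorm(80, 5, 0.3), rnorm(80, 5, 0.3))
  st3 <- similarity_test(occ1, far, bg2, R = 40, n_perm = 49, seed = 11)
  expect_gt(st3$p, 0.05)
  degenerate <- cbind(rep(1, 10), rep(1, 10))
  expect_error(similarity_test(occ1, occ2, degenerate), "too small")
})

test_that("estimated expansion grows with the true niche separation", {
  stk <- toy_landscape(n = 40, noise_sd = 0.3, seed = 20)
  ctr <- grid_centers(stk$grid)
  cells <- expand.grid(r = seq_len(stk$grid$n_rows),
                       c = seq_len(stk$grid$n_cols))
  bg_env <- extract_values(stk, ctr$lon[cells$c], ctr$lat[cells$r])
  native <- virtual_niche(c(4, 5, 5), c(1.5, 1.5, 1.5))
  e_vals <- sapply(c(0, 2, 4), function(shift) {
    intro <- virtual_niche(c(4 + shift, 5, 5), c(1.5, 1.5, 1.5))
    sim <- simulate_virtual_species(
      stk, virtual_species_config(native, intro, 800, 800, seed = 21))
    occ_n <- extract_values(stk, sim$native$lon, sim$native$lat)
    occ_i <- extract_values(stk, sim$introduced$lon, sim$introduced$lat)
    niche_dynamics(occ_n, occ_i, bg_env, bg_env, R = 100)$coue$E
  })
  expect_true(all(diff(e_vals) >= 0))
  expect_gt(e_vals[3], e_vals[1])
})

test_that("moderate-shift species recover E and U within 0.1 of truth", {
  stk <- generate_landscape(landscape_config(
    n_rows = 60, n_cols = 60, n_gradient_layers = 3,
    noise_sd = 0.5, autocorrelation_range = 3, seed = 101))
  ctr <- grid_centers(stk$grid)
  cells <- expand.grid(r = 1:60, c = 1:60)
  bg_env <- extract_values(stk, ctr$lon[cells$c], ctr$lat[cells$r])
  native <- virtual_niche(c(5, 5, 5), c(1.5, 1.5, 1.5))
  intro <- virtual_niche(c(6, 5, 5), c(1.5, 1.5, 1.5))
  for (seed in 1:3) {
    sim <- simulate_virtual_species(
      stk, virtual_species_config(native, intro, 2000, 2000, seed = seed))
    nd <- niche_dynamics(
      extract_values(stk, sim$native$lon, sim$native$lat),
      extract_values(stk, sim$introduced$lon, sim$introduced$lat),
      bg_env, bg_env, R = 100)
    expect_lt(abs(nd$coue$E - sim$truth$E), 0.1)
    expect_lt(abs(nd$coue$U - sim$truth$U), 0.1)
  }
})

test_that("full niche dynamics run reports coherent indices", {
  stk <- toy_landscape(n = 30, noise_sd = 0.3, seed = 22)
  ctr <- grid_centers(stk$grid)
  cells <- expand.grid(r = 1:30, c = 1:30)
  bg_env <- extract_values(stk, ctr$lon[cells$c], ctr$lat[cells$r])
  niche <- virtual_niche(c(5, 5, 5), c(1.5, 1.5, 1.5))
  sim <- simulate_virtual_species(
    stk, virtual_species_config(niche, niche, 400, 400, seed = 23))
  occ_n <- extract_values(stk, sim$native$lon, sim$native$lat)
  occ_i <- extract_values(stk, sim$introduced$lon, sim$introduced$lat)
  nd <- niche_dynamics(occ_n, occ_i, bg_env, bg_env, R = 60,
                       n_perm = 9, seed = 24)
  expect_equal(nd$coue$E + nd$coue$S, 1)
  expect_true(nd$D >= 0 && nd$D <= 1)
  expect_equal(nd$verdict,
               conservatism_verdict(nd$BR, nd$SI))
  expect_true(nd$equivalency$p >= 0.1 && nd$equivalency$p <= 1)
  expect_lte(nd$similarity$p, 1)
})
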