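# The synthetic landscape generator: surfaces, plot networks, tallies and
# whole datasets with known ground truth.

test_that("covariate surfaces are standardized, smooth and reproducible", {
  cfg <- landscape_config(width_km = 200, height_km = 200, n_covariates = 4,
                          corr_length_km = 10, seed = 8)
  env1 <- generate_environment(cfg)
  env2 <- generate_environment(cfg)
  set.seed(1)
  xy <- cbind(runif(10000, 0, cfg$width_m), runif(10000, 0, cfg$height_m))
  z1 <- predict(env1, xy)
  expect_identical(z1, predict(env2, xy))
  expect_equal(dim(z1), c(10000, 4))
  expect_true(all(abs(colMeans(z1)) < 0.05))
  expect_true(all(abs(apply(z1, 2, sd) - 1) < 0.1))
  # correlation decays: shifting by 5 correlation lengths decorrelates.
  # A single realization on a finite window retains sampling noise in the
  # empirical correlation, so the check averages across surfaces.
  shift <- 5 * cfg$corr_length_m
  xs <- cbind(runif(4000, 0, cfg$width_m - shift), runif(4000, 0, cfg$height_m))
  za <- predict(env1, xs)
  zb <- predict(env1, cbind(xs[, 1] + shift, xs[, 2]))
  shifted_cor <- vapply(1:4, function(j) abs(cor(za[, j], zb[, j])),
                        numeric(1))
  expect_lt(mean(shifted_cor), 0.2)
})

test_that("plot networks follow the regional Poisson intensities", {
  regions <- data.frame(xmin = c(0, 100000), xmax = c(100000, 200000),
                        ymin = 0, ymax = 100000, intensity = c(4, 0))
  plots <- generate_plots(regions, seed = 3)
  expect_true(all(plots$x < 100000))        # intensity-0 region stays empty
  # expected count = intensity x (region area / fine-cell area) = 4 * 100
  expect_lt(abs(nrow(plots) - 400), 4 * sqrt(400))
  expect_false(anyDuplicated(plots$plot_id) > 0)
})

test_that("contrasting plot densities produce a mixed hybrid lattice", {
  ds <- generate_dataset(landscape_config(width_km = 160, height_km = 160,
                                          seed = 5), n_species = 1)
  expect_true(all(c("fine", "coarse") %in% ds$lattice$cells$level))
  # the dense western half is mostly refined, the sparse east mostly not
  west <- ds$lattice$cells$xmax <= 80000
  expect_gt(mean(ds$lattice$cells$level[west] == "fine"), 0.8)
  expect_lt(mean(ds$lattice$cells$level[!west] == "fine"), 0.3)
})

test_that("tallies reproduce the intended importance values", {
  cfg <- landscape_config(width_km = 150, height_km = 150, n_covariates = 3,
                          seed = 12)
  env <- generate_environment(cfg)
  set.seed(2)
  plots <- data.frame(plot_id = sprintf("p%04d", 1:1000),
                      x = runif(1000, 0, cfg$width_m),
                      y = runif(1000, 0, cfg$height_m))
  sp <- synthetic_species("sp", optima = c(cov01 = 0.2, cov02 = -0.4),
                          breadths = c(1, 1.4), max_iv = 55, noise_sd = 4)
  st <- generate_species_tallies(env, sp, plots, seed = 6)
  got <- compute_plot_ivs(st$tallies)
  got_sp <- got[got$species == "sp", ]
  intended <- st$intended_iv
  merged <- merge(intended, got_sp, by = "plot_id", all.x = TRUE)
  merged$iv.y[is.na(merged$iv.y)] <- 0
  expect_lt(max(abs(merged$iv.x - merged$iv.y)), 0.5)
  # per-plot closure holds with the background pool
  sums <- tapply(got$iv, got$plot_id, sum)
  expect_equal(unname(range(sums)), c(100, 100))
})

test_that("the niche response peaks at the optimum and vanishes far away", {
  cfg <- landscape_config(n_covariates = 2, seed = 3)
  sp <- synthetic_species("sp", optima = c(cov01 = 0.5), breadths = 0.8,
                          max_iv = 60, noise_sd = 0)
  z_opt <- matrix(c(0.5, 0), 1, dimnames = list(NULL, c("cov01", "cov02")))
  expect_equal(expected_iv(sp, z_opt), 60)
  z_far <- matrix(c(0.5 + 6 * 0.8, 0), 1,
                  dimnames = list(NULL, c("cov01", "cov02")))
  expect_equal(expected_iv(sp, z_far), 0)
})

test_that("datasets regenerate identically from the same seed", {
  cfg <- landscape_config(width_km = 120, height_km = 120, n_covariates = 4,
                          seed = 21)
  d1 <- generate_dataset(cfg, n_species = 2)
  d2 <- generate_dataset(cfg, n_species = 2)
  expect_identical(d1$plots, d2$plots)
  expect_identical(d1$tallies, d2$tallies)
  expect_identical(d1$cell_covariates, d2$cell_covariates)
  expect_identical(d1$forest_fraction, d2$forest_fraction)
  # and IVs derived from the tallies match the recorded intention
  pv <- compute_plot_ivs(d1$tallies)
  sp1 <- d1$species[[1]]$name
  got <- pv[pv$species == sp1, ]
  want <- d1$intended_iv[[sp1]]
  m <- match(d1$intended_iv$plot_id, got$plot_id)
  got_iv <- ifelse(is.na(m), 0, got$iv[m])
  expect_lt(max(abs(got_iv - want)), 0.5)
})

test_that("cells near the niche optimum receive higher combined predictions", {
  sp <- synthetic_species("SP01", optima = c(cov03 = 0.8, cov07 = -0.8),
                          breadths = 0.8, max_iv = 60, noise_sd = 3)
  ds <- generate_dataset(landscape_config(width_km = 250, height_km = 250,
                                          seed = 31), species = list(sp))
  pv <- compute_plot_ivs(ds$tallies)
  samples <- aggregate_cell_iv(pv, ds$assignment$assignment, sp$name,
                               cells = ds$lattice$cells$cell_id,
                               forest_fraction = ds$forest_fraction)
  tr <- suppressWarnings(filter_training_cells(samples,
                                               predictors = ds$cell_covariates))
  m <- fit_rf(tr, rf_config(n_trees = 301, seed = 31))
  pred <- predict_combined(m, ds$cell_covariates)
  z <- as.matrix(ds$cell_covariates[names(sp$optima)])
  # distance from the optimum in breadth units
  u <- sqrt(rowSums(sweep(sweep(z, 2, sp$optima), 2, sp$breadths, "/")^2))
  near <- u < 1
  far <- u >= 3
  expect_gt(sum(near), 5)
  expect_gt(sum(far), 5)
  expect_gt(mean(pred$iv[near]), mean(pred$iv[far]))
})
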