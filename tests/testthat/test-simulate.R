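test_that("ground truth is reproducible, dimensioned, and respects zero scales", {
  cfg <- simulation_config(n_plots = 50, n_species = 20, n_env = 3,
                           n_latent = 2, seed = 7)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  expect_equal(dim(t1$lambda), c(20, 2))
  expect_equal(dim(t1$lambda_cwd), c(20, 2))
  expect_equal(dim(t1$beta), c(20, 4))  # intercept + 3 covariates
  expect_equal(dim(t1$eta), c(50, 2))
  # total loading contract over the standardized gradient
  tot <- pmax(abs(t1$lambda - sqrt(3) * t1$lambda_cwd),
              abs(t1$lambda + sqrt(3) * t1$lambda_cwd))
  expect_lte(max(tot), 10)

  cfg0 <- simulation_config(n_plots = 10, n_species = 5, seed = 1,
                            effect_scales = list(beta = 0, lambda = 0,
                                                 lambda_cwd = 0))
  t0 <- generate_truth(cfg0)
  expect_true(all(t0$beta == 0))
  expect_true(all(t0$lambda == 0))
  expect_true(all(t0$lambda_cwd == 0))
})

test_that("config validation rejects bad inputs", {
  expect_error(simulation_config(n_plots = 0), "n_plots")
  expect_error(simulation_config(cwd_range = c(500, 100)), "cwd_range")
  expect_error(simulation_config(
    tolerance_mix = c(drought_tolerant = 0.5, intermediate = 0.2,
                      drought_sensitive = 0.2)), "sum to 1")
})

test_that("tolerance mix produces non-empty groups spanning the E_m scale", {
  cfg <- simulation_config(n_plots = 10, n_species = 30, seed = 3)
  tr <- generate_truth(cfg)
  g <- classify_tolerance(tr$em_values)
  expect_true(all(c("drought_tolerant", "intermediate",
                    "drought_sensitive") %in% g))
  expect_true(all(tr$em_values >= 1 & tr$em_values <= 9))
})

test_that("community generation reproduces bit-for-bit under a fixed seed", {
  cfg <- simulation_config(n_plots = 200, n_species = 10, seed = 5)
  tr <- generate_truth(cfg)
  d1 <- generate_community(tr, cfg)
  d2 <- generate_community(tr, cfg)
  expect_identical(d1$Y, d2$Y)
  expect_identical(d1$cwd, d2$cwd)
  expect_true(all(d1$Y %in% c(0, 1)))
  expect_true(all(d1$cwd >= 0 & d1$cwd <= 1100))
})

test_that("a saturated intercept makes every species ubiquitous", {
  cfg <- simulation_config(n_plots = 300, n_species = 4, n_env = 1,
                           n_latent = 0, seed = 9,
                           effect_scales = list(beta = 0, lambda = 0,
                                                lambda_cwd = 0))
  tr <- generate_truth(cfg)
  tr$beta[, 1] <- 8  # probit intercept of 8: Phi(8) ~ 1
  ds <- generate_community(tr, cfg)
  expect_true(all(ds$Y == 1))
})

test_that("without latent structure, occupancy matches Phi(x beta) and pairs are independent", {
  cfg <- simulation_config(n_plots = 5000, n_species = 6, n_env = 2,
                           n_latent = 0, seed = 13)
  tr <- generate_truth(cfg)
  ds <- generate_community(tr, cfg)
  # reconstruct the standardized design the generator used
  Xs <- ds$X
  Xs[, "CWD_GS"] <- (ds$cwd - tr$cwd_scaling$center) / tr$cwd_scaling$scale
  expected_occ <- colMeans(pnorm(Xs %*% t(tr$beta)))
  expect_lt(max(abs(colMeans(ds$Y) - expected_occ)), 0.02)

  # with beta = 0 too: occupancy 1/2 and vanishing pairwise correlation
  tr$beta[] <- 0
  ds0 <- generate_community(tr, cfg)
  expect_lt(max(abs(colMeans(ds0$Y) - 0.5)), 0.03)
  C <- cor(ds0$Y)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})

test_that("a shared latent factor induces excess co-occurrence", {
  cfg <- simulation_config(n_plots = 5000, n_species = 2, n_env = 1,
                           n_latent = 1, seed = 17,
                           effect_scales = list(beta = 0, lambda = 0,
                                                lambda_cwd = 0))
  tr <- generate_truth(cfg)
  tr$lambda[] <- 3  # both species load +3 on the shared factor
  ds <- generate_community(tr, cfg)
  co <- mean(ds$Y[, 1] * ds$Y[, 2])
  indep <- mean(ds$Y[, 1]) * mean(ds$Y[, 2])
  expect_gt(co, indep + 0.05)
})

test_that("with static loadings, associations match between wet and dry halves", {
  cfg <- simulation_config(n_plots = 5000, n_species = 2, n_env = 1,
                           n_latent = 1, seed = 19,
                           effect_scales = list(beta = 0, lambda = 0,
                                                lambda_cwd = 0))
  tr <- generate_truth(cfg)
  tr$lambda[] <- 2
  ds <- generate_community(tr, cfg)
  dry <- ds$cwd > median(ds$cwd)
  co_rate <- function(idx) mean(ds$Y[idx, 1] == ds$Y[idx, 2])
  pt <- prop.test(c(sum(ds$Y[dry, 1] == ds$Y[dry, 2]),
                    sum(ds$Y[!dry, 1] == ds$Y[!dry, 2])),
                  c(sum(dry), sum(!dry)))
  expect_gt(pt$p.value, 0.01)
})

test_that("the SGH scenario plants the advertised loading structure", {
  cfg <- simulation_config(n_plots = 50, n_species = 12, n_latent = 2,
                           tolerance_mix = c(drought_tolerant = 1/3,
                                             intermediate = 1/3,
                                             drought_sensitive = 1/3),
                           seed = 23)
  tr <- sgh_truth(cfg)
  g <- classify_tolerance(tr$em_values)
  ds <- g == "drought_sensitive"; dt <- g == "drought_tolerant"
  expect_true(all(tr$lambda_cwd[ds, 1] > 0))   # DS factor-1 loading rises
  expect_true(all(tr$lambda_cwd[dt, 2] < 0))   # DT factor-2 loading falls
  # balanced cross-loading signs: both planted shift classes non-empty
  expect_true(any(tr$lambda[ds, 2] > 0) && any(tr$lambda[ds, 2] < 0))
  expect_true(any(tr$lambda[dt, 1] > 0) && any(tr$lambda[dt, 1] < 0))
  expect_error(sgh_truth(simulation_config(n_latent = 3)), "2 latent")
})

test_that("climate series presets honour their contracts", {
  c1 <- generate_climate_series(3, "constant", seed = 1)
  expect_equal(unname(as.numeric(c1[1, paste0("tmean_", 1:12)])), rep(10, 12))
  expect_equal(unname(as.numeric(c1[1, paste0("prec_", 1:12)])), rep(50, 12))
  c2a <- generate_climate_series(5, "arid", seed = 2)
  c2b <- generate_climate_series(5, "arid", seed = 2)
  expect_identical(c2a, c2b)
  expect_true(all(c2a[, paste0("prec_", 5:8)] == 0))
  expect_true(all(c2a[, paste0("tmin_", 1:12)] <=
                    c2a[, paste0("tmean_", 1:12)]))
})

test_that("community CSV round-trip preserves the data", {
  cfg <- simulation_config(n_plots = 40, n_species = 6, n_env = 2, seed = 31)
  tr <- generate_truth(cfg)
  d <- generate_community(tr, cfg)
  dir <- withr::local_tempdir()
  write_community(d, dir)
  expect_true(file.exists(file.path(dir, "metadata.txt")))
  d2 <- read_dataset(file.path(dir, "occurrence.csv"),
                     file.path(dir, "environment.csv"),
                     file.path(dir, "traits.csv"))
  expect_equal(unname(d2$Y), unname(d$Y))
  expect_equal(d2$cwd, d$cwd, tolerance = 1e-10)
  expect_equal(unname(d2$traits), unname(d$traits))
})
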