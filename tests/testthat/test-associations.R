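test_that("association matrix agrees with the brute-force oracle to 1e-12", {
  set.seed(101)
  worst <- 0
  for (k in c(1, 2, 5, 20)) {
    for (rep in 1:25) {
      S <- sample(3:8, 1)
      lam <- matrix(rnorm(S * k), S, k)
      lamc <- matrix(rnorm(S * k, 0, 0.5), S, k)
      cwd <- runif(1, 0, 1100)
      sc <- list(center = 550, scale = 1100 / sqrt(12))
      R <- association_matrix(lam, lamc, cwd, sc)
      Ro <- oracle_association(lam, lamc, cwd, sc$center, sc$scale)
      worst <- max(worst, max(abs(R - Ro), na.rm = TRUE))
      expect_equal(R, Ro, tolerance = 1e-12)
      expect_equal(R, t(R))
      expect_equal(diag(R)[is.finite(diag(R))],
                   rep(1, sum(is.finite(diag(R)))))
      expect_true(all(abs(R[is.finite(R)]) <= 1 + 1e-12))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("a single factor forces off-diagonal correlations to plus/minus one", {
  set.seed(5)
  for (rep in 1:10) {
    lam <- matrix(rnorm(5), 5, 1)
    lamc <- matrix(rnorm(5, 0, 0.3), 5, 1)
    R <- association_matrix(lam, lamc, runif(1, 0, 1100),
                            list(center = 550, scale = 318))
    off <- R[upper.tri(R)]
    expect_true(all(abs(abs(off[is.finite(off)]) - 1) < 1e-12))
  }
  # the worked single-factor case: loadings (2, -1) anticorrelate exactly
  R2 <- association_matrix(matrix(c(2, -1), 2, 1),
                           matrix(0, 2, 1), cwd = 300,
                           list(center = 0, scale = 1))
  expect_equal(R2[1, 2], -1)
})

test_that("vanishing total loadings are flagged undefined, never zeroed", {
  lam <- matrix(c(1, 0, 1, 0), 2, 2)   # species 2 has no loading at all
  R <- association_matrix(lam, matrix(0, 2, 2), 100,
                          list(center = 0, scale = 1))
  expect_true(all(is.na(R[2, ])))
  expect_true(all(is.na(R[, 2])))
  expect_equal(R[1, 1], 1)
})

test_that("the association posterior has the contracted shape and invariants", {
  res <- cached_sgh()
  assoc <- association_posterior(res$fit, c(300, 800))
  expect_equal(dim(assoc$R), c(2000, 2, 12, 12))
  expect_true(all(abs(assoc$R[is.finite(assoc$R)]) <= 1 + 1e-9))
  r_slice <- assoc$R[17, 2, , ]
  expect_equal(r_slice, t(r_slice))
  expect_equal(diag(r_slice), rep(1, 12))
})

test_that("context-independent draws give identical associations everywhere", {
  res <- cached_sgh()
  fit0 <- res$fit
  fit0$lambda_cwd[] <- 0
  assoc <- association_posterior(fit0, c(100, 600, 1000))
  expect_equal(assoc$R[, 1, , ], assoc$R[, 3, , ], tolerance = 1e-12)
})

test_that("posterior-mean associations recover the generative truth", {
  res <- cached_sgh()
  anchors <- cwd_percentiles(res$data, c(0.25, 0.75))
  sc <- res$truth$cwd_scaling
  assoc <- association_posterior(res$fit, anchors)
  Rbar <- apply(assoc$R, c(2, 3, 4), mean)
  ut <- upper.tri(matrix(0, 12, 12))
  for (a in 1:2) {
    Rt <- association_matrix(res$truth$lambda, res$truth$lambda_cwd,
                             anchors[a], sc)
    expect_gt(cor(Rbar[a, , ][ut], Rt[ut]), 0.7)
  }
})

test_that("shift classification reduces to counting posterior draws", {
  # constructed posterior: controlled number of positive differences
  build <- function(n_pos, n = 1000) {
    R <- array(0, c(n, 2, 2, 2))
    d <- c(rep(0.1, n_pos), rep(-0.1, n - n_pos))
    R[, 1, 1, 2] <- R[, 1, 2, 1] <- 0.2
    R[, 2, 1, 2] <- R[, 2, 2, 1] <- 0.2 + d
    R[, , 1, 1] <- R[, , 2, 2] <- 1
    fake_assoc(R, c(420, 665))
  }
  s960 <- classify_shift(build(960), 420, 665)
  expect_equal(s960$pr_dry_gt_wet, 0.96)
  expect_equal(as.character(s960$shift), "positive")
  s940 <- classify_shift(build(940), 420, 665)
  expect_equal(s940$pr_dry_gt_wet, 0.94)
  expect_equal(as.character(s940$shift), "none")
  s10 <- classify_shift(build(10), 420, 665)
  expect_equal(as.character(s10$shift), "negative")
  # unanimous draws
  s_all <- classify_shift(build(1000), 420, 665)
  expect_equal(s_all$pr_dry_gt_wet, 1)
  # draw-by-draw ties split evenly
  s_tie <- classify_shift(build(0) |> (\(a) {a$R[, 2, , ] <- a$R[, 1, , ]; a})(),
                          420, 665)
  expect_equal(s_tie$pr_dry_gt_wet, 0.5)
  expect_equal(as.character(s_tie$shift), "none")
  expect_error(classify_shift(build(10), 420, 665, upper = 0.1,
                              lower = 0.5), "exceed")
  expect_error(classify_shift(build(10), 300, 665), "not among")
})

test_that("shift classification depends only on the sign of the draw difference", {
  # strictly monotone relabelling of draws leaves the classification fixed
  set.seed(33)
  n <- 500
  R <- array(0, c(n, 2, 2, 2))
  R[, 1, 1, 2] <- R[, 1, 2, 1] <- runif(n, -0.5, 0.5)
  R[, 2, 1, 2] <- R[, 2, 2, 1] <- R[, 1, 1, 2] + rnorm(n, 0.05, 0.1)
  R[, , 1, 1] <- R[, , 2, 2] <- 1
  a1 <- fake_assoc(R, c(1, 2))
  mono <- function(x) tanh(3 * x)  # strictly increasing
  R2 <- R; R2[, , 1, 2] <- mono(R[, , 1, 2]); R2[, , 2, 1] <- R2[, , 1, 2]
  a2 <- fake_assoc(R2, c(1, 2))
  expect_equal(classify_shift(a1, 1, 2)$pr_dry_gt_wet,
               classify_shift(a2, 1, 2)$pr_dry_gt_wet)
})

test_that("water-deficit percentiles follow the linear interpolation convention", {
  expect_equal(unname(cwd_percentiles(c(100, 200, 300, 400), 0.5)), 250)
  expect_equal(unname(cwd_percentiles(c(100, 200, 300, 400), c(0, 1))),
               c(100, 400))
  set.seed(8)
  u <- runif(1e5, 0, 1100)
  q <- cwd_percentiles(u, c(0.25, 0.75))
  expect_lt(abs(q[[1]] - 275), 10)
  expect_lt(abs(q[[2]] - 825), 10)
  expect_error(cwd_percentiles(u, 1.5), "0, 1")
})

test_that("Ellenberg cutoffs classify boundaries inclusively", {
  em <- c(a = 3, b = 5, c = 4, d = 1, e = 9, f = NA, g = 2.5, h = 5.5)
  g <- classify_tolerance(em)
  expect_equal(as.character(g[c("a", "d", "g")]),
               rep("drought_tolerant", 3))
  expect_equal(as.character(g[c("b", "e", "h")]),
               rep("drought_sensitive", 3))
  expect_equal(as.character(g[["c"]]), "intermediate")
  expect_equal(as.character(g[["f"]]), "unclassified")
  gs <- classify_tolerance(em, preset = "stringent")
  expect_equal(as.character(gs[["g"]]), "drought_tolerant")  # 2.5 specialist
  expect_equal(as.character(gs[["h"]]), "drought_sensitive") # 5.5 highly DS
  expect_equal(as.character(gs[["a"]]), "intermediate")      # 3 no longer DT
})

test_that("significance filtering uses equal-tailed posterior quantiles", {
  n <- 1000
  mk <- function(vals) {
    R <- array(0, c(n, 1, 2, 2))
    R[, 1, 1, 2] <- R[, 1, 2, 1] <- vals
    R[, 1, 1, 1] <- R[, 1, 2, 2] <- 1
    fake_assoc(R, 500)
  }
  expect_equal(significant_associations(mk(rep(0.4, n)), 500)[1, 2], 1)
  set.seed(2)
  expect_equal(significant_associations(mk(rnorm(n, 0, 0.2)), 500)[1, 2], 0)
  # boundary: exactly 25 of 1000 draws below zero; the type-7 2.5 percent
  # quantile interpolates between order statistics 25 and 26
  vals <- c(seq(-1, -0.1, length.out = 25), seq(0.5, 1, length.out = 975))
  q_oracle <- -0.1 + 0.975 * (0.5 - (-0.1))
  expect_gt(q_oracle, 0)
  expect_equal(significant_associations(mk(sample(vals)), 500)[1, 2], 1)
})

test_that("community association equals exhaustive counting on a labelled toy", {
  # 5 species: 2 DT, 1 intermediate, 2 DS; hand-built sign matrix
  g <- factor(c("drought_tolerant", "drought_tolerant", "intermediate",
                "drought_sensitive", "drought_sensitive"),
              levels = levels(classify_tolerance(1)))
  sig <- matrix(0, 5, 5)
  set_pair <- function(i, j, v) sig[i, j] <<- sig[j, i] <<- v
  set_pair(1, 2, +1)  # DT-DT positive
  set_pair(1, 3, -1)  # DT-int negative
  set_pair(2, 4, -1)  # DT-DS negative
  set_pair(3, 4, +1)  # int-DS positive
  set_pair(4, 5, +1)  # DS-DS positive
  set_pair(1, 5, 0)   # not significant
  # exhaustive hand counts
  expect_equal(community_association(sig, g, "DT_DT"),
               list(ca = 1, n_positive = 1L, n_negative = 0L,
                    defined = TRUE))
  expect_equal(community_association(sig, g, "DS_DS")$ca, 1)
  expect_equal(community_association(sig, g, "DS_DT")$ca, -1)
  expect_equal(community_association(sig, g, "DT_intermediate")$ca, -1)
  expect_equal(community_association(sig, g, "DS_intermediate")$ca, 1)
  # overall DS: pairs (2,4)=-1, (3,4)=+1, (4,5)=+1, (1,5)=0 -> (2-1)/3
  ov <- community_association(sig, g, "overall_DS")
  expect_equal(ov$ca, 1 / 3)
  expect_equal(ov$n_positive + ov$n_negative, 3L)
  # worked ratio: 3 positive, 1 negative -> 0.5
  sig2 <- matrix(0, 5, 5)
  sig2[1, 2] <- sig2[2, 1] <- 1; sig2[1, 3] <- sig2[3, 1] <- 1
  sig2[1, 4] <- sig2[4, 1] <- 1; sig2[1, 5] <- sig2[5, 1] <- -1
  expect_equal(community_association(sig2, g, "overall_DT")$ca, 0.5)
  # all-negative case pins CA at -1
  sig3 <- -abs(sig)
  expect_equal(community_association(sig3, g, "overall_DS")$ca, -1)
  # empty count is undefined and flagged
  e <- community_association(matrix(0, 5, 5), g, "DS_DS")
  expect_false(e$defined)
  expect_true(is.na(e$ca))
  expect_error(community_association(sig, g, "DS_overall"), "arg")
})

test_that("CA profiles respect limits and degenerate grids fail loudly", {
  res <- cached_sgh()
  grp <- classify_tolerance(res$data$traits)
  expect_error(ca_profile(res$fit, grp, cwd_grid = 500), "2 points")
  fit0 <- res$fit
  fit0$lambda_cwd[] <- 0  # static posterior: flat profiles
  prof <- ca_profile(fit0, grp, cwd_grid = c(200, 600, 1000),
                     combinations = "overall_DS")
  expect_true(all(abs(prof$ca - prof$ca[1]) < 1e-12))
  expect_true(all(prof$ca >= -1 & prof$ca <= 1, na.rm = TRUE))
})

test_that("delta CA is an elementwise contrast with the documented sign", {
  expect_equal(delta_ca(0.5, 0.2), 0.3)
  expect_equal(delta_ca(0.4, 0.4), 0)
  res <- cached_sgh()
  grp <- classify_tolerance(res$data$traits)
  prof <- ca_profile(res$fit, grp, cwd_grid = c(300, 800),
                     combinations = "overall_DS")
  d0 <- delta_ca(prof, prof)
  expect_true(all(d0$delta_ca == 0 | is.na(d0$delta_ca)))
})

test_that("stacked richness sums occurrence probabilities per group", {
  res <- cached_sgh()
  grp <- classify_tolerance(res$data$traits)
  fit0 <- res$fit
  fit0$beta[] <- 0  # every probability is exactly 1/2
  rich <- stacked_richness(fit0, res$data, grp, cwd_grid = c(200, 900))
  n_ds <- sum(grp == "drought_sensitive")
  expect_equal(rich$richness[rich$group == "drought_sensitive"],
               rep(n_ds / 2, 2))
  fit0$beta[] <- 0
  fit0$beta[, , 1] <- -30  # intercept-driven vanishing occupancy
  rich0 <- stacked_richness(fit0, res$data, grp, cwd_grid = c(200, 900))
  expect_true(all(rich0$richness < 1e-6))
})

test_that("planted residual trends are detected and degenerate species flagged", {
  res <- cached_sgh()
  # construct residuals rising linearly with the deficit for one species
  rc <- residual_cwd_correlation(res$fit, res$data)
  expect_true(all(rc$table$defined))
  expect_lt(abs(rc$summary$mean_correlation), 0.05)
  # planted signal: y replaced by a deterministic function of cwd
  d2 <- res$data
  d2$Y[, 1] <- as.integer(d2$cwd > quantile(d2$cwd, 0.5))
  rc2 <- residual_cwd_correlation(res$fit, d2)
  expect_gt(rc2$table$correlation[1], 0.5)
  expect_lt(rc2$table$p_value[1], 1e-10)
  # perfectly predicted species: constant residual is flagged, not zeroed
  fit0 <- res$fit
  fit0$beta[] <- 0; fit0$lambda[] <- 0; fit0$lambda_cwd[] <- 0
  d3 <- res$data
  d3$Y[, 2] <- 1L  # probability is exactly 1/2 everywhere: residual 1/2
  rc3 <- residual_cwd_correlation(fit0, d3)
  expect_false(rc3$table$defined[2])
  expect_true(is.na(rc3$table$correlation[2]))
})
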