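#' Configuration for synthetic community generation
#'
#' Bundles the dimensions and effect scales used to draw ground-truth
#' parameters and generate binary occurrence data under the
#' context-dependent latent-factor probit model. The defaults describe a
#' desk-scale community: 1,000 plots, 20 species, a water-deficit gradient
#' spanning 0--1,100 mm (the extent of the European dry-grassland gradient
#' this model class was developed for), and two latent factors.
#'
#' @param n_plots Number of vegetation plots (rows of the occurrence matrix).
#' @param n_species Number of species (columns).
#' @param n_env Number of environmental covariates including the water
#'   deficit (quadratic terms are a downstream preprocessing step, not
#'   generated here). Must be at least 1; the last covariate is always the
#'   water deficit CWD.
#' @param n_latent Number of latent factors \eqn{n_h}.
#' @param cwd_range Interval (mm) over which plot water-deficit values are
#'   drawn uniformly.
#' @param effect_scales List with elements `beta`, `lambda`, `lambda_cwd`:
#'   standard deviations of the corresponding ground-truth draws.
#' @param tolerance_mix Named proportions of species assigned Ellenberg
#'   moisture values in the drought-tolerant (E_m <= 3), intermediate
#'   (3 < E_m < 5) and drought-sensitive (E_m >= 5) ranges. Must sum to 1.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `simulation_config`.
#' @seealso [generate_truth()], [generate_community()]
#' @export
simulation_config <- function(n_plots = 1000, n_species = 20, n_env = 2,
                              n_latent = 2, cwd_range = c(0, 1100),
                              effect_scales = list(beta = 0.7, lambda = 0.8,
                                                   lambda_cwd = 0.4),
                              tolerance_mix = c(drought_tolerant = 0.3,
                                                intermediate = 0.4,
                                                drought_sensitive = 0.3),
                              seed = NULL) {
  stopifnot(n_plots >= 1, n_species >= 1, n_env >= 1, n_latent >= 0)
  if (length(cwd_range) != 2 || !(cwd_range[1] < cwd_range[2]))
    stop("`cwd_range` must be an interval with lower < upper", call. = FALSE)
  if (any(cwd_range < 0))
    stop("`cwd_range` must be non-negative (mm)", call. = FALSE)
  req <- c("beta", "lambda", "lambda_cwd")
  if (!all(req %in% names(effect_scales)))
    stop("`effect_scales` needs elements beta, lambda, lambda_cwd",
         call. = FALSE)
  if (abs(sum(tolerance_mix) - 1) > 1e-8)
    stop("`tolerance_mix` proportions must sum to 1", call. = FALSE)
  structure(list(n_plots = as.integer(n_plots),
                 n_species = as.integer(n_species),
                 n_env = as.integer(n_env),
                 n_latent = as.integer(n_latent),
                 cwd_range = as.numeric(cwd_range),
                 effect_scales = effect_scales,
                 tolerance_mix = tolerance_mix,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

# Standardization constants implied by a uniform CWD over `range`:
# theoretical mean and sd, used symmetrically by generator and tests.
cwd_uniform_scaling <- function(range) {
  list(center = mean(range), scale = diff(range) / sqrt(12))
}

em_levels <- list(drought_tolerant = c(1, 1.5, 2, 2.5, 3),
                  intermediate = c(3.5, 4, 4.5),
                  drought_sensitive = c(5, 5.5, 6, 7, 8, 9))

#' Draw ground-truth parameters for a synthetic community
#'
#' Realizes regression coefficients `beta` (species x predictors), latent
#' loadings `lambda` and their water-deficit slopes `lambda_cwd` (species x
#' factors), latent plot scores `eta` (plots x factors, standard normal)
#' and stratified Ellenberg moisture values. The water deficit enters the
#' loading term on a standardized scale (theoretical moments of the uniform
#' `cwd_range`); the scaling constants are stored in the returned object.
#' Total loadings `lambda + lambda_cwd * c` are rescaled if necessary so
#' their magnitude never exceeds 10 anywhere on the gradient.
#'
#' @param config A [simulation_config()].
#' @return An object of class `ground_truth` with elements `beta`,
#'   `lambda`, `lambda_cwd`, `eta`, `em_values`, `cwd_scaling`, `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  S <- config$n_species; k <- config$n_latent
  p <- config$n_env + 1L
  es <- config$effect_scales
  beta <- matrix(rnorm(S * p, 0, es$beta), S, p)
  lambda <- matrix(rnorm(S * max(k, 1), 0, es$lambda), S, max(k, 1))
  lambda_cwd <- matrix(rnorm(S * max(k, 1), 0, es$lambda_cwd), S, max(k, 1))
  if (k == 0) {
    lambda <- matrix(0, S, 0); lambda_cwd <- matrix(0, S, 0)
  }
  eta <- matrix(rnorm(config$n_plots * k), config$n_plots, k)

  scaling <- cwd_uniform_scaling(config$cwd_range)
  c_max <- sqrt(3)  # standardized uniform endpoints are +/- sqrt(3)
  if (k > 0) {
    tot <- pmax(abs(lambda - c_max * lambda_cwd),
                abs(lambda + c_max * lambda_cwd))
    m <- max(tot)
    if (m > 10) {
      lambda <- lambda * (10 / m)
      lambda_cwd <- lambda_cwd * (10 / m)
    }
  }

  em <- assign_em_values(S, config$tolerance_mix)
  structure(list(beta = beta, lambda = lambda, lambda_cwd = lambda_cwd,
                 eta = eta, em_values = em, cwd_scaling = scaling,
                 config = config),
            class = "ground_truth")
}

# Stratified Ellenberg moisture assignment: group sizes follow the
# configured proportions (largest-remainder rounding, every named group
# with positive proportion gets at least one species when S allows).
assign_em_values <- function(S, mix) {
  groups <- names(em_levels)
  target <- mix[groups] * S
  sizes <- floor(target)
  rem <- S - sum(sizes)
  if (rem > 0) {
    ord <- order(target - sizes, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  for (g in groups) {
    if (mix[g] > 0 && sizes[g] == 0 && max(sizes) >= 2) {
      donor <- which.max(sizes)
      sizes[donor] <- sizes[donor] - 1
      sizes[g] <- 1
    }
  }
  em <- numeric(0)
  for (g in groups)
    em <- c(em, sample(em_levels[[g]], sizes[g], replace = TRUE))
  sample(em)  # shuffle species order
}

#' Generate a binary community dataset from ground-truth parameters
#'
#' Runs the generative model forward: draws plot water-deficit values
#' uniformly over the configured range, i.i.d. standard-normal values for
#' the remaining covariates, forms the latent score
#' \eqn{z_{ij} = \sum_k x_{ik}\beta_{jk} + \sum_h \eta_{ih}(\lambda_{jh} +
#' \lambda^{CWD}_{jh} c_i)} with standardized water deficit \eqn{c_i}, adds
#' a unit-variance probit residual and thresholds at zero.
#'
#' The stored environment matrix `X` carries the water deficit on its raw
#' mm scale (column `CWD_GS`); the standardized version used inside the
#' model is reconstructed from `truth$cwd_scaling`.
#'
#' @param truth A [generate_truth()] result (dimensions must match `config`).
#' @param config The same [simulation_config()].
#' @return An object of class `community_dataset` with elements `Y`, `X`,
#'   `cwd`, `species_ids`, `plot_ids`, `traits`, `truth`.
#' @export
generate_community <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  S <- config$n_species; n <- config$n_plots; k <- config$n_latent
  if (nrow(truth$beta) != S || ncol(truth$beta) != config$n_env + 1L ||
      nrow(truth$eta) != n || ncol(truth$lambda) != k)
    stop("truth dimensions do not match config", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)

  cwd <- runif(n, config$cwd_range[1], config$cwd_range[2])
  sc <- truth$cwd_scaling
  cwd_std <- (cwd - sc$center) / sc$scale
  n_other <- config$n_env - 1L
  E <- if (n_other > 0) matrix(rnorm(n * n_other), n, n_other) else
    matrix(0, n, 0)
  if (n_other > 0) colnames(E) <- paste0("env", seq_len(n_other))
  X_model <- cbind(`(Intercept)` = 1, E, CWD_GS = cwd_std)

  z <- X_model %*% t(truth$beta)
  if (k > 0) {
    z <- z + truth$eta %*% t(truth$lambda) +
      (truth$eta * cwd_std) %*% t(truth$lambda_cwd)
  }
  if (!all(is.finite(z))) {
    bad <- which(!is.finite(z), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite latent score at plot %d, species %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  Y <- (z + matrix(rnorm(n * S), n, S) > 0) * 1L

  X <- X_model
  X[, "CWD_GS"] <- cwd  # store raw mm scale
  species_ids <- sprintf("sp%03d", seq_len(S))
  plot_ids <- sprintf("plot%05d", seq_len(n))
  dimnames(Y) <- list(plot_ids, species_ids)
  rownames(X) <- plot_ids
  traits <- setNames(truth$em_values, species_ids)
  community_dataset(Y = Y, X = X, cwd = cwd, species_ids = species_ids,
                    plot_ids = plot_ids, traits = traits, truth = truth)
}

#' Construct (and validate) a community dataset object
#'
#' @param Y Binary plots x species matrix.
#' @param X Plots x predictors matrix including an intercept column.
#' @param cwd Plot water-deficit vector (mm).
#' @param species_ids,plot_ids Label vectors (unique).
#' @param traits Named numeric vector of Ellenberg moisture values
#'   (`NA` allowed).
#' @param truth Optional [generate_truth()] object.
#' @return Object of class `community_dataset`.
#' @export
community_dataset <- function(Y, X, cwd, species_ids = colnames(Y),
                              plot_ids = rownames(Y), traits = NULL,
                              truth = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (!all(Y %in% c(0, 1)))
    stop("occurrence matrix Y must be strictly binary", call. = FALSE)
  if (nrow(Y) != nrow(X) || nrow(Y) != length(cwd))
    stop("Y, X and cwd must agree on the number of plots", call. = FALSE)
  if (anyDuplicated(species_ids) || anyDuplicated(plot_ids))
    stop("species and plot labels must be unique", call. = FALSE)
  if (any(!is.finite(cwd)) || any(cwd < 0))
    stop("cwd must be finite and non-negative (mm)", call. = FALSE)
  structure(list(Y = Y, X = X, cwd = as.numeric(cwd),
                 species_ids = species_ids, plot_ids = plot_ids,
                 traits = traits, truth = truth),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  cat("community_dataset:", nrow(x$Y), "plots x", ncol(x$Y), "species;",
      ncol(x$X), "predictor columns\n")
  cat("  CWD range:", round(min(x$cwd)), "-", round(max(x$cwd)), "mm;",
      "mean occupancy:", round(mean(x$Y), 3), "\n")
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Structured ground truth encoding a stress-gradient scenario
#'
#' Builds a two-factor ground truth in which drought-sensitive (DS) species
#' share a factor whose loadings grow with water deficit (their residual
#' associations become more positive toward the dry end) while
#' drought-tolerant (DT) species share a factor whose loadings shrink with
#' water deficit (their associations weaken/fall). Each species also gets a
#' constant-magnitude loading of random sign on the other factor so that
#' correlations are not rank-1 degenerate. Regression coefficients give DS
#' species declining and DT species increasing occurrence probability along
#' the gradient, mirroring the expected richness turnover.
#'
#' @param config A [simulation_config()] with `n_latent = 2`.
#' @return A `ground_truth` object.
#' @export
sgh_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_latent != 2)
    stop("the stress-gradient scenario uses exactly 2 latent factors",
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  S <- config$n_species
  n_dt <- max(1L, round(S * config$tolerance_mix[["drought_tolerant"]]))
  n_ds <- max(1L, round(S * config$tolerance_mix[["drought_sensitive"]]))
  n_int <- S - n_dt - n_ds
  if (n_int < 0) stop("tolerance_mix leaves no room for all groups",
                      call. = FALSE)
  group <- c(rep("drought_tolerant", n_dt), rep("intermediate", n_int),
             rep("drought_sensitive", n_ds))

  lambda <- matrix(0, S, 2); lambda_cwd <- matrix(0, S, 2)
  jit <- function(m) rnorm(m, 0, 0.05)
  # balanced alternating signs guarantee both same- and opposite-sign
  # pairs inside each group (the planted shift classes are never empty)
  sgn <- function(m) rep_len(c(-1, 1), m)
  ds <- group == "drought_sensitive"
  dt <- group == "drought_tolerant"
  it <- group == "intermediate"
  # DS share factor 1 with a loading that rises through zero along the
  # gradient (mixed-sign pair covariances at the wet end, uniformly
  # positive at the dry end); a constant random-sign loading on factor 2
  # keeps correlations away from the rank-1 +/-1 degeneracy.
  lambda[ds, 1] <- 0.6 + jit(n_ds)
  lambda_cwd[ds, 1] <- 1.2 + jit(n_ds)
  lambda[ds, 2] <- 0.8 * sgn(n_ds)
  # DT mirror the construction on factor 2 with a falling loading:
  # within-group associations uniformly positive when wet, mixed when dry.
  lambda[dt, 2] <- 0.6 + jit(n_dt)
  lambda_cwd[dt, 2] <- -(1.2 + jit(n_dt))
  lambda[dt, 1] <- 0.8 * sgn(n_dt)
  if (n_int > 0) {
    lambda[it, 1] <- 0.6 * sgn(n_int)
    lambda[it, 2] <- 0.6 * sgn(n_int)
  }

  p <- config$n_env + 1L
  beta <- matrix(rnorm(S * p, 0, 0.2), S, p)
  beta[, 1] <- rnorm(S, 0.2, 0.2)                 # intercept
  beta[, p] <- 0.1 * rnorm(S)                      # CWD response
  beta[ds, p] <- -0.8 + 0.1 * rnorm(n_ds)
  beta[dt, p] <- 0.8 + 0.1 * rnorm(n_dt)

  em <- numeric(S)
  em[dt] <- sample(em_levels$drought_tolerant, n_dt, replace = TRUE)
  em[it] <- sample(em_levels$intermediate, max(n_int, 1), replace = TRUE)[seq_len(n_int)]
  em[ds] <- sample(em_levels$drought_sensitive, n_ds, replace = TRUE)

  structure(list(beta = beta, lambda = lambda, lambda_cwd = lambda_cwd,
                 eta = matrix(rnorm(config$n_plots * 2), config$n_plots, 2),
                 em_values = em,
                 cwd_scaling = cwd_uniform_scaling(config$cwd_range),
                 config = config),
            class = "ground_truth")
}

#' Synthetic monthly climate table for water-balance testing
#'
#' Emits one row per synthetic cell with 12 monthly minimum/mean/maximum
#' temperatures (deg C), 12 monthly precipitation values (mm), available
#' soil water capacity (mm) and latitude. Presets: `"temperate"`
#' (sinusoidal seasonal temperature, winter-skewed rain), `"arid"` (hot,
#' zero summer precipitation), `"constant"` (10 deg C and 50 mm/month all
#' year).
#'
#' @param n_cells Number of cells.
#' @param preset One of `"temperate"`, `"arid"`, `"constant"`.
#' @param seed Optional RNG seed.
#' @return A data.frame with columns `cell_id`, `tmin_1..12`,
#'   `tmean_1..12`, `tmax_1..12`, `prec_1..12`, `awc`, `latitude`.
#' @export
generate_climate_series <- function(n_cells = 10,
                                    preset = c("temperate", "arid",
                                               "constant"),
                                    seed = NULL) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(seed)
  m <- 1:12
  base <- switch(preset,
    temperate = list(tmean = 8 + 9 * sin(2 * pi * (m - 4) / 12),
                     prec = 70 + 30 * cos(2 * pi * (m - 1) / 12),
                     awc = 120, lat = 48),
    arid = list(tmean = 18 + 10 * sin(2 * pi * (m - 4) / 12),
                prec = ifelse(m %in% 5:8, 0, 25),
                awc = 60, lat = 38),
    constant = list(tmean = rep(10, 12), prec = rep(50, 12),
                    awc = 100, lat = 45))
  rows <- lapply(seq_len(n_cells), function(i) {
    dt <- if (preset == "constant") 0 else rnorm(1, 0, 1)
    dp <- if (preset == "constant") 1 else exp(rnorm(1, 0, 0.1))
    tmean <- base$tmean + dt
    prec <- base$prec * dp
    spread <- if (preset == "constant") 4 else 4 + abs(rnorm(1, 0, 0.5))
    c(tmean - spread, tmean, tmean + spread, prec,
      base$awc * dp, base$lat)
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c(paste0("tmin_", m), paste0("tmean_", m),
                     paste0("tmax_", m), paste0("prec_", m),
                     "awc", "latitude")
  data.frame(cell_id = sprintf("cell%03d", seq_len(n_cells)), tab,
             check.names = FALSE)
}

#' Write a community dataset as plain-text CSV files
#'
#' Writes `occurrence.csv` (plot id + one binary column per species),
#' `environment.csv` (plot id + predictor columns excluding the
#' intercept; `CWD_GS` in mm), `traits.csv` (species id, Ellenberg
#' moisture value) and a `metadata.txt` sidecar echoing the generating
#' configuration.
#'
#' @param data A `community_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_community <- function(data, dir) {
  stopifnot(inherits(data, "community_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keep <- apply(data$X, 2, function(v) sd(v) > 0)  # drop intercept
  occ <- data.frame(plot_id = data$plot_ids, data$Y, check.names = FALSE)
  env <- data.frame(plot_id = data$plot_ids, data$X[, keep, drop = FALSE],
                    check.names = FALSE)
  tr <- data.frame(species_id = data$species_ids,
                   Em = if (is.null(data$traits)) NA_real_ else
                     as.numeric(data$traits[data$species_ids]))
  paths <- file.path(dir, c("occurrence.csv", "environment.csv",
                            "traits.csv", "metadata.txt"))
  write.csv(occ, paths[1], row.names = FALSE)
  write.csv(env, paths[2], row.names = FALSE)
  write.csv(tr, paths[3], row.names = FALSE)
  cfg <- if (!is.null(data$truth)) data$truth$config else NULL
  meta <- c(sprintf("n_plots: %d", nrow(data$Y)),
            sprintf("n_species: %d", ncol(data$Y)),
            if (!is.null(cfg)) sprintf("seed: %s",
                                       ifelse(is.null(cfg$seed), "NULL",
                                              cfg$seed)),
            if (!is.null(cfg)) sprintf("cwd_range: %g %g",
                                       cfg$cwd_range[1], cfg$cwd_range[2]))
  writeLines(meta, paths[4])
  invisible(paths)
}
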