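# Independent brute-force oracle for the association matrix: forms the
# total-loading matrix L(c) element by element and computes the
# correlation from explicit double loops (no shared code with the
# implementation path).
oracle_association <- function(lambda, lambda_cwd, cwd, center, scale) {
  c_std <- (cwd - center) / scale
  S <- nrow(lambda); k <- ncol(lambda)
  L <- matrix(0, S, k)
  for (j in seq_len(S))
    for (h in seq_len(k))
      L[j, h] <- lambda[j, h] + lambda_cwd[j, h] * c_std
  Om <- matrix(0, S, S)
  for (j1 in seq_len(S))
    for (j2 in seq_len(S))
      Om[j1, j2] <- sum(L[j1, ] * L[j2, ])
  R <- matrix(NA_real_, S, S)
  for (j1 in seq_len(S))
    for (j2 in seq_len(S)) {
      dd <- Om[j1, j1] * Om[j2, j2]
      if (dd > 0) R[j1, j2] <- Om[j1, j2] / sqrt(dd)
    }
  diag(R)[diag(Om) > 0] <- 1
  R
}

# Assemble a hand-constructed association posterior (draws x cwd x S x S)
# so classification operations can be tested against counting oracles.
fake_assoc <- function(R_array, cwd_values,
                       species = sprintf("sp%02d", dim(R_array)[3])) {
  structure(list(R = R_array,
                 cwd_values = cwd_values,
                 species_ids = sprintf("sp%02d", seq_len(dim(R_array)[3]))),
            class = "association_posterior")
}

# Shared small SGH-scenario fit, computed once per test run (several test
# files probe different aspects of the same fitted posterior).
.fit_cache <- new.env(parent = emptyenv())
cached_sgh <- function() {
  if (!is.null(.fit_cache$sgh)) return(.fit_cache$sgh)
  cfg <- simulation_config(
    n_plots = 800, n_species = 12, n_env = 2, n_latent = 2,
    tolerance_mix = c(drought_tolerant = 1/3, intermediate = 1/3,
                      drought_sensitive = 1/3),
    seed = 21)
  truth <- sgh_truth(cfg)
  data <- generate_community(truth, cfg)
  fit <- fit_context_jsdm(
    data, mcmc_config(n_chains = 2, n_burnin = 1500, n_samples = 1000,
                      n_latent = 2, seed = 5,
                      prior_hyperparams = list(a1 = 3, a2 = 3)))
  .fit_cache$sgh <- list(config = cfg, truth = truth, data = data,
                         fit = fit)
  .fit_cache$sgh
}
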