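#' Read a community dataset from CSV/TSV tables
#'
#' Expects an occurrence table (plot id first column, one binary column
#' per species), an environment table (plot id first column, one column
#' per covariate, including the water-deficit column), and optionally a
#' trait table (species id first column, Ellenberg moisture value
#' second). Plots are matched between the occurrence and environment
#' tables by identifier; species missing from the trait table get `NA`
#' (they end up `unclassified`) with a warning.
#'
#' @param occurrence_file,environment_file,traits_file File paths
#'   (`.csv` or `.tsv`); `traits_file` may be `NULL`.
#' @param cwd_column Name of the water-deficit column (mm) in the
#'   environment table.
#' @return A `community_dataset` (X gains an intercept column).
#' @export
read_dataset <- function(occurrence_file, environment_file,
                         traits_file = NULL, cwd_column = "CWD_GS") {
  read_tab <- function(path) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    read.csv(path, sep = sep, check.names = FALSE)
  }
  occ <- read_tab(occurrence_file)
  env <- read_tab(environment_file)
  plot_ids <- as.character(occ[[1]])
  Y <- as.matrix(occ[, -1, drop = FALSE])
  bad <- which(!(Y %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(Y))
    stop(sprintf(
      "non-binary occurrence value %s at plot '%s', species '%s'",
      Y[bad[1]], plot_ids[rc[1]], colnames(Y)[rc[2]]), call. = FALSE)
  }
  storage.mode(Y) <- "integer"
  env_ids <- as.character(env[[1]])
  m <- match(plot_ids, env_ids)
  if (anyNA(m))
    stop("plots missing from the environment table: ",
         paste(head(plot_ids[is.na(m)], 5), collapse = ", "),
         call. = FALSE)
  env <- env[m, -1, drop = FALSE]
  if (!cwd_column %in% colnames(env))
    stop("environment table lacks the water-deficit column '",
         cwd_column, "'", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(env))
  rownames(X) <- plot_ids
  rownames(Y) <- plot_ids
  traits <- NULL
  species_ids <- colnames(Y)
  if (!is.null(traits_file)) {
    tr <- read_tab(traits_file)
    traits <- setNames(rep(NA_real_, length(species_ids)), species_ids)
    hit <- match(species_ids, as.character(tr[[1]]))
    traits[!is.na(hit)] <- as.numeric(tr[[2]][hit[!is.na(hit)]])
    if (anyNA(traits))
      warning("species without trait values (left unclassified): ",
              paste(species_ids[is.na(traits)], collapse = ", "))
  }
  community_dataset(Y = Y, X = X, cwd = as.numeric(env[[cwd_column]]),
                    species_ids = species_ids, plot_ids = plot_ids,
                    traits = traits)
}

#' Greedy collinearity pruning of environmental covariates
#'
#' Iteratively removes covariates until no pair exceeds the absolute
#' Pearson correlation threshold. At each step the variable with the
#' largest mean absolute correlation among the violating variables is
#' dropped; variables named in `keep_priority` are never dropped.
#'
#' @param X Covariate matrix (constant/intercept columns are passed
#'   through untouched).
#' @param threshold Absolute correlation threshold (default .7).
#' @param keep_priority Column names protected from dropping.
#' @return List: `X` (pruned matrix) and `report` (data frame of drops
#'   with the triggering correlation).
#' @export
prune_collinear <- function(X, threshold = 0.7, keep_priority = character()) {
  X <- as.matrix(X)
  missing_prio <- setdiff(keep_priority, colnames(X))
  if (length(missing_prio))
    stop("keep_priority names absent columns: ",
         paste(missing_prio, collapse = ", "), call. = FALSE)
  const <- apply(X, 2, sd) == 0
  vars <- colnames(X)[!const]
  if (length(vars) < 2)
    return(list(X = X, report = data.frame(variable = character(),
                                           partner = character(),
                                           correlation = numeric())))
  drops <- list()
  repeat {
    C <- abs(cor(X[, vars, drop = FALSE]))
    diag(C) <- 0
    if (max(C) <= threshold) break
    viol <- which(C > threshold, arr.ind = TRUE)
    involved <- unique(vars[viol[, 1]])
    candidates <- setdiff(involved, keep_priority)
    if (!length(candidates)) {
      warning("remaining violations involve only protected variables")
      break
    }
    mean_abs <- colMeans(abs(cor(X[, vars, drop = FALSE])) -
                           diag(length(vars))) # exclude self-correlation
    names(mean_abs) <- vars
    drop <- candidates[which.max(mean_abs[candidates])]
    partner_idx <- which.max(C[drop, ])
    drops[[length(drops) + 1]] <- data.frame(
      variable = drop, partner = vars[partner_idx],
      correlation = max(C[drop, ]))
    vars <- setdiff(vars, drop)
    if (length(vars) < 2) break
  }
  keep_cols <- colnames(X)[const | colnames(X) %in% vars]
  list(X = X[, keep_cols, drop = FALSE],
       report = if (length(drops)) do.call(rbind, drops) else
         data.frame(variable = character(), partner = character(),
                    correlation = numeric()))
}

#' Append quadratic terms to the covariate matrix
#'
#' Adds a squared column `<name>_sq` for every non-constant covariate.
#' Calling it on a matrix that already carries `_sq` columns is an error
#' (quartics are never intended).
#'
#' @param X Covariate matrix including the intercept.
#' @return Expanded matrix.
#' @export
add_quadratics <- function(X) {
  X <- as.matrix(X)
  if (any(grepl("_sq$", colnames(X))))
    stop("X already contains quadratic columns", call. = FALSE)
  vary <- apply(X, 2, sd) > 0
  sq <- X[, vary, drop = FALSE]^2
  colnames(sq) <- paste0(colnames(X)[vary], "_sq")
  cbind(X, sq)
}

#' Retain one random plot per grid cell
#'
#' Guards against pseudo-replication of plots falling in the same
#' environmental-data grid cell: within each cell one plot is kept,
#' selected uniformly at random.
#'
#' @param data A `community_dataset`.
#' @param cell_ids Vector of cell identifiers, one per plot.
#' @param seed Optional RNG seed for reproducibility.
#' @return Subsampled `community_dataset`.
#' @export
one_plot_per_cell <- function(data, cell_ids, seed = NULL) {
  stopifnot(inherits(data, "community_dataset"))
  if (length(cell_ids) != nrow(data$Y) || anyNA(cell_ids))
    stop("cell_ids must be complete and aligned with plots", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  keep <- vapply(split(seq_along(cell_ids), cell_ids), function(idx) {
    if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
  }, 0L)
  keep <- sort(unname(keep))
  subset_plots(data, keep)
}

subset_plots <- function(data, idx) {
  community_dataset(Y = data$Y[idx, , drop = FALSE],
                    X = data$X[idx, , drop = FALSE],
                    cwd = data$cwd[idx],
                    species_ids = data$species_ids,
                    plot_ids = data$plot_ids[idx],
                    traits = data$traits, truth = data$truth)
}

#' Minimum-presence cutoff implied by the events-per-predictor rule
#'
#' @param min_per_predictor Required presences per predictor (default 10).
#' @param n_env Number of environmental predictors (quadratics included,
#'   intercept excluded).
#' @param n_latent Number of latent variables.
#' @return Scalar minimum number of presences.
#' @export
min_presence_cutoff <- function(min_per_predictor = 10, n_env, n_latent) {
  min_per_predictor * (n_env + n_latent)
}

#' Remove species with too few presences
#'
#' A species is retained when its total presence count reaches
#' `min_per_predictor` times the number of predictors, where predictors
#' count the environmental variables (quadratics included, intercept
#' excluded) plus the latent variables.
#'
#' @param data A `community_dataset`.
#' @param min_per_predictor Presences required per predictor.
#' @param n_latent Number of latent variables to include in the count.
#' @param n_predictors Override the predictor count entirely (otherwise
#'   computed from `data$X` and `n_latent`).
#' @return List: `data` (filtered dataset), `report` (removed species and
#'   their presence counts), `cutoff`.
#' @export
filter_rare_species <- function(data, min_per_predictor = 10, n_latent = 0,
                                n_predictors = NULL) {
  stopifnot(inherits(data, "community_dataset"))
  if (is.null(n_predictors)) {
    n_env <- sum(apply(data$X, 2, sd) > 0)
    n_predictors <- n_env + n_latent
  }
  cutoff <- min_presence_cutoff(min_per_predictor, n_predictors, 0)
  if (cutoff >= nrow(data$Y))
    warning("presence cutoff (", cutoff, ") is not below the plot count; ",
            "the filtered dataset may be empty")
  presences <- colSums(data$Y)
  keep <- presences >= cutoff
  removed <- data.frame(species = data$species_ids[!keep],
                        presences = presences[!keep])
  out <- data
  out$Y <- data$Y[, keep, drop = FALSE]
  out$species_ids <- data$species_ids[keep]
  if (!is.null(data$traits)) out$traits <- data$traits[keep]
  list(data = out, report = removed, cutoff = cutoff)
}

#' Pipeline configuration
#'
#' @param occurrence_file,environment_file,traits_file Input paths (or
#'   supply `data` directly to [run_pipeline()]).
#' @param cwd_column Water-deficit column name.
#' @param collinearity_threshold Absolute Pearson correlation above which
#'   covariates are pruned.
#' @param keep_priority Covariates never pruned (the water-deficit column
#'   by default).
#' @param quadratics Add squared covariate columns.
#' @param cell_column Optional column of `environment_file` holding grid
#'   cell ids for the one-plot-per-cell subsampling (`NULL` to skip).
#' @param min_per_predictor Presences required per predictor for a species
#'   to be retained.
#' @param percentiles Wet/dry anchor percentiles for shift classification
#'   (default 25th/75th; the 5th/95th pair probes a wider gradient).
#' @param tolerance_preset `"standard"` or `"stringent"` Ellenberg
#'   cutoffs.
#' @param mcmc An [mcmc_config()].
#' @param ca_grid_size Number of water-deficit grid points for CA
#'   profiles.
#' @param out_dir Optional output directory for CSV artifacts and the run
#'   manifest.
#' @param seed Pipeline-level seed (subsampling; the MCMC uses
#'   `mcmc$seed`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(occurrence_file = NULL, environment_file = NULL,
                            traits_file = NULL, cwd_column = "CWD_GS",
                            collinearity_threshold = 0.7,
                            keep_priority = cwd_column,
                            quadratics = TRUE, cell_column = NULL,
                            min_per_predictor = 10,
                            percentiles = c(0.25, 0.75),
                            tolerance_preset = "standard",
                            mcmc = mcmc_config(), ca_grid_size = 20,
                            out_dir = NULL, seed = 1) {
  stopifnot(collinearity_threshold > 0, collinearity_threshold <= 1,
            length(percentiles) == 2, percentiles[1] < percentiles[2],
            min_per_predictor >= 0, ca_grid_size >= 2)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates: read (or take) the dataset, prune collinear covariates,
#' add quadratic terms, subsample one plot per cell, filter rare species,
#' fit the context-dependent and the static model, evaluate the residual
#' association posterior at the wet/dry anchor percentiles, classify
#' pairwise shifts, build community-association profiles for both models,
#' contrast them, compute stacked group richness, and run the
#' residual-versus-deficit diagnostic. Every stage is logged with its
#' input/output dimensions; a machine-readable manifest captures the
#' configuration, seeds and convergence summary.
#'
#' @param config A [pipeline_config()].
#' @param data Optional in-memory `community_dataset` (skips file
#'   reading).
#' @param verbose Emit progress messages.
#' @return List with the fitted models, shift table, CA profiles, delta
#'   CA, richness curves, residual diagnostic, convergence report, and
#'   manifest.
#' @export
run_pipeline <- function(config, data = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  log <- list()
  stage <- function(name, ...) {
    say("[%s] %s", name, sprintf(...))
    log[[name]] <<- sprintf(...)
  }

  if (is.null(data)) {
    data <- read_dataset(config$occurrence_file, config$environment_file,
                         config$traits_file, config$cwd_column)
  }
  stage("read", "%d plots x %d species, %d predictor columns",
        nrow(data$Y), ncol(data$Y), ncol(data$X))

  cell_ids <- NULL
  if (!is.null(config$cell_column)) {
    if (!config$cell_column %in% colnames(data$X))
      stop("cell column '", config$cell_column, "' not found", call. = FALSE)
    cell_ids <- data$X[, config$cell_column]
    data$X <- data$X[, setdiff(colnames(data$X), config$cell_column),
                     drop = FALSE]
  }

  pruned <- prune_collinear(data$X, config$collinearity_threshold,
                            keep_priority = intersect(
                              config$keep_priority, colnames(data$X)))
  data$X <- pruned$X
  stage("prune", "%d covariates dropped, %d columns retained",
        nrow(pruned$report), ncol(data$X))

  if (config$quadratics) {
    data$X <- add_quadratics(data$X)
    stage("quadratics", "expanded to %d columns", ncol(data$X))
  }

  if (!is.null(cell_ids)) {
    n0 <- nrow(data$Y)
    data <- one_plot_per_cell(data, cell_ids, seed = config$seed)
    stage("subsample", "one plot per cell: %d -> %d plots", n0, nrow(data$Y))
  }

  filt <- filter_rare_species(data, config$min_per_predictor,
                              n_latent = config$mcmc$n_latent)
  data <- filt$data
  stage("rare_filter", "cutoff %d presences; %d species retained",
        filt$cutoff, ncol(data$Y))
  if (ncol(data$Y) < 2)
    stop("fewer than 2 species survive the rare-species filter",
         call. = FALSE)

  stage("fit_dynamic", "fitting context-dependent model (%d chains x %d+%d)",
        config$mcmc$n_chains, config$mcmc$n_burnin, config$mcmc$n_samples)
  fit_dyn <- fit_context_jsdm(data, config$mcmc, cwd_dependent = TRUE)
  stage("fit_static", "fitting static model")
  fit_sta <- fit_context_jsdm(data, config$mcmc, cwd_dependent = FALSE)

  conv <- if (config$mcmc$n_chains >= 2)
    convergence_report(fit_dyn, include_loadings = FALSE) else NULL
  if (!is.null(conv) && !conv$converged)
    warning("dynamic model not converged: max PSRF = ",
            round(conv$max_psrf, 3), ", min ESS = ", round(conv$min_ess),
            immediate. = TRUE)

  anchors <- cwd_percentiles(data, config$percentiles)
  assoc <- association_posterior(fit_dyn, anchors)
  shifts <- classify_shift(assoc, anchors[1], anchors[2])
  stage("shifts", "anchors %.0f / %.0f mm; %d pairs classified",
        anchors[1], anchors[2], nrow(shifts))

  groups <- classify_tolerance(data$traits, preset = config$tolerance_preset)
  grid <- seq(min(data$cwd), max(data$cwd),
              length.out = config$ca_grid_size)
  ca_dyn <- ca_profile(fit_dyn, groups, cwd_grid = grid,
                       combinations = c("overall_DS", "overall_DT"))
  ca_sta <- ca_profile(fit_sta, groups, cwd_grid = grid,
                       combinations = c("overall_DS", "overall_DT"))
  dca <- delta_ca(ca_sta, ca_dyn)
  stage("ca", "CA profiles on %d grid points", length(grid))

  rich <- stacked_richness(fit_dyn, data, groups, cwd_grid = grid,
                           cwd_column = config$cwd_column)
  resid <- residual_cwd_correlation(fit_dyn, data)
  stage("residual_check", "mean residual correlation %.4f",
        resid$summary$mean_correlation)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cdjsdm")),
    seed = config$seed, mcmc_seed = config$mcmc$seed,
    config = config[setdiff(names(config), "mcmc")],
    mcmc = unclass(config$mcmc),
    stages = log,
    convergence = if (!is.null(conv))
      list(max_psrf = conv$max_psrf, min_ess = conv$min_ess,
           converged = conv$converged) else NULL)

  result <- list(data = data, fit_dynamic = fit_dyn, fit_static = fit_sta,
                 convergence = conv, anchors = anchors,
                 shift_table = shifts, groups = groups,
                 ca_dynamic = ca_dyn, ca_static = ca_sta, delta_ca = dca,
                 richness = rich, residual_check = resid,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wp <- function(obj, f) write.csv(obj, file.path(config$out_dir, f),
                                     row.names = FALSE)
    wp(as.data.frame(shifts), "shift_table.csv")
    wp(as.data.frame(ca_dyn), "ca_dynamic.csv")
    wp(as.data.frame(ca_sta), "ca_static.csv")
    wp(dca, "delta_ca.csv")
    wp(rich, "richness.csv")
    wp(resid$table, "residual_check.csv")
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    say("[write] artifacts in %s", config$out_dir)
  }
  result
}
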