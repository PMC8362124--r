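#' Potential scale reduction factor (split-chain Gelman-Rubin)
#'
#' Each chain is split in half (the middle element is dropped for odd
#' lengths), then the classic between/within variance ratio is computed
#' over the split chains:
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}.
#'
#' Chains with zero variance throughout return 1 with a warning (defined
#' behaviour for automated pipelines); zero within-chain variance with
#' separated means returns `Inf`.
#'
#' @param chains Matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least 2 chains of length >= 10.
#' @return Scalar PSRF.
#' @export
psrf <- function(chains) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1) stop("chains must have equal length", call. = FALSE)
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2)
    stop("PSRF requires at least two chains", call. = FALSE)
  if (nrow(chains) < 10)
    stop("chains must have length >= 10", call. = FALSE)
  half <- floor(nrow(chains) / 2)
  splits <- cbind(chains[seq_len(half), , drop = FALSE],
                  chains[nrow(chains) - half + seq_len(half), ,
                         drop = FALSE])
  n <- nrow(splits)
  W <- mean(apply(splits, 2, var))
  B <- n * var(colMeans(splits))
  if (W == 0) {
    if (B == 0) {
      warning("zero-variance chains; PSRF defined as 1")
      return(1)
    }
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size (initial monotone positive-pair estimator)
#'
#' Autocorrelation-based ESS with Geyer's truncation: successive
#' autocorrelation pairs \eqn{\Gamma_m = \rho_{2m} + \rho_{2m+1}} are
#' summed while positive, with the running sequence forced monotone
#' non-increasing. A constant sequence returns its length with a warning.
#'
#' @param x Numeric draw sequence, length >= 10.
#' @return Scalar effective sample size.
#' @export
ess <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("ESS requires at least 10 draws", call. = FALSE)
  if (var(x) == 0) {
    warning("constant sequence; ESS defined as the sequence length")
    return(n)
  }
  lag_max <- min(n - 1, max(200L, floor(10 * sqrt(n))))
  rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)
  n_pairs <- floor((length(rho)) / 2)
  gam <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  # initial positive sequence, then monotone envelope
  pos <- which(gam <= 0)
  if (length(pos)) gam <- gam[seq_len(pos[1] - 1)]
  if (length(gam) > 1) gam <- cummin(gam)
  tau <- max(2 * sum(gam) - 1, 1e-12)
  min(n / tau, n * 1.5)
}

#' Convergence report for a fitted model
#'
#' Computes the PSRF (across chains) and total ESS (summed over chains)
#' for every regression coefficient and, optionally, every loading, and
#' summarizes them as the maximum PSRF and minimum ESS the original
#' model-checking protocol reports.
#'
#' @param fit A `cdjsdm_fit` with at least two chains.
#' @param psrf_max,ess_min Convergence thresholds for the `converged` flag.
#' @param include_loadings Also diagnose `lambda` and `lambda_cwd` (their
#'   sign/rotation is not identified, so diagnostics are computed on the
#'   absolute loadings).
#' @return Object of class `convergence_report`: data frame `table`
#'   (parameter, psrf, ess) and scalars `max_psrf`, `min_ess`,
#'   `converged`.
#' @export
convergence_report <- function(fit, psrf_max = 1.1, ess_min = 100,
                               include_loadings = TRUE) {
  stopifnot(inherits(fit, "cdjsdm_fit"))
  if (fit$config$n_chains < 2)
    stop("convergence diagnostics require >= 2 chains", call. = FALSE)
  ids <- fit$chain_ids
  per_param <- function(v, name) {
    m <- do.call(cbind, split(v, ids))
    data.frame(parameter = name, psrf = psrf(m),
               ess = sum(apply(m, 2, ess)))
  }
  rows <- list()
  S <- dim(fit$beta)[2]; p <- dim(fit$beta)[3]
  for (j in seq_len(S))
    for (q in seq_len(p))
      rows[[length(rows) + 1]] <- per_param(
        fit$beta[, j, q],
        sprintf("beta[%s,%s]", fit$species_ids[j], fit$predictor_names[q]))
  k <- dim(fit$lambda)[3]
  if (include_loadings && k > 0) {
    for (j in seq_len(S))
      for (h in seq_len(k)) {
        rows[[length(rows) + 1]] <- per_param(
          abs(fit$lambda[, j, h]),
          sprintf("|lambda|[%s,%d]", fit$species_ids[j], h))
        if (fit$cwd_dependent)
          rows[[length(rows) + 1]] <- per_param(
            abs(fit$lambda_cwd[, j, h]),
            sprintf("|lambda_cwd|[%s,%d]", fit$species_ids[j], h))
      }
  }
  tab <- suppressWarnings(do.call(rbind, rows))
  structure(list(table = tab, max_psrf = max(tab$psrf),
                 min_ess = min(tab$ess),
                 converged = max(tab$psrf) <= psrf_max &&
                   min(tab$ess) >= ess_min),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "convergence: max PSRF = %.3f, min ESS = %.0f (%d parameters) -> %s\n",
    x$max_psrf, x$min_ess, nrow(x$table),
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
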