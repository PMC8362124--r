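#' Residual association matrix at a given water deficit
#'
#' Forms the loading covariance at water deficit `cwd` (mm),
#' \eqn{\Omega_{j_1 j_2} = \sum_h (\lambda_{j_1 h} + \lambda^{CWD}_{j_1 h} c)
#' (\lambda_{j_2 h} + \lambda^{CWD}_{j_2 h} c)} with \eqn{c} the
#' standardized deficit, and normalizes it to a correlation matrix
#' \eqn{R_{j_1 j_2} = \Omega_{j_1 j_2} / \sqrt{\Omega_{j_1 j_1}
#' \Omega_{j_2 j_2}}}. A species whose total loading vanishes at this
#' deficit has no defined residual correlation: its row and column are
#' returned as `NA` (never silently zero).
#'
#' @param lambda,lambda_cwd Species x factors loading matrices.
#' @param cwd Water-deficit value in mm.
#' @param scaling List with `center` and `scale` mapping mm to the
#'   standardized scale used inside the model (defaults leave `cwd`
#'   untransformed).
#' @param return_omega Also return the covariance matrix.
#' @return Correlation matrix (species x species), or a list
#'   `list(R, Omega)` when `return_omega` is `TRUE`.
#' @export
association_matrix <- function(lambda, lambda_cwd, cwd,
                               scaling = list(center = 0, scale = 1),
                               return_omega = FALSE) {
  lambda <- as.matrix(lambda); lambda_cwd <- as.matrix(lambda_cwd)
  if (!all(dim(lambda) == dim(lambda_cwd)))
    stop("lambda and lambda_cwd must have the same shape", call. = FALSE)
  c_std <- (cwd - scaling$center) / scaling$scale
  L <- lambda + lambda_cwd * c_std
  Omega <- tcrossprod(L)
  d <- sqrt(diag(Omega))
  R <- Omega / outer(d, d)
  diag(R) <- 1
  zero <- d == 0
  if (any(zero)) {
    R[zero, ] <- NA_real_
    R[, zero] <- NA_real_
  }
  if (return_omega) list(R = R, Omega = Omega) else R
}

#' Posterior of residual associations at chosen water-deficit values
#'
#' Applies [association_matrix()] to every retained posterior draw at each
#' requested water-deficit value.
#'
#' @param fit A `cdjsdm_fit` with at least one latent factor.
#' @param cwd_values Evaluation points in mm (within or near the fitted
#'   gradient).
#' @return Object of class `association_posterior`: array `R` of dimension
#'   draws x cwd-points x species x species, plus `cwd_values` and
#'   `species_ids`.
#' @export
association_posterior <- function(fit, cwd_values) {
  stopifnot(inherits(fit, "cdjsdm_fit"))
  n_draws <- dim(fit$lambda)[1]
  if (n_draws == 0) stop("empty draw set", call. = FALSE)
  k <- dim(fit$lambda)[3]
  if (k == 0)
    stop("model has no latent factors; associations are undefined",
         call. = FALSE)
  S <- dim(fit$lambda)[2]
  sc <- list(center = fit$scaling$cwd_center, scale = fit$scaling$cwd_scale)
  R <- array(NA_real_, c(n_draws, length(cwd_values), S, S))
  for (d in seq_len(n_draws)) {
    L0 <- matrix(fit$lambda[d, , ], S, k)
    Lc <- matrix(fit$lambda_cwd[d, , ], S, k)
    for (w in seq_along(cwd_values))
      R[d, w, , ] <- association_matrix(L0, Lc, cwd_values[w], sc)
  }
  structure(list(R = R, cwd_values = as.numeric(cwd_values),
                 species_ids = fit$species_ids),
            class = "association_posterior")
}

#' @export
print.association_posterior <- function(x, ...) {
  cat("association_posterior:", dim(x$R)[1], "draws x",
      length(x$cwd_values), "CWD points x", dim(x$R)[3], "species\n")
  invisible(x)
}

match_cwd <- function(assoc, cwd) {
  w <- which(abs(assoc$cwd_values - cwd) < 1e-8)
  if (!length(w))
    stop(sprintf("CWD value %g mm is not among the evaluated points", cwd),
         call. = FALSE)
  w[1]
}

#' Classify pairwise association shifts between wet and dry anchors
#'
#' For each unordered species pair, the probability of the residual
#' association being higher at the dry than at the wet anchor is the
#' fraction of posterior draws with \eqn{R_{dry} > R_{wet}} (exact ties
#' count one half). The shift is classified `positive` when that
#' probability exceeds `upper` (default .95), `negative` below `lower`
#' (default .05), and `none` otherwise.
#'
#' @param assoc An [association_posterior()] containing both anchors.
#' @param cwd_wet,cwd_dry Anchor water-deficit values in mm (wet < dry).
#' @param upper,lower Classification thresholds on
#'   \eqn{\Pr(R_{dry} > R_{wet})}.
#' @return Data frame of class `shift_table`: `species_1`, `species_2`,
#'   `pr_dry_gt_wet`, `shift` (factor positive/negative/none),
#'   `mean_R_wet`, `mean_R_dry`.
#' @export
classify_shift <- function(assoc, cwd_wet, cwd_dry,
                           upper = 0.95, lower = 0.05) {
  stopifnot(inherits(assoc, "association_posterior"))
  if (upper <= lower)
    stop("`upper` must exceed `lower`", call. = FALSE)
  iw <- match_cwd(assoc, cwd_wet); id <- match_cwd(assoc, cwd_dry)
  S <- dim(assoc$R)[3]
  pairs <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    j1 <- pairs[r, 1]; j2 <- pairs[r, 2]
    rw <- assoc$R[, iw, j1, j2]; rd <- assoc$R[, id, j1, j2]
    ok <- is.finite(rw) & is.finite(rd)
    if (!any(ok))
      return(data.frame(species_1 = assoc$species_ids[j1],
                        species_2 = assoc$species_ids[j2],
                        pr_dry_gt_wet = NA_real_, shift = NA_character_,
                        mean_R_wet = NA_real_, mean_R_dry = NA_real_))
    d <- rd[ok] - rw[ok]
    pr <- mean(d > 0) + 0.5 * mean(d == 0)
    cls <- if (pr > upper) "positive" else if (pr < lower) "negative"
           else "none"
    data.frame(species_1 = assoc$species_ids[j1],
               species_2 = assoc$species_ids[j2],
               pr_dry_gt_wet = pr, shift = cls,
               mean_R_wet = mean(rw[ok]), mean_R_dry = mean(rd[ok]))
  })
  tab <- do.call(rbind, out)
  tab$shift <- factor(tab$shift, levels = c("positive", "negative", "none"))
  class(tab) <- c("shift_table", "data.frame")
  attr(tab, "cwd_wet") <- cwd_wet
  attr(tab, "cwd_dry") <- cwd_dry
  tab
}

#' Empirical water-deficit percentiles over plots
#'
#' Linear interpolation between order statistics (the default quantile
#' convention, type 7).
#'
#' @param data A `community_dataset` (or numeric cwd vector).
#' @param probs Probabilities in \[0, 1\].
#' @return Named vector of water-deficit values (mm).
#' @export
cwd_percentiles <- function(data, probs = c(0.25, 0.75)) {
  cwd <- if (inherits(data, "community_dataset")) data$cwd else
    as.numeric(data)
  if (!length(cwd)) stop("empty cwd vector", call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("probs must lie in [0, 1]", call. = FALSE)
  quantile(cwd, probs = probs, type = 7)
}

#' Drought-tolerance groups from Ellenberg moisture values
#'
#' Standard cutoffs classify E_m <= 3 as drought tolerant and E_m >= 5 as
#' drought sensitive; the stringent preset restricts to drought
#' specialists (E_m <= 2.5) and highly drought-sensitive species
#' (E_m >= 5.5). Missing values are `unclassified`.
#'
#' @param traits Numeric vector of E_m values (names kept).
#' @param preset `"standard"` (3/5) or `"stringent"` (2.5/5.5), or supply
#'   `cutoffs` directly.
#' @param cutoffs Length-2 vector `c(tolerant_max, sensitive_min)`.
#' @return Factor with levels `drought_tolerant`, `intermediate`,
#'   `drought_sensitive`, `unclassified`, with the cutoffs stored as an
#'   attribute.
#' @export
classify_tolerance <- function(traits, preset = c("standard", "stringent"),
                               cutoffs = NULL) {
  preset <- match.arg(preset)
  if (is.null(cutoffs))
    cutoffs <- if (preset == "standard") c(3, 5) else c(2.5, 5.5)
  if (cutoffs[1] >= cutoffs[2])
    stop("tolerant cutoff must lie below sensitive cutoff", call. = FALSE)
  g <- rep("unclassified", length(traits))
  known <- !is.na(traits)
  g[known & traits <= cutoffs[1]] <- "drought_tolerant"
  g[known & traits >= cutoffs[2]] <- "drought_sensitive"
  g[known & traits > cutoffs[1] & traits < cutoffs[2]] <- "intermediate"
  out <- factor(g, levels = c("drought_tolerant", "intermediate",
                              "drought_sensitive", "unclassified"))
  names(out) <- names(traits)
  attr(out, "cutoffs") <- cutoffs
  out
}

#' Significant associations at a water-deficit value
#'
#' A pair counts as significantly positive (+1) when the equal-tailed
#' credible interval of its residual association lies entirely above zero,
#' significantly negative (-1) when entirely below, and 0 otherwise.
#'
#' @param assoc An [association_posterior()].
#' @param cwd Evaluation point (must be among `assoc$cwd_values`).
#' @param ci Credible level (default 0.95, i.e. the 2.5/97.5 percent
#'   quantiles).
#' @return Symmetric species x species matrix with entries -1/0/+1 (`NA`
#'   where the correlation is undefined in every draw).
#' @export
significant_associations <- function(assoc, cwd, ci = 0.95) {
  stopifnot(inherits(assoc, "association_posterior"))
  w <- match_cwd(assoc, cwd)
  S <- dim(assoc$R)[3]
  alpha <- (1 - ci) / 2
  sig <- matrix(0, S, S,
                dimnames = list(assoc$species_ids, assoc$species_ids))
  for (j1 in seq_len(S - 1))
    for (j2 in (j1 + 1):S) {
      rs <- assoc$R[, w, j1, j2]
      rs <- rs[is.finite(rs)]
      if (!length(rs)) {
        sig[j1, j2] <- sig[j2, j1] <- NA_real_
        next
      }
      q <- quantile(rs, c(alpha, 1 - alpha), type = 7)
      val <- if (q[1] > 0) 1 else if (q[2] < 0) -1 else 0
      sig[j1, j2] <- sig[j2, j1] <- val
    }
  diag(sig) <- NA_real_
  sig
}

CA_COMBINATIONS <- c("overall_DS", "overall_DT", "DS_DS", "DS_DT", "DT_DT",
                     "DT_intermediate", "DS_intermediate")

pair_in_combination <- function(g1, g2, combination) {
  DS <- "drought_sensitive"; DT <- "drought_tolerant"; IT <- "intermediate"
  switch(combination,
    overall_DS = g1 == DS | g2 == DS,
    overall_DT = g1 == DT | g2 == DT,
    DS_DS = g1 == DS & g2 == DS,
    DT_DT = g1 == DT & g2 == DT,
    DS_DT = (g1 == DS & g2 == DT) | (g1 == DT & g2 == DS),
    DT_intermediate = (g1 == DT & g2 == IT) | (g1 == IT & g2 == DT),
    DS_intermediate = (g1 == DS & g2 == IT) | (g1 == IT & g2 == DS),
    stop("unknown group combination: ", combination, call. = FALSE))
}

#' Community association for a species-group combination
#'
#' \eqn{CA = (N_{+} - N_{-}) / (N_{+} + N_{-})} over the unordered species
#' pairs matching the combination, counting only significant associations
#' (nonzero entries of `signed`). The `overall_*` combinations take every
#' pair with at least one member in the focal group, any partner; the
#' two-group combinations require one member in each named group. When no
#' significant association exists the value is undefined and flagged, not
#' fabricated.
#'
#' @param signed Symmetric -1/0/+1 matrix from
#'   [significant_associations()].
#' @param groups Factor from [classify_tolerance()], aligned with the
#'   matrix rows.
#' @param combination One of `"overall_DS"`, `"overall_DT"`, `"DS_DS"`,
#'   `"DS_DT"`, `"DT_DT"`, `"DT_intermediate"`, `"DS_intermediate"`.
#' @return List: `ca`, `n_positive`, `n_negative`, `defined`.
#' @export
community_association <- function(signed, groups, combination) {
  combination <- match.arg(combination, CA_COMBINATIONS)
  S <- nrow(signed)
  stopifnot(length(groups) == S)
  g <- as.character(groups)
  idx <- which(upper.tri(signed), arr.ind = TRUE)
  keep <- pair_in_combination(g[idx[, 1]], g[idx[, 2]], combination)
  vals <- signed[idx][keep]
  vals <- vals[!is.na(vals)]
  np <- sum(vals == 1); nn <- sum(vals == -1)
  if (np + nn == 0)
    return(list(ca = NA_real_, n_positive = 0L, n_negative = 0L,
                defined = FALSE))
  list(ca = (np - nn) / (np + nn), n_positive = np, n_negative = nn,
       defined = TRUE)
}

#' Community-association profile along the water-deficit gradient
#'
#' Evaluates [community_association()] on a grid of water-deficit values.
#' The point estimate uses the credible-interval-filtered significance
#' classification (pairs whose 95 percent CI excludes zero); posterior
#' uncertainty bands come from the draw-wise CA distribution, where each
#' draw contributes the sign of every defined pairwise correlation.
#'
#' @param fit A `cdjsdm_fit`.
#' @param groups Factor from [classify_tolerance()].
#' @param cwd_grid Water-deficit grid (mm), at least 2 points; when `NULL`
#'   a 50-point grid over the observed range of `data$cwd`.
#' @param data Optional `community_dataset` (required when `cwd_grid` is
#'   `NULL`).
#' @param combinations Which group combinations to evaluate.
#' @param ci Credible level for significance filtering and bands.
#' @return Data frame of class `ca_profile`: `cwd`, `combination`, `ca`
#'   (CI-filtered point estimate), `ca_draw_mean` (posterior mean of the
#'   draw-wise CA), `lower`, `upper` (draw-wise band), `n_positive`,
#'   `n_negative`, `defined`.
#' @export
ca_profile <- function(fit, groups, cwd_grid = NULL, data = NULL,
                       combinations = CA_COMBINATIONS, ci = 0.95) {
  stopifnot(inherits(fit, "cdjsdm_fit"))
  if (is.null(cwd_grid)) {
    if (is.null(data))
      stop("supply either cwd_grid or data", call. = FALSE)
    cwd_grid <- seq(min(data$cwd), max(data$cwd), length.out = 50)
  }
  if (length(cwd_grid) < 2)
    stop("cwd_grid needs at least 2 points", call. = FALSE)
  combinations <- match.arg(combinations, CA_COMBINATIONS,
                            several.ok = TRUE)
  alpha <- (1 - ci) / 2
  rows <- list()
  for (w in cwd_grid) {
    assoc_w <- association_posterior(fit, w)  # streams one point at a time
    sig <- significant_associations(assoc_w, w, ci)
    # draw-wise CA per combination
    n_draws <- dim(assoc_w$R)[1]
    for (comb in combinations) {
      point <- community_association(sig, groups, comb)
      ca_d <- vapply(seq_len(n_draws), function(d) {
        sgn <- sign(assoc_w$R[d, 1, , ])
        community_association(sgn, groups, comb)$ca
      }, 0)
      band <- if (all(is.na(ca_d))) c(NA_real_, NA_real_) else
        quantile(ca_d, c(alpha, 1 - alpha), na.rm = TRUE, type = 7)
      rows[[length(rows) + 1]] <- data.frame(
        cwd = w, combination = comb, ca = point$ca,
        ca_draw_mean = mean(ca_d, na.rm = TRUE),
        lower = band[1], upper = band[2],
        n_positive = point$n_positive, n_negative = point$n_negative,
        defined = point$defined)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ca_profile", "data.frame")
  out
}

#' Static-versus-dynamic community association contrast
#'
#' \eqn{\Delta CA = CA_{static} - CA}; positive values mean the static
#' (context-independent) model overestimates the prevalence of positive
#' associations relative to the context-dependent model.
#'
#' @param ca_static,ca_dynamic `ca_profile` data frames on the same grid
#'   and combinations (or single numeric CA values).
#' @return Data frame `cwd`, `combination`, `ca_static`, `ca_dynamic`,
#'   `delta_ca` (or a scalar for numeric inputs). Undefined inputs
#'   propagate as `NA`.
#' @export
delta_ca <- function(ca_static, ca_dynamic) {
  if (is.numeric(ca_static) && is.numeric(ca_dynamic))
    return(ca_static - ca_dynamic)
  stopifnot(inherits(ca_static, "ca_profile"),
            inherits(ca_dynamic, "ca_profile"))
  m <- merge(ca_static[, c("cwd", "combination", "ca")],
             ca_dynamic[, c("cwd", "combination", "ca")],
             by = c("cwd", "combination"),
             suffixes = c("_static", "_dynamic"))
  if (nrow(m) == 0)
    stop("profiles share no (cwd, combination) cells", call. = FALSE)
  m$delta_ca <- m$ca_static - m$ca_dynamic
  m[order(m$combination, m$cwd), ]
}

#' Expected group richness along the water-deficit gradient
#'
#' Stacked probability of occurrence: all predictors other than the water
#' deficit are held at their observed median (quadratic columns are
#' recomputed from the medians of their base columns), the water-deficit
#' column sweeps the grid, and per grid point the occurrence probabilities
#' \eqn{\Phi(x'\beta_j)} are summed over the group's species and averaged
#' over posterior draws. Latent factors are excluded: this is richness
#' without species associations.
#'
#' @param fit A `cdjsdm_fit`.
#' @param data The fitted `community_dataset`.
#' @param groups Factor from [classify_tolerance()].
#' @param cwd_grid Water-deficit grid (mm).
#' @param cwd_column Name of the water-deficit column of `data$X`.
#' @return Data frame `cwd`, `group`, `richness`.
#' @export
stacked_richness <- function(fit, data, groups,
                             cwd_grid = seq(min(data$cwd), max(data$cwd),
                                            length.out = 50),
                             cwd_column = "CWD_GS") {
  stopifnot(inherits(fit, "cdjsdm_fit"),
            inherits(data, "community_dataset"))
  X <- data$X
  if (!cwd_column %in% colnames(X))
    stop("column ", cwd_column, " not found in X", call. = FALSE)
  med <- apply(X, 2, median)
  prof <- matrix(rep(med, each = length(cwd_grid)), nrow = length(cwd_grid),
                 dimnames = list(NULL, colnames(X)))
  prof[, cwd_column] <- cwd_grid
  # recompute quadratic columns from their base medians / the grid
  sq <- grep("_sq$", colnames(X), value = TRUE)
  for (s in sq) {
    base <- sub("_sq$", "", s)
    if (base %in% colnames(prof)) prof[, s] <- prof[, base]^2
  }
  Xs <- sweep(sweep(prof, 2, fit$scaling$X_center, "-"),
              2, fit$scaling$X_scale, "/")
  n_draws <- dim(fit$beta)[1]
  S <- dim(fit$beta)[2]; p <- dim(fit$beta)[3]
  probs <- matrix(0, length(cwd_grid), S)
  for (d in seq_len(n_draws)) {
    B <- matrix(fit$beta[d, , ], S, p)
    probs <- probs + pnorm(Xs %*% t(B))
  }
  probs <- probs / n_draws
  lv <- setdiff(levels(groups), "unclassified")
  rows <- lapply(lv, function(g) {
    members <- which(as.character(groups) == g)
    if (!length(members)) {
      warning("group ", g, " has no species; richness reported as 0")
      return(data.frame(cwd = cwd_grid, group = g, richness = 0))
    }
    data.frame(cwd = cwd_grid, group = g,
               richness = rowSums(probs[, members, drop = FALSE]))
  })
  do.call(rbind, rows)
}

#' Residual-versus-deficit diagnostic
#'
#' Computes occurrence residuals against the unconditional predictions,
#' \eqn{r_{ij} = y_{ij} - \hat p_{ij}}, and tests each species' residual
#' vector for Pearson correlation with the water deficit. Under a
#' well-specified model the correlations center on zero; systematic
#' correlation would indicate that association shifts are artefacts of
#' shared absences along the gradient.
#'
#' @param fit A `cdjsdm_fit`.
#' @param data The fitted `community_dataset`.
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()].
#' @return List: `table` (species, correlation, p_value, p_adjusted,
#'   defined) and `summary` (mean correlation, number and proportion
#'   significant at 0.05 after adjustment).
#' @export
residual_cwd_correlation <- function(fit, data, p_adjust = "BH") {
  stopifnot(inherits(fit, "cdjsdm_fit"),
            inherits(data, "community_dataset"))
  P <- predict_unconditional(fit, data$X, data$cwd)
  res <- data$Y - P
  rows <- lapply(seq_len(ncol(res)), function(j) {
    v <- res[, j]
    if (sd(v) == 0)
      return(data.frame(species = data$species_ids[j],
                        correlation = NA_real_, p_value = NA_real_,
                        defined = FALSE))
    ct <- cor.test(v, data$cwd)
    data.frame(species = data$species_ids[j],
               correlation = unname(ct$estimate),
               p_value = ct$p.value, defined = TRUE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- p.adjust(tab$p_value, method = p_adjust)
  n_sig <- sum(tab$p_adjusted < 0.05, na.rm = TRUE)
  list(table = tab,
       summary = list(mean_correlation = mean(tab$correlation, na.rm = TRUE),
                      n_significant = n_sig,
                      prop_significant = n_sig / sum(tab$defined)))
}
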