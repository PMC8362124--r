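need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
}

#' Plot community-association profiles
#'
#' CA against water deficit, one line per group combination, with the
#' draw-wise credible band.
#'
#' @param profile A [ca_profile()] result.
#' @return A ggplot object.
#' @export
plot_ca_profile <- function(profile) {
  need_ggplot()
  stopifnot(inherits(profile, "ca_profile"))
  df <- as.data.frame(profile)
  ggplot2::ggplot(df, ggplot2::aes(x = cwd, y = ca,
                                   colour = combination,
                                   fill = combination)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "CWD_GS (mm)", y = "Community association (CA)") +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::theme_minimal()
}

#' Plot posterior-mean association curves by shift class
#'
#' Mean residual association of each pair as a function of water deficit,
#' panelled by shift class (positive / negative / none).
#'
#' @param fit A `cdjsdm_fit`.
#' @param shifts A [classify_shift()] result.
#' @param cwd_grid Water-deficit grid (mm).
#' @return A ggplot object.
#' @export
plot_shift_curves <- function(fit, shifts,
                              cwd_grid = seq(0, 1100, length.out = 25)) {
  need_ggplot()
  stopifnot(inherits(fit, "cdjsdm_fit"), inherits(shifts, "shift_table"))
  assoc <- association_posterior(fit, cwd_grid)
  Rbar <- apply(assoc$R, c(2, 3, 4), mean)
  rows <- lapply(seq_len(nrow(shifts)), function(r) {
    j1 <- match(shifts$species_1[r], fit$species_ids)
    j2 <- match(shifts$species_2[r], fit$species_ids)
    data.frame(cwd = cwd_grid, R = Rbar[, j1, j2],
               pair = paste(shifts$species_1[r], shifts$species_2[r]),
               shift = shifts$shift[r])
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = cwd, y = R, group = pair)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~shift) +
    ggplot2::labs(x = "CWD_GS (mm)", y = "Residual association R") +
    ggplot2::theme_minimal()
}
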