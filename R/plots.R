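# ggplot2 visualisations of the main result types.

#' Scatter plot of a harmonized instrument set
#'
#' Per-SNP exposure vs outcome effects with error bars and the fitted method
#' slopes (IVW through the origin, MR-Egger with intercept).
#'
#' @param object An `mr_harmonized` set.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_harmonized <- function(object, ...) {
  h <- as_mr_harmonized(object)
  fits <- tibble(
    method = c("IVW", "MR-Egger"),
    slope = c(mr_ivw(h)$estimate, if (nrow(h) >= 3) mr_egger(h)$estimate else NA),
    intercept = c(0, if (nrow(h) >= 3) mr_egger(h)$extras$egger_intercept else NA)
  )
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se_y,
                                        ymax = .data$by + .data$se_y),
                           linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$se_x,
                                         xmax = .data$bx + .data$se_x),
                            linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(
      data = filter(fits, !is.na(.data$slope)),
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)
    ) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of leave-one-out estimates
#'
#' @param object A [leave_one_out()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_loo <- function(object, ...) {
  full <- filter(object, .data$omitted == "none")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimate,
                               y = stats::reorder(.data$omitted, .data$estimate))) +
    ggplot2::geom_vline(xintercept = full$estimate, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper), height = 0.25) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate (SNP omitted)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of proportions mediated
#'
#' @param object A `mediation_estimate` from [decompose_mediation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mediation_estimate <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mediator, y = .data$proportion,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$prop_ci_lower,
                                        ymax = .data$prop_ci_upper),
                           width = 0.2, position = ggplot2::position_dodge(0.9)) +
    ggplot2::labs(x = NULL, y = "Proportion mediated (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the sample-overlap bias approximation
#'
#' Bias and implied type-I error of the IVW estimate as the overlap fraction
#' runs from 0 to 1.
#'
#' @param mean_f,confounded_assoc,se_iv,alpha As in [overlap_bias()].
#' @return A ggplot with one panel per quantity.
#' @export
plot_overlap_bias <- function(mean_f, confounded_assoc, se_iv, alpha = 0.05) {
  grid <- overlap_bias(seq(0, 1, by = 0.02), mean_f, confounded_assoc,
                       se_iv, alpha)
  long <- tidyr::pivot_longer(grid, c("bias", "type1"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$overlap_frac, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Overlap fraction", y = NULL) +
    ggplot2::theme_minimal()
}
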