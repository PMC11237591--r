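#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot niche profiles
#'
#' Levins' niche breadth against occurrence frequency, coloured by niche
#' class, with strict taxa emphasised.
#'
#' @param object A [null_classify()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot niche_profiles
#' @export
autoplot.niche_profiles <- function(object, ...) {
  df <- as_tibble(object)
  strict <- if ("class_strict" %in% names(df)) {
    df$class_strict != "opportunist"
  } else rep(FALSE, nrow(df))
  df$strict <- ifelse(strict, "strict", "other")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occ_f, y = .data$levins_b,
                                   colour = .data$class,
                                   alpha = .data$strict)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_alpha_manual(values = c(strict = 1, other = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "Occurrence frequency", y = "Levins' niche breadth B",
                  colour = "Class") +
    ggplot2::theme_minimal()
}

#' @method autoplot distance_decay
#' @export
autoplot.distance_decay <- function(object, ...) {
  df <- tibble(logd = object$lm$model[[2]], logdiss = object$lm$model[[1]])
  ggplot2::ggplot(df, ggplot2::aes(.data$logd, .data$logdiss)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "log(distance + 1)", y = "log(dissimilarity)",
                  title = sprintf("Distance decay%s: slope %.3f, R^2 %.2f",
                                  if (is.na(object$group)) "" else
                                    paste0(" (", object$group, ")"),
                                  object$beta_slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of assembly-process fractions
#'
#' @param summary Output of [summarize_assembly()].
#' @return A ggplot.
#' @export
plot_assembly_summary <- function(summary) {
  summary$process <- factor(summary$process, levels = rev(assembly_processes))
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$group, y = .data$fraction,
                                        fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu") +
    ggplot2::labs(x = NULL, y = "Fraction of sample pairs",
                  fill = "Assembly process") +
    ggplot2::theme_minimal()
}

#' Zi-Pi role plot
#'
#' Within-module vs among-module connectivity with the role thresholds
#' (Zi = 2.5, Pi = 0.62) drawn in.
#'
#' @param roles Output of [zi_pi()].
#' @return A ggplot.
#' @export
plot_zi_pi <- function(roles) {
  ggplot2::ggplot(roles, ggplot2::aes(x = .data$pi, y = .data$zi,
                                      colour = .data$role)) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::geom_hline(yintercept = 2.5, linetype = 2, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0.62, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "Among-module connectivity Pi",
                  y = "Within-module connectivity Zi", colour = "Role") +
    ggplot2::theme_minimal()
}
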