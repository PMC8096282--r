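#' Plot a SHAPE reactivity profile
#'
#' Bar plot of per-position reactivities; when a structure is supplied,
#' bars are coloured by pairing state and missing positions are marked
#' along the axis.
#'
#' @param object A `shape_profile`.
#' @param structure Optional [rna_structure] for pairing-state colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_profile <- function(object, structure = NULL, ...) {
  df <- tibble::tibble(position = seq_along(object),
                       reactivity = as.numeric(object),
                       missing = is.na(object))
  if (!is.null(structure)) {
    df$state <- ifelse(partner_vector(structure) > 0L, "paired", "unpaired")
  } else {
    df$state <- "unknown"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$reactivity,
                                   fill = .data$state)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$missing),
      mapping = ggplot2::aes(x = .data$position, y = 0),
      shape = 4, size = 1, colour = "grey40", inherit.aes = FALSE) +
    ggplot2::labs(x = "position (nt)", y = "SHAPE reactivity",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the class-conditional densities of a posterior model
#'
#' Overlays the fitted true-loop (NIG) and false-loop (Johnson's SU)
#' difference densities, with the posterior probability of the true class
#' as a secondary curve.
#'
#' @param object A `posterior_model`.
#' @param from,to Evaluation range of the difference `D`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.posterior_model <- function(object, from = -2, to = 2, ...) {
  x <- seq(from, to, length.out = 400)
  dens <- dplyr::bind_rows(
    tibble::tibble(d = x, curve = "f_true (NIG)",
                   value = exp(cc_log_density(object$f_true$family,
                                              object$f_true$params, x))),
    tibble::tibble(d = x, curve = "f_false (Johnson SU)",
                   value = exp(cc_log_density(object$f_false$family,
                                              object$f_false$params, x))),
    tibble::tibble(d = x, curve = "posterior P(true | D)",
                   value = posterior_prob(object, x))
  )
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$d, y = .data$value,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "SHAPE difference D (high - low position)",
                  y = "density / probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-loop penalties of a classified structure
#'
#' @param assessments Output of [classify_loops()].
#' @return A ggplot object: penalty per loop, coloured by category.
#' @export
plot_loop_penalties <- function(assessments) {
  df <- dplyr::mutate(assessments,
                      penalty_shown = ifelse(is.na(.data$penalty), 0,
                                             .data$penalty))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$loop_id),
                                   y = .data$penalty_shown,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "loop", y = "penalty", fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot a noise-robustness table
#'
#' @param robustness Output of [robustness_run()].
#' @return A ggplot object: mean sensitivity/PPV/MCC against the shuffle
#'   fraction, with standard-error ribbons.
#' @export
plot_robustness <- function(robustness) {
  long <- tidyr::pivot_longer(
    robustness,
    cols = c("mean_sensitivity", "mean_ppv", "mean_mcc"),
    names_to = "metric", values_to = "mean")
  long$se <- dplyr::case_when(
    long$metric == "mean_sensitivity" ~ robustness$se_sensitivity[
      match(long$fraction, robustness$fraction)],
    long$metric == "mean_ppv" ~ robustness$se_ppv[
      match(long$fraction, robustness$fraction)],
    TRUE ~ robustness$se_mcc[match(long$fraction, robustness$fraction)]
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$mean,
                                     colour = .data$metric,
                                     fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "shuffled fraction of SHAPE data", y = "mean metric",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
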