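#' Plot a healthy-donor noise profile
#'
#' VAF (log scale) against panel position for every artefact call in a donor
#' panel, coloured by ALT_RATIO so strand-biased calls stand out, with a
#' dashed line at the 0.5% noise ceiling.
#'
#' @param object A [noise_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot noise_profile
#' @export
autoplot.noise_profile <- function(object, ...) {
  df <- object$variants
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pos, y = 100 * .data$vaf, colour = .data$alt_ratio
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_gradient(
      low = "firebrick", high = "steelblue", limits = c(0, 0.5),
      name = "ALT_RATIO"
    ) +
    ggplot2::labs(
      x = "panel position (bp)", y = "VAF (%)",
      title = sprintf("Healthy-donor cfDNA noise (%d samples, max VAF %.3g%%)",
                      object$n_samples, 100 * object$max_vaf)
    )
}

#' Plot allele-burden trajectories
#'
#' One line per patient: total TP53 allele burden (% VAF summed over passing
#' variants) against weeks on treatment.
#'
#' @param burden A [burden_series()] tibble.
#' @param detected_only Drop patients never detected (default `TRUE`).
#' @return A ggplot.
#' @export
plot_burden_trajectories <- function(burden, detected_only = TRUE) {
  if (detected_only) {
    keep <- burden |>
      group_by(.data$patient_id) |>
      summarise(any_det = any(.data$detected), .groups = "drop") |>
      filter(.data$any_det)
    burden <- semi_join(burden, keep, by = "patient_id")
  }
  ggplot2::ggplot(burden, ggplot2::aes(
    x = .data$timepoint_weeks, y = .data$burden_pct,
    colour = .data$patient_id, group = .data$patient_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "weeks on treatment", y = "TP53 allele burden (sum VAF, %)",
      colour = "patient"
    )
}

#' Plot the per-patient detection matrix
#'
#' Tile matrix of patients by timepoints, coloured by whether a TP53 mutation
#' was called above the VAF threshold at that timepoint.
#'
#' @param detection A [detect_samples()] tibble.
#' @return A ggplot.
#' @export
plot_detection_matrix <- function(detection) {
  ggplot2::ggplot(detection, ggplot2::aes(
    x = factor(.data$timepoint_weeks), y = .data$patient_id,
    fill = .data$detected
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "darkgreen", `TRUE` = "orange"),
      name = "mutation called"
    ) +
    ggplot2::labs(x = "weeks on treatment", y = "patient")
}

#' Plot CT change against allele burden with the fitted linear-log line
#'
#' @param object A `burden_lm` from [burden_regression()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot burden_lm
#' @export
autoplot.burden_lm <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_burden, y = .data$ct_change)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(
      x = "log10 TP53 allele burden (%)",
      y = "CT change from baseline (%)",
      title = sprintf("slope %.3g (p = %.3g), R^2 = %.3f",
                      object$slope, object$slope_p, object$r_squared)
    )
}
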