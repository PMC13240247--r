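#' Plot an RSF surface
#'
#' Relative probability of use (0-1) as a filled raster, dark (low use) to
#' light (high use).
#'
#' @param object An [apply_rsf()] surface.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rsf_surface <- function(object, ...) {
  g <- object$values
  df <- tidyr::expand_grid(
    y = grid_row_y(g),
    x = grid_col_x(g)
  )
  df$use <- as.vector(t(g$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$use)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s model, %s", object$source_range, object$season),
      x = "Easting (m)", y = "Northing (m)", fill = "Relative\nuse"
    )
}

#' Plot transferability pairs
#'
#' Cell-wise scatterplot of reference vs transferred relative use, with the
#' 1:1 line; tight scatter along the diagonal indicates transferable
#' models.
#'
#' @param object A [compare_surfaces()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transferability_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$reference, .data$transferred)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("%s: %s vs %s (r = %.3f)", object$season,
                      object$reference_range, object$transferred_range,
                      object$pearson_r),
      x = sprintf("%s model", object$reference_range),
      y = sprintf("%s model (transferred)", object$transferred_range)
    )
}

#' Plot ensemble outcome distributions
#'
#' Violin of realized growth rates per scenario with the expected
#' `lambda_bar` (point) and the self-sustainability threshold (dashed
#' line).
#'
#' @param object A [run_ensemble()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.caribou_ensemble <- function(object, ...) {
  lv <- unique(object$draws$scenario)
  draws <- dplyr::mutate(object$draws,
                         scenario = factor(.data$scenario, levels = lv))
  summ <- dplyr::mutate(object$summary,
                        scenario = factor(.data$scenario, levels = lv))
  ggplot2::ggplot(draws,
                  ggplot2::aes(.data$scenario, .data$realized_lambda)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_point(data = summ,
                        ggplot2::aes(y = .data$lambda_bar), size = 2) +
    ggplot2::geom_hline(
      yintercept = object$options$self_sustaining_threshold, linetype = 2
    ) +
    ggplot2::labs(x = NULL, y = expression(lambda),
                  title = "Realized population growth by scenario")
}

#' Plot population rate trajectories over disturbance
#'
#' Quantile-persistent survival (or recruitment) trajectories of sample
#' populations across a disturbance gradient; trajectories never cross
#' because each population keeps its quantile.
#'
#' @param model A [demographic_model()].
#' @param anthro_grid Disturbance values (percent) to sweep.
#' @param quantiles A [sample_population_quantiles()] tibble (e.g., 25
#'   populations).
#' @param rate `"survival"` or `"recruitment"`.
#' @return A ggplot.
#' @export
plot_rate_trajectories <- function(model, anthro_grid = seq(0, 50, 2.5),
                                   quantiles = sample_population_quantiles(25),
                                   rate = c("survival", "recruitment")) {
  rate <- match.arg(rate)
  df <- purrr::map_dfr(anthro_grid, function(a) {
    r <- rates_at_quantile(model, disturbance_covariates(a), quantiles)
    dplyr::mutate(r, anthro = a)
  })
  df$value <- if (rate == "survival") df$S else df$R * 100
  ggplot2::ggplot(df, ggplot2::aes(.data$anthro, .data$value,
                                   group = .data$population_id,
                                   colour = .data$population_id)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(
      x = "Anthropogenic disturbance (%, buffered 500 m)",
      y = if (rate == "survival") "Adult female survival" else
        "Recruitment (calves per 100 cows)"
    )
}
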