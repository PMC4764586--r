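#' Plot an ensemble MSD curve
#'
#' MSD against lag with standard-error bars (per-track SEM).
#'
#' @param object A `msd_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$msd - .data$sem,
                                        ymax = .data$msd + .data$sem),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_classic()
}

#' Plot a displacement-CDF fit over the empirical CDF
#'
#' @param object A `cdf_fit` object.
#' @param d The displacement set the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdf_fit
#' @export
autoplot.cdf_fit <- function(object, d, ...) {
  r <- sort(d$r)
  emp <- tibble::tibble(r = r, p = seq_along(r) / length(r))
  rr <- seq(0, max(r), length.out = 400)
  mod <- tibble::tibble(r = rr, p = if (object$n_components == 1)
    cdf_one_model(rr, object$D_app, object$lag)
    else cdf_two_model(rr, object$A, object$D_slow, object$D_fast, object$lag))
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$r, y = .data$p)) +
    ggplot2::geom_step() +
    ggplot2::geom_line(data = mod, colour = "red", linetype = "dashed") +
    ggplot2::labs(x = expression(r ~ (mu * m)), y = "P(displacement <= r)") +
    ggplot2::theme_classic()
}

#' Plot a local-diffusion heat map
#'
#' Undefined nodes (fewer than the minimum displacement count) are simply
#' absent, i.e. transparent.
#'
#' @param object A `diffusion_map` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffusion_map
#' @export
autoplot.diffusion_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$node_x, y = .data$node_y,
                               fill = .data$D)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(D[app] ~ (mu * m^2 / s))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m))) +
    ggplot2::theme_classic()
}

#' Plot a localization density map
#'
#' @param object A `density_map` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot density_map
#' @export
autoplot.density_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin_x, y = .data$bin_y,
                               fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "magma", name = "localizations") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m))) +
    ggplot2::theme_classic()
}

#' Plot an area-normalized distance distribution
#'
#' Under channel independence the normalized density is flat; colocalization
#' shows as a short-distance peak.
#'
#' @param object A `distance_distribution` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_distribution
#' @export
autoplot.distance_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r_mid, y = .data$density)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "grey60") +
    ggplot2::labs(x = expression(d[mRNA - Ribo] ~ (mu * m)),
                  y = expression(density ~ (counts / mu * m^2))) +
    ggplot2::theme_classic()
}

#' Map trajectories coloured by annotated motion state
#'
#' Draws each track as a polyline whose segments are coloured by the Viterbi
#' state of the step, optionally over a compartment mask.
#'
#' @param tracks Track tibble.
#' @param annotation An [annotate_states()] result.
#' @param mask Optional `compartment_mask` drawn underneath.
#' @return A ggplot object.
#' @export
plot_state_tracks <- function(tracks, annotation, mask = NULL) {
  segs <- tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(xend = dplyr::lead(.data$x_um),
                  yend = dplyr::lead(.data$y_um)) |>
    dplyr::ungroup() |>
    dplyr::inner_join(annotation$steps, by = c("track_id", "frame")) |>
    dplyr::filter(!is.na(.data$xend))
  p <- ggplot2::ggplot()
  if (!is.null(mask)) {
    ps <- mask$pixel_size
    idx <- which(mask$mask > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      mm <- tibble::tibble(x = (idx[, 2] - 0.5) * ps, y = (idx[, 1] - 0.5) * ps)
      p <- p + ggplot2::geom_raster(data = mm,
                                    ggplot2::aes(x = .data$x, y = .data$y),
                                    fill = "grey20")
    }
  }
  p +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x_um, y = .data$y_um,
                   xend = .data$xend, yend = .data$yend,
                   colour = factor(.data$state))) +
    ggplot2::scale_colour_manual(values = c("1" = "#2166AC", "2" = "#1B7837"),
                                 name = "state",
                                 labels = c("1" = "fast (D1)", "2" = "slow (D2)")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(x ~ (mu * m)), y = expression(y ~ (mu * m))) +
    ggplot2::theme_classic()
}
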