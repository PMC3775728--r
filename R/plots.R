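raster_df <- function(m) {
  tibble::tibble(
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    value = as.vector(m))
}

#' Plot a CBV map
#'
#' Raster display of one coronal CBV slice; vessel-excluded voxels, if the
#' exclusion layer is present, are overdrawn in grey.
#'
#' @param object A [cbv_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cbv_map
#' @export
autoplot.cbv_map <- function(object, ...) {
  df <- raster_df(object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "CBV\n(ml/100 g)", option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("CBV map, animal %s, bregma %g mm",
                                  object$animal_id, object$bregma_level),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(object$excluded) && any(object$excluded)) {
    ex <- raster_df(object$excluded)
    ex <- ex[ex$value > 0, ]
    p <- p + ggplot2::geom_raster(data = ex, fill = "grey70")
  }
  p
}

#' Plot an infarct probability map
#'
#' Displays the stacked-tracing rendering (each animal's trace composited at
#' the configured opacity); lighter regions are more commonly infarcted.
#'
#' @param object An `infarct_probability_map` from [probability_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot infarct_probability_map
#' @export
autoplot.infarct_probability_map <- function(object, ...) {
  df <- raster_df(object$rendering)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = "stacked\nopacity") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Infarct probability, n = %d, bregma %g mm",
                                  object$n, object$level)) +
    ggplot2::theme_void()
}

#' Group infarct-volume plot
#'
#' Jittered per-animal corrected infarct volumes by occlusion-duration group,
#' coloured by AChAo status, with group-mean crossbars.
#'
#' @param data Cohort tibble with `group`, `acha_occluded` and the volume
#'   column.
#' @param volume_col Volume column to plot.
#' @return A ggplot.
#' @export
plot_group_volumes <- function(data, volume_col = "infarct_volume_total") {
  data$group <- factor(data$group, levels = c("1h", "2h", "permanent"))
  ggplot2::ggplot(data, ggplot2::aes(.data$group, .data[[volume_col]],
                                     colour = .data$acha_occluded)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = "occlusion duration", y = "infarct volume (mm³)",
                  colour = "AChA occluded") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
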