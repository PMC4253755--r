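#' Plot a volume-time curve, optionally with ED/ES markers
#'
#' @param object An `lv_volume_curve`.
#' @param detection Optional `lv_cycles` whose ED/ES frames are highlighted.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lv_volume_curve <- function(object, detection = NULL, ...) {
  p <- ggplot(object, aes(x = .data$time_s, y = .data$volume_ml)) +
    geom_line(color = "grey30") +
    geom_point(size = 0.8, color = "grey30") +
    labs(x = "time (s)", y = "LV volume (mL)")
  if (!is.null(detection)) {
    marks <- bind_rows(
      tibble(frame = detection$ed_frames, label = "ED"),
      tibble(frame = detection$es_frames, label = "ES")
    )
    marks <- dplyr::left_join(marks, object, by = "frame")
    p <- p +
      geom_point(data = marks, aes(color = .data$label), size = 2.5) +
      scale_color_manual(values = c(ED = "#c0392b", ES = "#2980b9"), name = NULL)
  }
  p
}

#' Plot a frame with one or more contours overlaid
#'
#' @param frame Intensity matrix.
#' @param ... Contours (each drawn as a closed path).
#' @param labels Optional legend labels, one per contour.
#' @return A ggplot.
#' @export
plot_frame_contours <- function(frame, ..., labels = NULL) {
  contours <- list(...)
  img <- tibble(
    x = rep(seq_len(ncol(frame)), each = nrow(frame)),
    y = rep(seq_len(nrow(frame)), ncol(frame)),
    value = as.numeric(frame)
  )
  p <- ggplot() +
    geom_raster(data = img, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    scale_y_reverse() +
    coord_fixed() +
    theme_void()
  if (length(contours) > 0) {
    if (is.null(labels)) labels <- paste("contour", seq_along(contours))
    paths <- bind_rows(lapply(seq_along(contours), function(i) {
      cc <- as_contour(contours[[i]])
      tibble(x = c(cc$x, cc$x[1]), y = c(cc$y, cc$y[1]), which = labels[i])
    }))
    p <- p + geom_path(
      data = paths,
      aes(x = .data$x, y = .data$y, color = .data$which),
      linewidth = 0.7
    ) +
      scale_color_brewer(palette = "Set1", name = NULL)
  }
  p
}

#' Agreement plots: regression and Bland-Altman panels
#'
#' @param object An `lv_agreement`.
#' @param type `"both"` (side by side, needs patchwork), `"regression"` or
#'   `"bland_altman"`.
#' @param ... Unused.
#' @return A ggplot (or patchwork for `type = "both"`).
#' @export
autoplot.lv_agreement <- function(object,
                                  type = c("both", "regression", "bland_altman"),
                                  ...) {
  type <- match.arg(type)
  if (type == "both" && !requireNamespace("patchwork", quietly = TRUE)) {
    type <- "bland_altman"
  }
  d <- object$data
  p_reg <- ggplot(d, aes(x = .data$reference, y = .data$estimated)) +
    geom_abline(slope = 1, intercept = 0, linetype = 3, color = "grey60") +
    geom_point(alpha = 0.7) +
    geom_abline(
      slope = object$regression$slope,
      intercept = object$regression$intercept, color = "#c0392b"
    ) +
    labs(
      x = paste("reference", object$label),
      y = paste("estimated", object$label),
      title = sprintf(
        "y = %.2f x + %.2f, r = %.3f",
        object$regression$slope, object$regression$intercept,
        object$regression$pearson_r
      )
    )
  ba <- object$bland_altman
  dd <- tibble(
    mean = (d$estimated + d$reference) / 2,
    diff = d$estimated - d$reference
  )
  p_ba <- ggplot(dd, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = ba$bias, color = "#c0392b") +
    geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
               linetype = 2, color = "#2980b9") +
    labs(
      x = paste("mean of methods,", object$label),
      y = paste("difference,", object$label),
      title = sprintf("bias %.2f, LoA [%.2f, %.2f]",
                      ba$bias, ba$loa_low, ba$loa_high)
    )
  switch(type,
    regression = p_reg,
    bland_altman = p_ba,
    both = patchwork::wrap_plots(p_reg, p_ba)
  )
}
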