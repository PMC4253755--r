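#' Analyze per-frame contours into a volume curve and cardiac indices
#'
#' The analysis half of the pipeline: disk-summation volumes per frame,
#' optional moving-average smoothing, ED/ES detection from per-cycle volume
#' extrema, and cardiac-function indices.
#'
#' @param contours List of contours, one per frame.
#' @param pixel_spacing mm per pixel.
#' @param frame_rate Hz.
#' @param n_cycles_hint Expected number of cycles in the clip.
#' @param n_disks Disks for the volume rule.
#' @param smoothing_window Odd moving-average window for [smooth_curve()]
#'   applied before detection (1 = off).
#' @param median_window Running-median prefilter passed to [detect_ed_es()];
#'   the pipeline defaults to 3 because volumes measured from speckled frames
#'   jitter by a few mL, which median filtering suppresses without moving
#'   plateau onsets.
#' @param hr_bpm Optional heart-rate override for [cardiac_indices()].
#' @return A list of class `lv_analysis`: `curve` (`lv_volume_curve`),
#'   `detection` (`lv_cycles`), `indices` (`lv_indices`, per cycle),
#'   `summary` (one-row tibble averaging cycles).
#' @export
analyze_contours <- function(contours, pixel_spacing, frame_rate,
                             n_cycles_hint = 1, n_disks = 20,
                             smoothing_window = 1, median_window = 3,
                             hr_bpm = NULL) {
  curve <- build_curve(contours, pixel_spacing, frame_rate, n_disks)
  det_curve <- smooth_curve(curve, smoothing_window)
  detection <- detect_ed_es(det_curve, n_cycles_hint,
                            median_window = median_window)
  indices <- cardiac_indices(curve, detection, hr_bpm = hr_bpm)
  structure(
    list(
      curve = curve,
      detection = detection,
      indices = indices,
      summary = glance(indices)
    ),
    class = "lv_analysis"
  )
}

#' @export
print.lv_analysis <- function(x, ...) {
  print(x$detection)
  s <- x$summary
  cat(sprintf(
    "  mean over %d cycle(s): EDV %.1f mL, ESV %.1f mL, SV %.1f mL, EF %.2f%%, HR %.1f bpm, CO %.0f mL/min\n",
    s$n_cycles, s$edv_ml, s$esv_ml, s$sv_ml, s$ef_percent, s$hr_bpm,
    s$co_ml_per_min
  ))
  invisible(x)
}

#' Segment and analyze a whole sequence in one call
#'
#' Convenience wrapper: [segment_sequence()] then [analyze_contours()].
#'
#' @param seq An `lv_sequence`.
#' @param seed `c(x, y)` seed point inside the cavity of frame 1.
#' @param params [level_set_params()].
#' @inheritParams analyze_contours
#' @return An `lv_analysis` (see [analyze_contours()]), with the contour list
#'   attached as `contours`.
#' @export
analyze_sequence <- function(seq, seed, params = level_set_params(),
                             n_cycles_hint = 1, n_disks = 20,
                             smoothing_window = 1, median_window = 3,
                             hr_bpm = NULL) {
  contours <- segment_sequence(seq, seed, params)
  out <- analyze_contours(
    contours,
    pixel_spacing = seq$pixel_spacing, frame_rate = seq$frame_rate,
    n_cycles_hint = n_cycles_hint, n_disks = n_disks,
    smoothing_window = smoothing_window, median_window = median_window,
    hr_bpm = hr_bpm
  )
  out$contours <- contours
  out
}
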