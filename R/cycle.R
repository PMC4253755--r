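#' Build the LV volume-time curve from per-frame contours
#'
#' Each contour is converted to a volume with [disk_volume()]; frame i is
#' stamped at time (i - 1) / frame_rate.
#'
#' @param contours List of contours, one per frame (e.g. from
#'   [segment_sequence()]).
#' @param pixel_spacing mm per pixel.
#' @param frame_rate Hz.
#' @param n_disks Disks used in the volume rule.
#' @return A tibble of class `lv_volume_curve` with columns `frame`, `time_s`,
#'   `volume_ml` and attributes `frame_rate`, `pixel_spacing`.
#' @export
build_curve <- function(contours, pixel_spacing, frame_rate, n_disks = 20) {
  if (length(contours) < 2) abort("need at least 2 contours")
  if (frame_rate <= 0) abort("frame_rate must be positive")
  vols <- vapply(seq_along(contours), function(i) {
    tryCatch(
      disk_volume(contours[[i]], pixel_spacing, n_disks)$volume_ml,
      error = function(e) {
        abort(sprintf("degenerate contour at frame %d: %s", i, conditionMessage(e)))
      }
    )
  }, numeric(1))
  out <- tibble(
    frame = seq_along(contours),
    time_s = (seq_along(contours) - 1) / frame_rate,
    volume_ml = vols
  )
  attr(out, "frame_rate") <- frame_rate
  attr(out, "pixel_spacing") <- pixel_spacing
  class(out) <- c("lv_volume_curve", class(out))
  out
}

# wrap a plain frame/time/volume table as an lv_volume_curve
as_volume_curve <- function(df, frame_rate) {
  out <- as_tibble(df)
  if (!all(c("frame", "time_s", "volume_ml") %in% names(out))) {
    abort("a volume curve needs frame, time_s, volume_ml columns")
  }
  if (any(diff(out$time_s) <= 0)) abort("times must be strictly increasing")
  if (any(out$volume_ml < 0)) abort("volumes must be >= 0")
  attr(out, "frame_rate") <- frame_rate
  class(out) <- unique(c("lv_volume_curve", class(out)))
  out
}

#' Moving-average smoothing of a volume curve
#'
#' Centered moving average with edge truncation (shorter windows at the
#' ends). `window = 1` returns the input unchanged.
#'
#' @param curve An `lv_volume_curve`.
#' @param window Odd window length in frames.
#' @return The smoothed curve (same class and attributes).
#' @export
smooth_curve <- function(curve, window = 1) {
  n <- nrow(curve)
  if (window %% 2 == 0) abort("window must be odd")
  if (window < 1 || window >= n) abort("window must satisfy 1 <= window < n_frames")
  if (window == 1) return(curve)
  half <- (window - 1) / 2
  v <- curve$volume_ml
  curve$volume_ml <- vapply(seq_len(n), function(i) {
    mean(v[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  curve
}

# run-length peak candidates: plateaus resolve to their first frame
find_extrema_runs <- function(v) {
  r <- rle(v)
  starts <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  m <- length(r$values)
  tibble(
    run = seq_len(m),
    idx = as.integer(starts),
    value = r$values,
    length = r$lengths,
    left = c(NA, r$values[-m]),
    right = c(r$values[-1], NA)
  )
}

#' Detect end-diastole and end-systole frames from a volume curve
#'
#' Local maxima of the volume signal are labelled ED, local minima ES.
#' Iso-volumic plateaus resolve to the plateau's first frame. Same-type peaks
#' closer than `0.6 * n_frames / n_cycles_hint` keep only the more extreme
#' one, and strict ED/ES alternation is enforced. A peak sitting on the first
#' or last frame is only admitted when an interior extremum of the opposite
#' type exists, so a strictly monotone curve raises "no complete cycle".
#'
#' @param curve An `lv_volume_curve` (or tibble with `frame`, `time_s`,
#'   `volume_ml`).
#' @param n_cycles_hint Expected number of cardiac cycles (>= 1).
#' @param plateau_tol Flatness tolerance for plateau grouping, as a fraction
#'   of the signal range: frames whose volume lies within
#'   `plateau_tol * range` of a detected extremum and are contiguous with it
#'   are treated as one iso-volumic plateau, resolved to its first frame.
#'   0 requires exact equality.
#' @param median_window Running-median prefilter width (odd) applied to the
#'   volume signal before peak finding; medians suppress speckle-induced
#'   volume jitter while preserving flat plateaus and their onsets exactly.
#'   1 (the default) disables the prefilter, so single-frame extrema are kept
#'   exactly; the segmentation pipeline ([analyze_contours()]) turns it on.
#' @return A list of class `lv_cycles`: `ed_frames`, `es_frames`,
#'   `cycle_spans` (tibble `start`, `end`, half-open frame spans).
#' @export
detect_ed_es <- function(curve, n_cycles_hint = 1, plateau_tol = 0.015,
                         median_window = 1) {
  v <- curve$volume_ml
  n <- length(v)
  if (n < 8) abort("need at least 8 frames")
  if (n_cycles_hint < 1) abort("n_cycles_hint must be >= 1")
  if (median_window %% 2 == 0) abort("median_window must be odd")
  if (median_window > 1) {
    v <- as.numeric(stats::runmed(v, median_window, endrule = "keep"))
  }
  runs <- find_extrema_runs(v)
  m <- nrow(runs)
  interior <- runs[-c(1, m), , drop = FALSE]
  int_max <- interior[interior$value > interior$left & interior$value > interior$right, ]
  int_min <- interior[interior$value < interior$left & interior$value < interior$right, ]
  peaks <- bind_rows(
    if (nrow(int_max)) tibble(idx = int_max$idx, value = int_max$value, type = "ED"),
    if (nrow(int_min)) tibble(idx = int_min$idx, value = int_min$value, type = "ES")
  )
  # boundary runs: admitted only when (a) an interior extremum of the
  # opposite type exists (rules out strictly monotone curves) and (b) the
  # boundary value is within 10% of the signal range of the global extremum
  # of its type (rules out clips truncated mid-ejection / mid-filling)
  if (m >= 2) {
    tol <- 0.10 * diff(range(v))
    for (j in c(1L, m)) {
      nb <- if (j == 1L) runs$value[2] else runs$value[m - 1]
      cand_type <- if (runs$value[j] > nb) "ED" else "ES"
      opposite <- if (cand_type == "ED") nrow(int_min) > 0 else nrow(int_max) > 0
      near_extreme <- if (cand_type == "ED") {
        runs$value[j] >= max(v) - tol
      } else {
        runs$value[j] <= min(v) + tol
      }
      if (opposite && near_extreme) {
        peaks <- bind_rows(peaks, tibble(
          idx = runs$idx[j], value = runs$value[j], type = cand_type
        ))
      }
    }
  }
  if (is.null(peaks) || nrow(peaks) == 0 ||
      !all(c("ED", "ES") %in% peaks$type)) {
    abort("no complete cycle: need at least one volume maximum and one minimum")
  }
  peaks <- dplyr::distinct(arrange(peaks, .data$idx))

  # minimum peak separation per type: keep the more extreme of close pairs
  min_sep <- 0.6 * n / n_cycles_hint
  prune_close <- function(p, better) {
    repeat {
      if (nrow(p) < 2) return(p)
      gaps <- diff(p$idx)
      k <- which(gaps < min_sep)
      if (length(k) == 0) return(p)
      k <- k[1]
      drop <- if (better(p$value[k], p$value[k + 1])) k + 1 else k
      p <- p[-drop, ]
    }
  }
  eds <- prune_close(peaks[peaks$type == "ED", ], `>`)
  ess <- prune_close(peaks[peaks$type == "ES", ], `<`)
  peaks <- arrange(bind_rows(eds, ess), .data$idx)

  # enforce alternation: of consecutive same-type peaks keep the more extreme
  keep <- rep(TRUE, nrow(peaks))
  last <- 1
  for (i in seq_len(nrow(peaks))[-1]) {
    if (peaks$type[i] == peaks$type[last]) {
      better_i <- if (peaks$type[i] == "ED") {
        peaks$value[i] > peaks$value[last]
      } else {
        peaks$value[i] < peaks$value[last]
      }
      if (better_i) keep[last] <- FALSE else keep[i] <- FALSE
      if (better_i) last <- i
    } else {
      last <- i
    }
  }
  peaks <- peaks[keep, ]

  # resolve near-flat plateaus to their first frame: walk left from each peak
  # while the volume stays within plateau_tol of the peak value
  tol_abs <- plateau_tol * diff(range(v))
  peaks$idx <- vapply(seq_len(nrow(peaks)), function(i) {
    j <- peaks$idx[i]
    while (j > 1 && abs(v[j - 1] - peaks$value[i]) <= tol_abs) j <- j - 1L
    as.integer(j)
  }, integer(1))

  ed_all <- peaks$idx[peaks$type == "ED"]
  es_all <- peaks$idx[peaks$type == "ES"]
  ed_vol <- peaks$value[peaks$type == "ED"]
  es_vol <- peaks$value[peaks$type == "ES"]
  # pair each ED with the (lowest-volume) ES that follows it before the next
  # ED; unpaired EDs (typically a trailing boundary peak) are discarded
  ed_frames <- integer(0); es_frames <- integer(0)
  for (k in seq_along(ed_all)) {
    hi <- if (k < length(ed_all)) ed_all[k + 1] else n + 1L
    sel <- which(es_all > ed_all[k] & es_all < hi)
    if (length(sel) >= 1) {
      sel <- sel[which.min(es_vol[sel])]
      if (ed_vol[k] >= es_vol[sel]) {
        ed_frames <- c(ed_frames, ed_all[k])
        es_frames <- c(es_frames, es_all[sel])
      }
    }
  }
  if (length(ed_frames) == 0) {
    abort("no complete cycle: no ED followed by an ES was found")
  }
  # cycle spans run from each paired ED to the next paired ED; the last cycle
  # is assumed to end one past the final frame (clip ends on a cycle boundary)
  spans <- tibble(
    start = as.integer(ed_frames),
    end = as.integer(c(ed_frames[-1], n + 1L))
  )
  structure(
    list(
      ed_frames = as.integer(ed_frames),
      es_frames = as.integer(es_frames),
      cycle_spans = spans
    ),
    class = "lv_cycles"
  )
}

#' @export
print.lv_cycles <- function(x, ...) {
  cat(sprintf(
    "<lv_cycles> %d cycle(s); ED frames: %s; ES frames: %s\n",
    length(x$ed_frames),
    paste(x$ed_frames, collapse = ", "),
    paste(x$es_frames, collapse = ", ")
  ))
  invisible(x)
}

#' Cardiac-function indices per detected cycle
#'
#' Per cycle: EDV = volume at the ED frame, ESV = volume at the ES frame,
#' SV = EDV - ESV, EF = SV / EDV x 100, HR = 60 / cycle duration, CO = SV x HR.
#' A summary row averaging the cycles is available via [glance()].
#'
#' @param curve An `lv_volume_curve`.
#' @param detection An `lv_cycles` from [detect_ed_es()].
#' @param hr_bpm Optional heart-rate override (bpm) for single-cycle clips
#'   whose duration is not fully captured; when given it replaces the
#'   cycle-length-derived HR in HR and CO.
#' @return A tibble of class `lv_indices`, one row per cycle: `cycle`,
#'   `ed_frame`, `es_frame`, `edv_ml`, `esv_ml`, `sv_ml`, `ef_percent`,
#'   `hr_bpm`, `co_ml_per_min`.
#' @export
cardiac_indices <- function(curve, detection, hr_bpm = NULL) {
  v <- curve$volume_ml
  frame_rate <- attr(curve, "frame_rate")
  if (is.null(frame_rate)) frame_rate <- 1 / diff(curve$time_s[1:2])
  ed <- detection$ed_frames
  es <- detection$es_frames
  spans <- detection$cycle_spans
  edv <- v[ed]; esv <- v[es]
  if (any(edv == 0)) abort("EDV is zero: ejection fraction undefined")
  sv <- edv - esv
  dur_s <- (spans$end - spans$start) / frame_rate
  hr <- if (is.null(hr_bpm)) 60 / dur_s else rep(hr_bpm, length(ed))
  out <- tibble(
    cycle = seq_along(ed),
    ed_frame = ed, es_frame = es,
    edv_ml = edv, esv_ml = esv, sv_ml = sv,
    ef_percent = sv / edv * 100,
    hr_bpm = hr,
    co_ml_per_min = sv * hr
  )
  class(out) <- c("lv_indices", class(out))
  out
}

#' Summary (cycle-averaged) cardiac indices
#'
#' @param x An `lv_indices` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the arithmetic mean of each index over
#'   cycles, plus `n_cycles`.
#' @export
glance.lv_indices <- function(x, ...) {
  tibble(
    n_cycles = nrow(x),
    edv_ml = mean(x$edv_ml),
    esv_ml = mean(x$esv_ml),
    sv_ml = mean(x$sv_ml),
    ef_percent = mean(x$ef_percent),
    hr_bpm = mean(x$hr_bpm),
    co_ml_per_min = mean(x$co_ml_per_min)
  )
}
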