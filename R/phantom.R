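#' Parameters for the synthetic beating-ventricle phantom
#'
#' The phantom emulates a single-plane (long-axis) echo view of the left
#' ventricle: a dark blood pool inside brighter myocardium, pulsating along
#' the physiological volume profile of the cardiac cycle, degraded by
#' Gaussian blur and multiplicative speckle. The cavity is an axis-aligned
#' ellipse whose long axis is fixed while the short axis follows the target
#' volume under the prolate-spheroid rule V = (4/3) pi a b^2, so analytic
#' ground-truth contours and volumes exist for every frame.
#'
#' @param grid_height,grid_width Frame size in pixels.
#' @param n_frames Frames per cardiac cycle (>= 8).
#' @param n_cycles Number of cycles in the sequence.
#' @param frame_rate Acquisition rate, Hz.
#' @param pixel_spacing mm per pixel.
#' @param edv_target,esv_target End-diastolic / end-systolic volume, mL.
#' @param cavity_intensity,myocardium_intensity Gray levels in \[0, 1\]; the
#'   blood pool is hypoechoic so `cavity_intensity < myocardium_intensity`.
#' @param speckle_sigma Scale of the multiplicative speckle (>= 0).
#' @param blur_sigma Gaussian point-spread sigma, pixels (>= 0).
#' @param rng_seed Integer seed; all phantom randomness flows from it.
#' @param long_axis_frac Fixed cavity long axis as a fraction of grid height.
#' @param plateau_frac Fraction of the cycle spent in each iso-volumic
#'   plateau (the flat segments at EDV and ESV).
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(grid_height = 128, grid_width = 128,
                           n_frames = 20, n_cycles = 3,
                           frame_rate = 25, pixel_spacing = 1,
                           edv_target = 120, esv_target = 50,
                           cavity_intensity = 0.15,
                           myocardium_intensity = 0.70,
                           speckle_sigma = 0.10, blur_sigma = 1,
                           rng_seed = 42L,
                           long_axis_frac = 0.70, plateau_frac = 0.10) {
  p <- list(
    grid_height = as.integer(grid_height), grid_width = as.integer(grid_width),
    n_frames = as.integer(n_frames), n_cycles = as.integer(n_cycles),
    frame_rate = frame_rate, pixel_spacing = pixel_spacing,
    edv_target = edv_target, esv_target = esv_target,
    cavity_intensity = cavity_intensity,
    myocardium_intensity = myocardium_intensity,
    speckle_sigma = speckle_sigma, blur_sigma = blur_sigma,
    rng_seed = as.integer(rng_seed),
    long_axis_frac = long_axis_frac, plateau_frac = plateau_frac
  )
  if (!(p$edv_target > p$esv_target && p$esv_target > 0)) {
    abort("edv_target > esv_target > 0 is required")
  }
  if (p$n_frames < 8) abort("n_frames must be >= 8")
  if (p$n_cycles < 1) abort("n_cycles must be >= 1")
  if (!(p$cavity_intensity < p$myocardium_intensity)) {
    abort("cavity_intensity must be below myocardium_intensity (blood pool is hypoechoic)")
  }
  if (p$speckle_sigma < 0 || p$blur_sigma < 0) abort("noise scales must be >= 0")
  if (p$frame_rate <= 0 || p$pixel_spacing <= 0) {
    abort("frame_rate and pixel_spacing must be positive")
  }
  if (p$plateau_frac <= 0 || p$plateau_frac > 0.2) {
    abort("plateau_frac must be in (0, 0.2]")
  }
  class(p) <- "phantom_params"
  p
}

# C1 ramp: 0 -> 1 with zero slope at both ends, skewed fast-early
ramp_fast_early <- function(s) {
  u <- pmin(pmax(s, 0), 1)^0.8
  u^2 * (3 - 2 * u)
}

#' Ground-truth volume profile of the phantom cycle
#'
#' Piecewise-smooth periodic volume with the qualitative shape of the
#' ventricular volume diagram over the cardiac cycle: a flat plateau at EDV
#' (iso-volumic contraction), rapid then reduced ejection down to ESV, a flat
#' plateau at ESV (iso-volumic relaxation), then rapid followed by reduced
#' filling back to EDV. The profile is pinned exactly to `edv_target` on the
#' ED plateau and `esv_target` on the ES plateau, once each per cycle.
#'
#' @param frame_index 1-based frame index (vectorized); must lie in
#'   `1:(n_frames * n_cycles)`.
#' @param params A [phantom_params()] object.
#' @return Volume in mL for each requested frame.
#' @export
volume_profile <- function(frame_index, params) {
  total <- params$n_frames * params$n_cycles
  if (any(frame_index < 1 | frame_index > total)) {
    abort(sprintf("frame_index out of range: valid range is 1..%d", total))
  }
  t <- ((frame_index - 1) %% params$n_frames) / params$n_frames
  p <- params$plateau_frac
  es_start <- 0.45
  es_end <- es_start + p
  edv <- params$edv_target; esv <- params$esv_target
  v <- numeric(length(t))
  ed_plateau <- t < p
  ejection <- t >= p & t < es_start
  es_plateau <- t >= es_start & t < es_end
  filling <- t >= es_end
  v[ed_plateau] <- edv
  v[ejection] <- edv - (edv - esv) * ramp_fast_early((t[ejection] - p) / (es_start - p))
  v[es_plateau] <- esv
  v[filling] <- esv + (edv - esv) * ramp_fast_early((t[filling] - es_end) / (1 - es_end))
  v
}

# designated ED/ES frame offsets within one cycle (1-based): first frame of
# each iso-volumic plateau
phantom_phase_frames <- function(params) {
  es_offset <- ceiling(0.45 * params$n_frames - 1e-9) + 1L
  list(ed = 1L, es = as.integer(es_offset))
}

# analytic ellipse contour for a cavity of volume v_ml, long semi-axis a_mm
phantom_ellipse <- function(v_ml, a_mm, center_xy, pixel_spacing, n_vertices = 180) {
  b_mm <- sqrt(3 * v_ml * 1000 / (4 * pi * a_mm))
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[seq_len(n_vertices)]
  as_contour(tibble(
    x = center_xy[1] + (b_mm / pixel_spacing) * cos(th),
    y = center_xy[2] + (a_mm / pixel_spacing) * sin(th)
  ))
}

#' Generate a synthetic echo-like beating-ventricle sequence
#'
#' Renders one frame per time point: myocardium-intensity background, a
#' cavity-intensity ellipse whose prolate-spheroid volume equals
#' [volume_profile()] at that frame, Gaussian blur, then multiplicative
#' speckle `I * (1 + speckle_sigma * eta)` with standard-normal `eta`,
#' clipped to \[0, 1\]. Ground truth carries the exact ellipse polygons,
#' analytic volumes, and designated ED/ES frame indices.
#'
#' @param params A [phantom_params()] object.
#' @return A list of class `lv_phantom` with elements
#'   * `sequence`: an `lv_sequence` (list of frames plus calibration),
#'   * `truth`: a list with `frames` (tibble: `frame`, `time_s`, `volume_ml`,
#'     `is_ed`, `is_es`), `contours` (list of `lv_contour`), `ed_frames`,
#'     `es_frames`, `ef_true`, `sv_true`, `co_true`, `hr_true`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  h <- params$grid_height; w <- params$grid_width
  sp <- params$pixel_spacing
  a_mm <- params$long_axis_frac * h * sp / 2
  b_edv_mm <- sqrt(3 * params$edv_target * 1000 / (4 * pi * a_mm))
  if (2 * a_mm > 0.9 * h * sp || 2 * b_edv_mm > 0.9 * w * sp) {
    abort(paste(
      "cavity ellipse exceeds grid bounds at EDV;",
      "use a larger grid or a smaller edv_target"
    ))
  }
  total <- params$n_frames * params$n_cycles
  center <- c((w + 1) / 2, (h + 1) / 2)
  vols <- volume_profile(seq_len(total), params)
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)

  frames <- vector("list", total)
  contours <- vector("list", total)
  # all randomness from one seed; global RNG state restored afterwards
  noise <- with_local_seed(params$rng_seed, function() {
    lapply(seq_len(total), function(i) {
      if (params$speckle_sigma > 0) matrix(rnorm(h * w), h, w) else NULL
    })
  })
  for (i in seq_len(total)) {
    b_mm <- sqrt(3 * vols[i] * 1000 / (4 * pi * a_mm))
    a_px <- a_mm / sp; b_px <- b_mm / sp
    inside <- ((xg - center[1]) / b_px)^2 + ((yg - center[2]) / a_px)^2 <= 1
    img <- matrix(params$myocardium_intensity, h, w)
    img[inside] <- params$cavity_intensity
    if (params$blur_sigma > 0) {
      img <- EBImage::gblur(img, sigma = params$blur_sigma, boundary = "replicate")
    }
    if (params$speckle_sigma > 0) {
      img <- img * (1 + params$speckle_sigma * noise[[i]])
    }
    frames[[i]] <- pmin(pmax(img, 0), 1)
    contours[[i]] <- phantom_ellipse(vols[i], a_mm, center, sp)
  }

  ph <- phantom_phase_frames(params)
  ed_frames <- (seq_len(params$n_cycles) - 1L) * params$n_frames + ph$ed
  es_frames <- (seq_len(params$n_cycles) - 1L) * params$n_frames + ph$es
  sv <- params$edv_target - params$esv_target
  ef <- sv / params$edv_target * 100
  hr <- 60 * params$frame_rate / params$n_frames
  truth <- list(
    frames = tibble(
      frame = seq_len(total),
      time_s = (seq_len(total) - 1) / params$frame_rate,
      volume_ml = vols,
      is_ed = seq_len(total) %in% ed_frames,
      is_es = seq_len(total) %in% es_frames
    ),
    contours = contours,
    ed_frames = ed_frames,
    es_frames = es_frames,
    ef_true = ef,
    sv_true = sv,
    hr_true = hr,
    co_true = sv * hr
  )
  structure(
    list(
      sequence = new_sequence(frames, params$frame_rate, sp),
      truth = truth,
      params = params
    ),
    class = "lv_phantom"
  )
}

#' @export
print.lv_phantom <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<lv_phantom> %dx%d px, %d cycles x %d frames @ %g Hz, EDV %g / ESV %g mL (EF %.2f%%)\n",
    p$grid_height, p$grid_width, p$n_cycles, p$n_frames, p$frame_rate,
    p$edv_target, p$esv_target, x$truth$ef_true
  ))
  invisible(x)
}
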