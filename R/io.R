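#' Image-sequence container
#'
#' @param frames List of numeric matrices in \[0, 1\], all the same shape.
#' @param frame_rate Hz.
#' @param pixel_spacing mm per pixel.
#' @return A list of class `lv_sequence`.
#' @export
new_sequence <- function(frames, frame_rate, pixel_spacing) {
  if (length(frames) < 2) abort("a sequence needs at least 2 frames")
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) abort("all frames must share one shape")
  if (frame_rate <= 0 || pixel_spacing <= 0) {
    abort("frame_rate and pixel_spacing must be positive")
  }
  structure(
    list(frames = frames, frame_rate = frame_rate, pixel_spacing = pixel_spacing),
    class = "lv_sequence"
  )
}

#' @export
print.lv_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<lv_sequence> %d frames, %dx%d px, %g Hz, %g mm/px\n",
    length(x$frames), d[1], d[2], x$frame_rate, x$pixel_spacing
  ))
  invisible(x)
}

# RGB(A) array -> Rec. 709 luminance matrix
to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3) {
      return(0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3])
    }
    return(a[, , 1])
  }
  abort("unsupported image array shape")
}

#' Read an image sequence from a directory or multi-page TIFF
#'
#' A directory is scanned for PNG/TIFF frames, sorted lexicographically by
#' filename; a single TIFF file is read page by page. RGB frames are
#' converted to luminance; intensities end up in \[0, 1\]. Spatial/temporal
#' calibration comes from the `pixel_spacing` / `frame_rate` arguments, or
#' from a `metadata.json` sidecar (`{"frame_rate": ..., "pixel_spacing": ...}`)
#' in the frame directory; explicit arguments win over the sidecar with a
#' warning.
#'
#' @param path Directory of frames or a multi-page TIFF file.
#' @param pixel_spacing,frame_rate Optional explicit calibration.
#' @return An `lv_sequence`.
#' @export
read_sequence <- function(path, pixel_spacing = NULL, frame_rate = NULL) {
  if (!file.exists(path)) abort(sprintf("path does not exist: %s", path))
  meta <- list()
  if (dir.exists(path)) {
    sidecar <- file.path(path, "metadata.json")
    if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2) abort("need at least 2 frames")
    frames <- lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
      to_gray(img)
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2) abort("need at least 2 frames")
    frames <- lapply(pages, to_gray)
  }
  resolve <- function(explicit, key, default) {
    sidecar_val <- meta[[key]]
    if (!is.null(explicit)) {
      if (!is.null(sidecar_val) && !isTRUE(all.equal(explicit, sidecar_val))) {
        warn(sprintf("%s: argument (%g) overrides metadata.json (%g)",
                     key, explicit, as.numeric(sidecar_val)))
      }
      explicit
    } else if (!is.null(sidecar_val)) {
      as.numeric(sidecar_val)
    } else {
      default
    }
  }
  new_sequence(
    frames,
    frame_rate = resolve(frame_rate, "frame_rate", 25),
    pixel_spacing = resolve(pixel_spacing, "pixel_spacing", 1)
  )
}

#' Write an image sequence as zero-padded PNG frames
#'
#' Writes `frame_0000.png`, `frame_0001.png`, ... (0-based numbering) plus a
#' `metadata.json` calibration sidecar.
#'
#' @param seq An `lv_sequence`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seq$frames)) {
    png::writePNG(
      pmin(pmax(seq$frames[[i]], 0), 1),
      file.path(dir, sprintf("frame_%04d.png", i - 1))
    )
  }
  jsonlite::write_json(
    list(frame_rate = seq$frame_rate, pixel_spacing = seq$pixel_spacing),
    file.path(dir, "metadata.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Write per-frame contours as CSV files
#'
#' One `frame_NNNN.csv` per contour (0-based numbering), columns
#' `x_px`, `y_px`, vertex order preserved.
#'
#' @param contours List of contours.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_contours <- function(contours, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(contours)) {
    cc <- as_contour(contours[[i]])
    readr::write_csv(
      tibble(x_px = cc$x, y_px = cc$y),
      file.path(dir, sprintf("frame_%04d.csv", i - 1))
    )
  }
  invisible(dir)
}

#' Read per-frame contour CSVs
#'
#' Reads every `*.csv` with `x_px`, `y_px` columns from a directory, sorted
#' lexicographically. Round trip with [write_contours()] preserves vertices
#' to better than 1e-4 px.
#'
#' @param dir Directory of contour CSVs.
#' @return A list of `lv_contour`.
#' @export
read_contours <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  # keep only contour tables (x_px,y_px header); directories may also hold
  # logs or curve exports
  has_vertex_header <- vapply(files, function(f) {
    hdr <- readLines(f, n = 1)
    length(hdr) == 1 && grepl("x_px", hdr) && grepl("y_px", hdr)
  }, logical(1))
  files <- files[has_vertex_header]
  if (length(files) == 0) abort("no contour CSVs found")
  lapply(files, read_contour_csv)
}

read_contour_csv <- function(file) {
  df <- suppressWarnings(
    readr::read_csv(file, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double()))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed CSV row in %s at line %d", file, probs$row[1]))
  }
  if (nrow(df) == 0) abort(sprintf("no vertices in %s", file))
  if (!all(c("x_px", "y_px") %in% names(df))) {
    abort(sprintf("%s must have x_px,y_px columns", file))
  }
  as_contour(tibble(x = df$x_px, y = df$y_px))
}

#' Read a run configuration from YAML
#'
#' Keys mirror [level_set_params()] field names exactly, plus `n_disks`,
#' `smoothing_window`, `pixel_spacing`, `frame_rate`, `seed_x`, `seed_y`,
#' `n_cycles_hint`, `hr_bpm` and the [phantom_params()] fields under
#' `phantom:`. Unknown keys raise an error; everything is validated before
#' any computation starts.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return A list: `levelset` (`level_set_params`), `phantom`
#'   (`phantom_params`), and the scalar pipeline settings.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c(
    names(formals(level_set_params)), "n_disks", "smoothing_window",
    "pixel_spacing", "frame_rate", "seed_x", "seed_y", "n_cycles_hint",
    "hr_bpm", "phantom"
  )
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  }
  ls_keys <- intersect(names(raw), names(formals(level_set_params)))
  ph_raw <- raw$phantom %||% list()
  bad_ph <- setdiff(names(ph_raw), names(formals(phantom_params)))
  if (length(bad_ph) > 0) {
    abort(sprintf("unknown phantom config keys: %s", paste(bad_ph, collapse = ", ")))
  }
  cfg <- list(
    levelset = do.call(level_set_params, raw[ls_keys]),
    phantom = do.call(phantom_params, ph_raw),
    n_disks = raw$n_disks %||% 20,
    smoothing_window = raw$smoothing_window %||% 1,
    pixel_spacing = raw$pixel_spacing %||% NULL,
    frame_rate = raw$frame_rate %||% NULL,
    seed_x = raw$seed_x %||% NULL,
    seed_y = raw$seed_y %||% NULL,
    n_cycles_hint = raw$n_cycles_hint %||% 1,
    hr_bpm = raw$hr_bpm %||% NULL
  )
  if (cfg$n_disks < 4) abort("n_disks must be >= 4")
  if (cfg$smoothing_window %% 2 == 0) abort("smoothing_window must be odd")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the volume curve with ED/ES labels as CSV
#'
#' Columns: `frame`, `time_s`, `volume_ml`, `label` (ED, ES or empty).
#'
#' @param curve An `lv_volume_curve`.
#' @param detection An `lv_cycles`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_volume_curve <- function(curve, detection, file) {
  label <- rep("", nrow(curve))
  label[detection$ed_frames] <- "ED"
  label[detection$es_frames] <- "ES"
  readr::write_csv(
    tibble(
      frame = curve$frame, time_s = curve$time_s,
      volume_ml = curve$volume_ml, label = label
    ),
    file
  )
  invisible(file)
}
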