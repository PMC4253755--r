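#' Level-set segmentation parameters
#'
#' Numerics and speed-function parameters for the edge-stopped level-set
#' evolution `phi_t = -F |grad phi|` with composite speed
#' `F = (v0 - eps_curv * kappa) * K1`, where `K1 = exp(-edge_gain * E_image)`
#' and `E_image = |grad(G_sigma * I)|` is the Gaussian-gradient image energy.
#'
#' @param sigma Gaussian scale (pixels) of the image-energy filter.
#' @param edge_gain Multiplier applied to the image energy before
#'   exponentiation; larger values stop the front harder at weaker edges.
#' @param v0 Balloon (constant normal) speed in pixels per unit time;
#'   positive inflates, appropriate for a seed placed inside the cavity.
#' @param eps_curv Curvature regularization weight (>= 0).
#' @param dt Explicit Euler time step; must satisfy the CFL bound
#'   `dt * max(|speed|) <= 0.5` pixels.
#' @param max_iters Iteration cap per frame.
#' @param reinit_every Iterations between signed-distance reinitializations.
#' @param converge_tol Stop when the fraction of grid points whose phi-sign
#'   changed over the last 5 iterations falls below this.
#' @param band_width Narrow-band half-width in pixels; 0 evolves the full grid.
#' @param snap_to_edge Relocate the converged contour onto the ridge of the
#'   image energy along local normals (subpixel edge localization). The
#'   edge-stopped speed decays on the inner flank of the gradient ridge, so
#'   the frozen front sits systematically about a pixel inside the true
#'   border; the snap removes that bias. Set `FALSE` to keep the raw front.
#' @param snap_search Half-width (pixels) of the normal search for the ridge.
#' @return A validated list of class `level_set_params`.
#' @export
level_set_params <- function(sigma = 1.5, edge_gain = 55, v0 = 1,
                             eps_curv = 0.35, dt = 0.35, max_iters = 600L,
                             reinit_every = 20L, converge_tol = 1e-4,
                             band_width = 0, snap_to_edge = TRUE,
                             snap_search = 3) {
  p <- list(
    sigma = sigma, edge_gain = edge_gain, v0 = v0, eps_curv = eps_curv,
    dt = dt, max_iters = as.integer(max_iters),
    reinit_every = as.integer(reinit_every), converge_tol = converge_tol,
    band_width = band_width, snap_to_edge = isTRUE(snap_to_edge),
    snap_search = snap_search
  )
  if (p$sigma < 0) abort("sigma must be >= 0")
  if (p$edge_gain <= 0) abort("edge_gain must be > 0")
  if (p$eps_curv < 0) abort("eps_curv must be >= 0")
  if (p$dt <= 0) abort("dt must be > 0")
  if (p$max_iters < 1) abort("max_iters must be >= 1")
  if (p$reinit_every < 1) abort("reinit_every must be >= 1")
  if (p$band_width < 0) abort("band_width must be >= 0")
  if (p$snap_search <= 0) abort("snap_search must be > 0")
  class(p) <- "level_set_params"
  p
}

# bilinear interpolation of matrix m (indexed [y, x]) at arbitrary points,
# clamped to the grid
bilinear_at <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  fx <- x - x0; fy <- y - y0
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# circular moving average of a vector
smooth_circular <- function(v, window) {
  if (window <= 1) return(v)
  half <- (window - 1) %/% 2
  n <- length(v)
  vv <- c(v[(n - half + 1):n], v, v[1:half])
  as.numeric(stats::filter(vv, rep(1 / window, window), sides = 2))[(half + 1):(half + n)]
}

#' Snap a contour onto the image-energy ridge
#'
#' Moves each vertex along the local outward normal to the maximum of the
#' image energy within `+/- search` pixels (the subpixel edge position),
#' smoothing the offsets along the contour to resist speckle-induced jitter.
#' Vertices with no meaningful energy in their search window stay put.
#'
#' @param contour An `lv_contour`.
#' @param energy An [image_energy()] matrix for the same frame.
#' @param search Normal search half-width, pixels.
#' @param n_vertices Resampling density before snapping.
#' @return The relocated `lv_contour`.
#' @export
snap_contour_to_ridge <- function(contour, energy, search = 3, n_vertices = 256) {
  cc <- resample_contour(contour, n_vertices)
  n <- nrow(cc)
  nx_t <- (cc$x[c(2:n, 1)] - cc$x[c(n, 1:(n - 1))]) / 2
  ny_t <- (cc$y[c(2:n, 1)] - cc$y[c(n, 1:(n - 1))]) / 2
  len <- pmax(sqrt(nx_t^2 + ny_t^2), 1e-12)
  nx <- ny_t / len; ny <- -nx_t / len # rotate tangent 90 degrees
  # orient outward (away from the centroid)
  cxm <- mean(cc$x); cym <- mean(cc$y)
  flip <- (nx * (cc$x - cxm) + ny * (cc$y - cym)) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  offsets <- seq(-search, search, by = 0.25)
  ev <- vapply(offsets, function(s) {
    bilinear_at(energy, cc$x + s * nx, cc$y + s * ny)
  }, numeric(n))
  best <- max.col(ev, ties.method = "first")
  s_star <- offsets[best]
  peak <- ev[cbind(seq_len(n), best)]
  s_star[peak < 1e-6] <- 0
  s_star <- smooth_circular(s_star, 5)
  as_contour(tibble(x = cc$x + s_star * nx, y = cc$y + s_star * ny))
}

# central-difference gradient with edge replication; returns list(gx, gy)
grad_central <- function(m) {
  list(
    gx = (shift_mat(m, 0, -1) - shift_mat(m, 0, 1)) / 2,
    gy = (shift_mat(m, -1, 0) - shift_mat(m, 1, 0)) / 2
  )
}

#' Image energy: gradient magnitude of the Gaussian-smoothed frame
#'
#' `E_image(x, y) = |grad(G_sigma * I)(x, y)|`, computed with a replicated
#' boundary. Zero on constant images; peaks on intensity edges.
#'
#' @param frame Numeric matrix of intensities.
#' @param sigma Gaussian scale in pixels (0 skips smoothing).
#' @return Nonnegative matrix, same shape as `frame`.
#' @export
image_energy <- function(frame, sigma = 1.5) {
  if (!all(is.finite(frame))) abort("frame contains non-finite pixels")
  if (sigma < 0) abort("sigma must be >= 0")
  sm <- if (sigma > 0) {
    EBImage::gblur(frame, sigma = sigma, boundary = "replicate")
  } else {
    frame
  }
  g <- grad_central(sm)
  sqrt(g$gx^2 + g$gy^2)
}

#' Edge-stopping map K1 = exp(-edge_gain * E_image)
#'
#' Values in (0, 1]: exactly 1 where the image energy vanishes, decaying
#' towards 0 on strong edges, where it freezes the front.
#'
#' @param edge An [image_energy()] matrix.
#' @param edge_gain Positive gain applied before exponentiation.
#' @return Matrix in (0, 1].
#' @export
stopping_map <- function(edge, edge_gain = 25) {
  if (edge_gain <= 0) abort("edge_gain must be > 0")
  exp(-edge_gain * edge)
}

#' Initialize a signed-distance field from a seed
#'
#' A point seed becomes a disk of radius `radius` pixels (exact circle signed
#' distance); a logical mask becomes its signed Euclidean distance transform.
#' The field is negative inside the seed region.
#'
#' @param seed Either `c(x, y)` (pixel coordinates) or a logical matrix of
#'   shape `shape` marking the inside.
#' @param shape `c(height, width)` of the frame.
#' @param radius Disk radius for point seeds, pixels.
#' @return A signed-distance matrix.
#' @export
init_phi <- function(seed, shape, radius = 5) {
  h <- shape[1]; w <- shape[2]
  if (is.matrix(seed)) {
    if (!any(seed)) abort("seed mask is empty")
    if (!all(dim(seed) == c(h, w))) abort("seed mask shape mismatch")
    m <- (seed != 0) * 1
    d_in <- as.numeric(EBImage::distmap(m))
    d_out <- as.numeric(EBImage::distmap(1 - m))
    phi <- matrix(ifelse(m > 0, -(d_in - 0.5), d_out - 0.5), h, w)
    phi
  } else {
    x0 <- seed[1]; y0 <- seed[2]
    if (x0 < 1 || x0 > w || y0 < 1 || y0 > h) abort("seed point outside grid")
    xg <- matrix(seq_len(w), h, w, byrow = TRUE)
    yg <- matrix(seq_len(h), h, w)
    sqrt((xg - x0)^2 + (yg - y0)^2) - radius
  }
}

#' Mean curvature of the level sets of phi
#'
#' `kappa = div(grad phi / |grad phi|)` by central differences, with the
#' gradient norm floored at 1e-8 and the result clamped to the grid
#' resolution limit |kappa| <= 1 per pixel.
#'
#' @param phi Level-set field (matrix).
#' @return Curvature matrix, finite everywhere.
#' @export
mean_curvature <- function(phi) {
  if (!all(is.finite(phi))) abort("phi contains non-finite values")
  gx <- (shift_mat(phi, 0, -1) - shift_mat(phi, 0, 1)) / 2
  gy <- (shift_mat(phi, -1, 0) - shift_mat(phi, 1, 0)) / 2
  gxx <- shift_mat(phi, 0, -1) - 2 * phi + shift_mat(phi, 0, 1)
  gyy <- shift_mat(phi, -1, 0) - 2 * phi + shift_mat(phi, 1, 0)
  gxy <- (shift_mat(phi, -1, -1) + shift_mat(phi, 1, 1) -
            shift_mat(phi, -1, 1) - shift_mat(phi, 1, -1)) / 4
  denom <- pmax((gx^2 + gy^2)^1.5, 1e-8)
  k <- (gxx * gy^2 - 2 * gx * gy * gxy + gyy * gx^2) / denom
  pmin(pmax(k, -1), 1)
}

#' One explicit evolution step of the edge-stopped level set
#'
#' Updates `phi <- phi - dt * k1 * (v0 * |grad phi|_upwind -
#' eps_curv * kappa * |grad phi|_central)`, with the upwind (Godunov) gradient
#' chosen by the sign of the advective speed. When `band_width > 0` the
#' update is restricted to the narrow band `|phi| <= band_width`.
#'
#' @param phi Level-set field.
#' @param k1 Edge-stopping map from [stopping_map()] (or a constant matrix).
#' @param params [level_set_params()].
#' @return The updated field.
#' @export
evolve_step <- function(phi, k1, params = level_set_params()) {
  speed_max <- max(abs(k1)) * (abs(params$v0) + params$eps_curv)
  if (params$dt * speed_max > 0.5 + 1e-9) {
    abort(sprintf(
      "CFL violated: dt * max|speed| = %.3f > 0.5; need dt <= %.4f",
      params$dt * speed_max, 0.5 / speed_max
    ))
  }
  dxm <- phi - shift_mat(phi, 0, 1)
  dxp <- shift_mat(phi, 0, -1) - phi
  dym <- phi - shift_mat(phi, 1, 0)
  dyp <- shift_mat(phi, -1, 0) - phi
  grad_plus <- sqrt(pmax(dxm, 0)^2 + pmin(dxp, 0)^2 +
                      pmax(dym, 0)^2 + pmin(dyp, 0)^2)
  grad_minus <- sqrt(pmin(dxm, 0)^2 + pmax(dxp, 0)^2 +
                       pmin(dym, 0)^2 + pmax(dyp, 0)^2)
  grad_up <- if (params$v0 >= 0) grad_plus else grad_minus
  adv <- params$v0 * grad_up
  curv <- if (params$eps_curv > 0) {
    g <- grad_central(phi)
    params$eps_curv * mean_curvature(phi) * sqrt(g$gx^2 + g$gy^2)
  } else {
    0
  }
  upd <- params$dt * k1 * (adv - curv)
  if (params$band_width > 0) {
    band <- abs(phi) <= params$band_width
    phi[band] <- phi[band] - upd[band]
    phi
  } else {
    phi - upd
  }
}

# extract all zero-level components as segment matrices (x1 y1 x2 y2) in
# (x = col, y = row) coordinates, decimated to at most max_vertices in total
zero_segments <- function(phi, max_vertices = 200) {
  cl <- contourLines(seq_len(nrow(phi)), seq_len(ncol(phi)), phi, levels = 0)
  if (length(cl) == 0) return(NULL)
  nv <- sum(vapply(cl, function(cc) length(cc$x), numeric(1)))
  keep_every <- max(1, floor(nv / max_vertices))
  segs <- lapply(cl, function(cc) {
    x <- cc$y; y <- cc$x # contourLines' x runs over rows
    if (keep_every > 1) {
      idx <- unique(c(seq(1, length(x), by = keep_every), length(x)))
      x <- x[idx]; y <- y[idx]
    }
    if (length(x) < 2) return(NULL)
    cbind(x[-length(x)], y[-length(y)], x[-1], y[-1])
  })
  do.call(rbind, segs)
}

#' Reinitialize phi to a signed-distance function
#'
#' Redistances the field by exact geometric distance from every grid point to
#' the current zero-level polyline (extracted by marching squares), keeping
#' the original sign. The zero level set moves by at most the isocontour
#' interpolation error (well under half a pixel).
#'
#' @param phi Level-set field with a nonempty zero level set.
#' @return A signed-distance matrix with the same zero level set.
#' @export
reinitialize <- function(phi) {
  if (all(phi > 0) || all(phi < 0)) abort("contour collapsed: zero level set is empty")
  segs <- zero_segments(phi)
  if (is.null(segs)) abort("contour collapsed: zero level set is empty")
  h <- nrow(phi); w <- ncol(phi)
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  d <- point_segment_dist(cbind(as.numeric(xg), as.numeric(yg)), segs)
  matrix(ifelse(as.numeric(phi) < 0, -d, d), h, w)
}

#' Extract the zero-level contour of phi
#'
#' Marching squares with linear interpolation; among closed components the
#' longest (by perimeter) is returned, counterclockwise. Open components
#' (truncated by the image border) are ignored.
#'
#' @param phi Level-set field.
#' @return An `lv_contour`.
#' @export
extract_contour <- function(phi) {
  cl <- suppressWarnings(
    contourLines(seq_len(nrow(phi)), seq_len(ncol(phi)), phi, levels = 0)
  )
  if (length(cl) == 0) abort("no zero level set found")
  closed <- purrr::keep(cl, function(cc) {
    n <- length(cc$x)
    n >= 4 && abs(cc$x[1] - cc$x[n]) < 1e-8 && abs(cc$y[1] - cc$y[n]) < 1e-8
  })
  if (length(closed) == 0) abort("no closed zero-level component found")
  per <- vapply(closed, function(cc) {
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2))
  }, numeric(1))
  cc <- closed[[which.max(per)]]
  as_contour(tibble(x = cc$y, y = cc$x)) # swap: contourLines' x is the row axis
}

#' Segment a single frame with the edge-stopped level set
#'
#' Iterates [evolve_step()] from an initial signed-distance field, with
#' periodic [reinitialize()] passes, until the fraction of grid points whose
#' phi-sign changed over the last 5 iterations drops below `converge_tol`, or
#' `max_iters` is reached.
#'
#' @param frame Intensity matrix in \[0, 1\].
#' @param init Initial level-set field (e.g. from [init_phi()]), zero set
#'   strictly inside the frame.
#' @param params [level_set_params()].
#' @return A list: `contour` (`lv_contour`), `phi` (final field),
#'   `iterations`, `converged` (logical).
#' @export
segment_frame <- function(frame, init, params = level_set_params()) {
  energy <- image_energy(frame, params$sigma)
  k1 <- stopping_map(energy, params$edge_gain)
  phi <- init
  converged <- FALSE
  it <- 0L
  snapshots <- list(sign(phi))
  for (it in seq_len(params$max_iters)) {
    phi <- evolve_step(phi, k1, params)
    if (all(phi > 0) || all(phi < 0)) {
      abort("contour collapsed during evolution")
    }
    if (it %% params$reinit_every == 0) phi <- reinitialize(phi)
    snapshots[[length(snapshots) + 1L]] <- sign(phi)
    if (length(snapshots) > 6) snapshots <- snapshots[-1]
    if (length(snapshots) >= 6) {
      frac <- mean(snapshots[[1]] != snapshots[[length(snapshots)]])
      if (frac < params$converge_tol) {
        converged <- TRUE
        break
      }
    }
  }
  inside <- phi < 0
  border <- c(inside[1, ], inside[nrow(inside), ], inside[, 1], inside[, ncol(inside)])
  if (any(border)) abort("contour touched the image border")
  contour <- extract_contour(phi)
  if (params$snap_to_edge) {
    contour <- snap_contour_to_ridge(contour, energy, search = params$snap_search)
  }
  list(
    contour = contour,
    phi = phi,
    iterations = it,
    converged = converged
  )
}

#' Segment a whole image sequence with temporal propagation
#'
#' Frame 1 is segmented from the given seed; each subsequent frame is
#' initialized from the previous frame's converged field shifted 2 px inward
#' (so the front re-approaches the border from inside even when the cavity
#' contracts between frames).
#'
#' @param seq An `lv_sequence` (see [read_sequence()] / [generate_phantom()]).
#' @param seed `c(x, y)` point inside the cavity of frame 1, or a logical
#'   seed mask.
#' @param params [level_set_params()].
#' @param erosion_px Inward shift applied when propagating between frames.
#' @return A list of `lv_contour`, one per frame, with attributes
#'   `iterations` and `converged` (per-frame vectors). On failure the error
#'   condition carries `frame` and `contours` (partial results) fields.
#' @export
segment_sequence <- function(seq, seed, params = level_set_params(),
                             erosion_px = 2) {
  frames <- seq$frames
  n <- length(frames)
  contours <- vector("list", n)
  iters <- integer(n)
  conv <- logical(n)
  phi <- init_phi(seed, dim(frames[[1]]))
  for (i in seq_len(n)) {
    res <- tryCatch(
      segment_frame(frames[[i]], phi, params),
      error = function(e) {
        abort(
          sprintf("segmentation failed at frame %d: %s", i, conditionMessage(e)),
          class = "lvecho_segmentation_error",
          frame = i, contours = contours[seq_len(i - 1)]
        )
      }
    )
    contours[[i]] <- res$contour
    iters[i] <- res$iterations
    conv[i] <- res$converged
    if (i < n) phi <- reinitialize(res$phi + erosion_px)
  }
  attr(contours, "iterations") <- iters
  attr(contours, "converged") <- conv
  contours
}
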