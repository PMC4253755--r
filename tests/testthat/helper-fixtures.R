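# shared fixtures and independent oracles, built in code

circle_contour <- function(r, cx = 0, cy = 0, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  as_contour(data.frame(x = cx + r * cos(th), y = cy + r * sin(th)))
}

ellipse_contour <- function(a, b, cx = 0, cy = 0, n = 256) {
  # semi-axis a along x, b along y
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  as_contour(data.frame(x = cx + a * cos(th), y = cy + b * sin(th)))
}

# exact signed distance to a circle, negative inside
circle_sdf <- function(r, h = 128, w = 128, cx = (w + 1) / 2, cy = (h + 1) / 2) {
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  sqrt((xg - cx)^2 + (yg - cy)^2) - r
}

# near-exact signed distance to an ellipse via a dense polygon
ellipse_sdf <- function(a, b, h = 128, w = 128, n = 720) {
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  ex <- cx + a * cos(th); ey <- cy + b * sin(th)
  segs <- cbind(ex, ey, c(ex[-1], ex[1]), c(ey[-1], ey[1]))
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  d <- matrix(
    lvecho:::point_segment_dist(cbind(as.numeric(xg), as.numeric(yg)), segs),
    h, w
  )
  inside <- ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
  ifelse(inside, -d, d)
}

# O(N^2) brute-force distance oracle: min distance from every pixel to the
# nearest boundary pixel of a mask (boundary = inside pixel with an outside
# 4-neighbour, or vice versa depending on side)
brute_force_sdf <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  xg <- matrix(seq_len(w), h, w, byrow = TRUE)
  yg <- matrix(seq_len(h), h, w)
  # boundary pixels: inside pixels adjacent to outside
  nb <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(h) - dr, 1), h)
    ci <- pmin(pmax(seq_len(w) - dc, 1), w)
    m[ri, ci]
  }
  edge_in <- mask & !(nb(mask, 1, 0) & nb(mask, -1, 0) & nb(mask, 0, 1) & nb(mask, 0, -1))
  edge_out <- !mask & (nb(mask, 1, 0) | nb(mask, -1, 0) | nb(mask, 0, 1) | nb(mask, 0, -1))
  bx <- c(xg[edge_in], xg[edge_out]); by <- c(yg[edge_in], yg[edge_out])
  d <- matrix(Inf, h, w)
  for (k in seq_along(bx)) {
    d <- pmin(d, sqrt((xg - bx[k])^2 + (yg - by[k])^2))
  }
  ifelse(mask, -d, d)
}

# memoize expensive phantom pipeline runs within one test session
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, fn) {
  if (!exists(key, envir = .run_cache)) assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

noiseless_phantom <- function() {
  cached("noiseless_phantom", function() {
    generate_phantom(phantom_params(speckle_sigma = 0, blur_sigma = 1))
  })
}

noiseless_run <- function() {
  cached("noiseless_run", function() {
    ph <- noiseless_phantom()
    analyze_sequence(ph$sequence, c(64.5, 64.5),
      params = level_set_params(), n_cycles_hint = 3
    )
  })
}

speckle_phantom <- function() {
  cached("speckle_phantom", function() {
    generate_phantom(phantom_params(speckle_sigma = 0.1, blur_sigma = 1))
  })
}

speckle_run <- function() {
  cached("speckle_run", function() {
    ph <- speckle_phantom()
    analyze_sequence(ph$sequence, c(64.5, 64.5),
      params = level_set_params(), n_cycles_hint = 3
    )
  })
}
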