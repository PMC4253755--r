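# run fn() under a fixed seed, restoring the caller's RNG state afterwards
with_local_seed <- function(seed, fn) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  fn()
}

# edge-replicated shift of a matrix by (dr, dc); dr = +1 pulls the row above
shift_mat <- function(m, dr = 0, dc = 0) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1), w)
  m[ri, ci, drop = FALSE]
}
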