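# Shared fixtures: tiny phantoms and small helpers. Everything is built in
# code at test time; nothing is read from disk.

# replace non-finite (flagged degenerate) map values by zero flow, the same
# convention used when maps are exported
zero_fill <- function(m) {
  m[!is.finite(m)] <- 0
  m
}

# small smooth test image with two blobs (no symmetry, non-trivial gradients)
blob_image <- function(n = 16) {
  xs <- matrix(rep(seq_len(n) - 1, n), n)
  ys <- t(xs)
  exp(-((xs - 0.45 * n)^2 + (ys - 0.52 * n)^2) / (0.05 * n^2)) +
    0.3 * exp(-((xs - 0.2 * n)^2 + (ys - 0.75 * n)^2) / (0.02 * n^2))
}

# a small DRO spec that keeps unit tests fast
small_dro_spec <- function(...) {
  dro_spec(matrix = c(32, 32), n_frames = 40, ...)
}

# single-pixel dynamic series from a signal vector (replicated over a
# minimal 2 x 2 spatial grid)
pixel_series <- function(signal, frame_times, n0) {
  nt <- length(signal)
  data <- aperm(array(signal, dim = c(nt, 2, 2)), c(2, 3, 1))
  dynamic_series(data, frame_times = frame_times, n0 = n0)
}
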