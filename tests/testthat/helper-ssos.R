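# Shared fixtures: a reduced 64 x 8 x 128 grid keeps every forward model and
# reconstruction in the sub-second range while Nyquist-sampling both cutoffs.

small_grid <- function() grid_spec(c(64L, 8L, 128L), voxel_xy = 40, voxel_z = 40)

small_scenario <- function(...) ssos_scenario(grid = small_grid(), ...)

# Forward models are deterministic; build each once per test file.
..fwd_cache <- new.env(parent = emptyenv())

cached_forward <- function(key = "small", builder = function() {
  simulate_scenario(small_scenario())
}) {
  if (!exists(key, envir = ..fwd_cache)) {
    assign(key, builder(), envir = ..fwd_cache)
  }
  get(key, envir = ..fwd_cache)
}

rel_l2 <- function(a, b, sel = TRUE) {
  sqrt(sum(Mod(a[sel] - b[sel])^2) / sum(Mod(b[sel])^2))
}

# Independent local-frequency estimate from linearly interpolated zero
# crossings of a (profile - offset) trace sampled at `spacing` (um).
zero_crossing_freq <- function(trace, spacing, n_last = 5) {
  zc <- c()
  for (i in seq_len(length(trace) - 1)) {
    if (trace[i] * trace[i + 1] < 0) {
      zc <- c(zc, i + trace[i] / (trace[i] - trace[i + 1]))
    }
  }
  zc <- utils::tail(zc, n_last)
  list(freq = 1 / (2 * mean(diff(zc)) * spacing), at_index = mean(zc))
}

# Circular convolution with a lattice-centred kernel, written independently of
# the package plumbing (direct use of stats::fft).
conv_ref <- function(v, h) {
  d <- dim(h)
  hs <- ssos::circshift(h, -(d %/% 2L))
  Re(stats::fft(stats::fft(v) * stats::fft(hs), inverse = TRUE)) / length(v)
}
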