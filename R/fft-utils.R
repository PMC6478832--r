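# Frequency-lattice helpers. Everything in the package works on DC-centred
# spectra: the zero-frequency bin sits at index floor(n/2) + 1 along each axis
# (grids are constrained to even sizes, so fftshift and its inverse use
# floor(n/2) and ceiling(n/2) respectively and agree).

#' Circularly shift an array
#'
#' Shifts array content by `shift[i]` bins along axis `i`, wrapping around.
#' A positive shift moves content towards higher indices, i.e.
#' `out[k] = a[k - shift]` (modulo the axis length).
#'
#' @param a array (any number of dimensions, vectors included)
#' @param shift integer vector, one entry per dimension of `a`
#' @return array of the same shape
#' @export
circshift <- function(a, shift) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  stopifnot(length(shift) == length(d))
  idx <- lapply(seq_along(d), function(i) {
    ((seq_len(d[i]) - 1L - as.integer(shift[i])) %% d[i]) + 1L
  })
  out <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  dim(out) <- dim(a)
  out
}

#' @rdname fftshift3
#' @export
ifftshift3 <- function(a) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  circshift(a, -(d %/% 2L))
}

#' Centre / un-centre the zero-frequency bin
#'
#' `fftshift3` moves the DC bin of an FFT-ordered array to the lattice centre
#' (`floor(n/2) + 1` per axis); `ifftshift3` is its inverse. Both work for any
#' dimensionality.
#'
#' @param a array
#' @return array of the same shape
#' @export
fftshift3 <- function(a) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  circshift(a, d %/% 2L)
}

#' Forward transform of a volume to a DC-centred spectrum
#'
#' @param v real or complex 3-D array, spatial origin at index 1
#' @return complex array, DC-centred
#' @export
vol_fft <- function(v) fftshift3(stats::fft(v))

#' Inverse transform of a DC-centred spectrum
#'
#' @param S complex DC-centred array
#' @param real if `TRUE` (default) return the real part (the imaginary
#'   residual of a conjugate-symmetric spectrum is numerical noise)
#' @return array (real if `real = TRUE`)
#' @export
spec_ifft <- function(S, real = TRUE) {
  v <- stats::fft(ifftshift3(S), inverse = TRUE) / length(S)
  if (real) Re(v) else v
}

# Shift a DC-centred spectrum (or mask) by `d` bins along kx (3rd axis):
# out(k) = in(k - d * x_hat).
shift_kx <- function(S, d) circshift(S, c(0L, 0L, as.integer(d)))

# Circular FFT convolution of a volume with a lattice-centred kernel.
# `Hraw` is fft(ifftshift3(h)) — precompute it when convolving repeatedly.
conv_fft <- function(v, Hraw) {
  Re(stats::fft(stats::fft(v) * Hraw, inverse = TRUE)) / length(v)
}

# DC-centred frequency axis in cycles/um for n samples at voxel_nm spacing.
freq_axis <- function(n, voxel_nm) {
  ((seq_len(n) - 1L) - n %/% 2L) / (n * voxel_nm / 1000)
}

# Relative conjugate-symmetry residual of a DC-centred spectrum; 0 for the
# spectrum of a real volume (up to roundoff).
conj_symmetry_residual <- function(S) {
  d <- dim(S)
  idx <- lapply(d, function(n) c(1L, seq(n, 2L)))
  Sm <- do.call(`[`, c(list(ifftshift3(S)), idx, list(drop = FALSE)))
  Sf <- ifftshift3(S)
  sqrt(sum(Mod(Sf - Conj(Sm))^2) / max(sum(Mod(Sf)^2), .Machine$double.xmin))
}

# Run code with a private, restored RNG state.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
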