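#' Tilted frequency-chirp phantom description
#'
#' The validation phantom is a stripe pattern whose wavevector is tilted by
#' `tilt_deg` from the optical axis (in the x-z plane) and whose local spatial
#' frequency along that tilted axis rises linearly with depth, from zero at the
#' top z-plane to `f_max` at the bottom. Reading a reconstruction of this
#' phantom depth by depth therefore reads out the recovered axial frequency
#' range directly.
#'
#' @param f_max local frequency at the bottom row, cycles/um along the tilted
#'   axis
#' @param tilt_deg tilt of the stripe wavevector from the optical axis, degrees
#'   in `[0, 90)`
#' @param grid a [grid_spec()]
#' @return object of class `chirp_spec`
#' @export
chirp_spec <- function(f_max, tilt_deg = 15, grid = default_grid()) {
  if (tilt_deg < 0 || tilt_deg >= 90) stop("tilt_deg must lie in [0, 90)")
  if (f_max <= 0) stop("f_max must be positive")
  th <- tilt_deg * pi / 180
  nyq_z <- 1000 / (2 * grid$voxel_z)
  nyq_x <- 1000 / (2 * grid$voxel_xy)
  if (f_max * cos(th) > nyq_z || f_max * sin(th) > nyq_x) {
    stop("f_max = ", signif(f_max, 5),
         " cycles/um exceeds the grid Nyquist limit along the tilted axis")
  }
  structure(list(f_max = f_max, tilt_deg = tilt_deg, grid = grid),
            class = "chirp_spec")
}

#' Generate the tilted frequency-chirp phantom
#'
#' Produces `s(x) = (1 + cos(phi))/2` with the phase chosen so that the local
#' frequency along the tilted axis at depth `z` is `f(z) = f_max * z / Z`
#' (exact on the central axis; the linear-in-depth chirp law is the simplest
#' consistent with a frequency ramp from zero to `f_max`). Values lie in
#' `[0, 1]`; the top plane is constant; `tilt_deg = 0` gives exactly
#' horizontal stripe planes.
#'
#' @param spec a [chirp_spec()]
#' @return real array `(nz, ny, nx)` in `[0, 1]`
#' @export
make_chirp_sample <- function(spec) {
  g <- spec$grid
  nz <- g$shape[1]; ny <- g$shape[2]; nx <- g$shape[3]
  th <- spec$tilt_deg * pi / 180
  dz <- g$voxel_z / 1000; dx <- g$voxel_xy / 1000
  Z <- (nz - 1) * dz
  z <- (seq_len(nz) - 1) * dz
  f <- spec$f_max * z / Z                     # local frequency per depth
  Fint <- spec$f_max * z^2 / (2 * Z)          # integral of f over depth
  xc <- (nx %/% 2L) * dx
  x <- (seq_len(nx) - 1) * dx - xc
  # phi/(2 pi) = F(z) cos(th) + f(z) sin(th) (x - xc): directional derivative
  # along the tilted axis equals f(z) (exactly at x = xc).
  phase <- 2 * pi * ((Fint * cos(th)) %o% rep(1, nx) + (f * sin(th)) %o% x)
  s <- 0.5 * (1 + cos(phase))                 # (nz, nx)
  out <- array(0, c(nz, ny, nx))
  for (iy in seq_len(ny)) out[, iy, ] <- s
  out
}

#' Illumination pattern descriptor
#'
#' Describes one pi-shifted pattern pair: integer lateral frequency offset in
#' bins along x, global phase offset, the raw optical modulation contrast `m`
#' of each projected pattern, the polarization intensity ratio `t`, and the
#' resulting effective modulation contrast `n = m (t-1)/(t+1)` seen in each
#' recorded image after polarization cross-talk.
#'
#' @param freq_px integer pattern frequency in bins along x (non-zero)
#' @param phase_offset global pattern phase phi0, radians
#' @param raw_mod raw modulation contrast m in `[0, 1]`
#' @param pol_ratio parallel-to-perpendicular intensity ratio t (>= 1)
#' @param mod_contrast effective contrast n; computed from `raw_mod` and
#'   `pol_ratio` when missing (supply directly for patterns measured from data)
#' @return object of class `pattern_params`
#' @export
pattern_params <- function(freq_px, phase_offset = 0, raw_mod = 1,
                           pol_ratio = 3, mod_contrast = NULL) {
  freq_px <- as.integer(freq_px)
  if (!is.na(raw_mod) && (raw_mod < 0 || raw_mod > 1)) {
    stop("raw_mod must lie in [0, 1]")
  }
  if (!is.na(pol_ratio) && pol_ratio < 1) stop("pol_ratio must be >= 1")
  if (is.null(mod_contrast)) {
    mod_contrast <- effective_modulation(pol_ratio, raw_mod)
  }
  structure(list(freq_px = freq_px, phase_offset = phase_offset,
                 raw_mod = raw_mod, pol_ratio = pol_ratio,
                 mod_contrast = mod_contrast),
            class = "pattern_params")
}

#' The pi-shifted normalized excitation pattern pair
#'
#' `e_p = (1 + m cos(2 pi p x / nx + phi0)) / (1 + m)` and `e_s` identical
#' with the phase advanced by pi. Both are invariant along y and z (the
#' patterns are invariant along the optical axis), strictly positive for
#' `m < 1`, and their sum is the spatial constant `2/(1+m)` — the sample sees
#' a homogeneous total exposure.
#'
#' @param params a [pattern_params()]
#' @param grid a [grid_spec()]
#' @return list with arrays `e_p` and `e_s`
#' @export
excitation_patterns <- function(params, grid) {
  if (params$freq_px == 0L) stop("structured illumination requires freq_px != 0")
  nz <- grid$shape[1]; ny <- grid$shape[2]; nx <- grid$shape[3]
  m <- params$raw_mod
  x <- seq_len(nx) - 1
  arg <- 2 * pi * params$freq_px * x / nx + params$phase_offset
  line_p <- (1 + m * cos(arg)) / (1 + m)
  line_s <- (1 + m * cos(arg + pi)) / (1 + m)
  expand <- function(line) {
    out <- array(0, c(nz, ny, nx))
    plane <- matrix(line, ny, nx, byrow = TRUE)
    for (iz in seq_len(nz)) out[iz, , ] <- plane
    out
  }
  list(e_p = expand(line_p), e_s = expand(line_s))
}

#' Parallel-to-perpendicular intensity ratio from fluorescence anisotropy
#'
#' From the anisotropy definition `r = (I_par - I_perp)/(I_par + 2 I_perp)`,
#' the intensity ratio is `t = (1 + 2r)/(1 - r)`. The one-photon theoretical
#' maximum for immobile dipoles is `r = 0.4`, giving the classic 3:1 ratio;
#' larger values are accepted with a warning.
#'
#' @param r fluorescence anisotropy, `0 <= r < 1`
#' @return intensity ratio t
#' @export
anisotropy_ratio <- function(r) {
  if (!is.numeric(r) || r < 0 || r >= 1) stop("anisotropy r must lie in [0, 1)")
  if (r > 0.4) {
    warning("anisotropy r = ", r,
            " exceeds the one-photon theoretical maximum of 0.4")
  }
  (1 + 2 * r) / (1 - r)
}

#' Effective modulation contrast after polarization cross-talk
#'
#' Each detection arm records `t` times its own pattern plus the orthogonal,
#' pi-shifted one; the combined single-harmonic pattern has amplitude-to-offset
#' ratio `n = m (t - 1)/(t + 1)`. For the ideal case `t = 3`, `m = 1` this is
#' 0.5 — the 50% contrast available to the polarization-multiplexed system.
#'
#' @param t polarization intensity ratio (>= 1)
#' @param m raw modulation contrast in `[0, 1]`
#' @return effective contrast n in `[0, 1]`
#' @export
effective_modulation <- function(t, m) {
  if (any(is.na(t)) || any(is.na(m))) return(NA_real_)
  if (t < 1) stop("intensity ratio t must be >= 1")
  if (m < 0 || m > 1) stop("raw modulation m must lie in [0, 1]")
  m * (t - 1) / (t + 1)
}

#' Form the polarization-mixed raw image pair
#'
#' The forward model of the two detection arms:
#' `i_p = h (*) [t (s e_p) + s e_s]` and `i_s = h (*) [t (s e_s) + s e_p]`
#' with circular FFT convolution. Equivalently each arm sees the sample under
#' a single effective sinusoidal pattern of contrast
#' `n = m (t-1)/(t+1)`; the pair sums to a scaled widefield image.
#'
#' @param s sample volume (non-negative array)
#' @param params a [pattern_params()] (uses `raw_mod` and `pol_ratio`)
#' @param h PSF on the same grid (lattice-centred, from [make_psf()])
#' @param grid a [grid_spec()] matching `s` and `h`
#' @return list with arrays `i_p` and `i_s`
#' @export
form_raw_pair <- function(s, params, h, grid) {
  if (!identical(dim(s), dim(h))) stop("sample and PSF grids differ")
  if (!identical(dim(s), as.integer(grid$shape))) {
    stop("sample shape does not match the grid spec")
  }
  t_ratio <- params$pol_ratio
  e <- excitation_patterns(params, grid)
  Hraw <- stats::fft(ifftshift3(h))
  list(i_p = conv_fft(t_ratio * (s * e$e_p) + s * e$e_s, Hraw),
       i_s = conv_fft(t_ratio * (s * e$e_s) + s * e$e_p, Hraw))
}

#' Apply Poisson shot noise at a given photon budget
#'
#' Scales the volume so its maximum equals `peak_photons`, then draws one
#' independent Poisson count per voxel with the scaled values as means. The
#' returned counts are *not* rescaled back. Reproducible: the RNG state is
#' local to the call and fully determined by `seed`.
#'
#' @param v non-negative volume
#' @param peak_photons expected photon count at the brightest voxel (> 0)
#' @param seed integer seed
#' @return array of Poisson counts (as doubles)
#' @export
add_poisson <- function(v, peak_photons, seed) {
  if (any(!is.finite(v))) stop("input volume contains non-finite values")
  if (any(v < 0)) stop("Poisson noise requires non-negative input values")
  if (peak_photons <= 0) stop("peak_photons must be positive")
  lam <- v * (peak_photons / max(v))
  counts <- with_local_seed(seed, stats::rpois(length(lam), lam))
  array(as.double(counts), dim(v))
}
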