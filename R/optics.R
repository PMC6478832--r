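#' Microscope optical configuration
#'
#' Bundles the parameters of the scalar diffraction model: objective numerical
#' aperture, immersion refractive index, emission and excitation wavelengths,
#' and the sampling voxel sizes. The refractive index here is the immersion
#' medium index, not to be confused with the modulation contrast `n` of an
#' illumination pattern.
#'
#' @param numerical_aperture objective NA (dimensionless, `0 < NA < refr_index`)
#' @param refr_index immersion refractive index
#' @param wavelength_em emission wavelength in nm
#' @param wavelength_exc excitation wavelength in nm
#' @param voxel_xy lateral voxel size in nm
#' @param voxel_z axial voxel size in nm
#' @return an object of class `optical_config`
#' @examples
#' cfg <- optical_config(1.49, 1.518, 520, 488, 40, 40)
#' lateral_cutoff(cfg, "emission")
#' @export
optical_config <- function(numerical_aperture, refr_index,
                           wavelength_em = 520, wavelength_exc = 488,
                           voxel_xy = 40, voxel_z = 40) {
  if (!is.numeric(numerical_aperture) || numerical_aperture <= 0) {
    stop("numerical_aperture must be > 0")
  }
  if (numerical_aperture >= refr_index) {
    stop("numerical_aperture must be strictly below the immersion index (got NA = ",
         numerical_aperture, ", n = ", refr_index, ")")
  }
  for (nm in c("wavelength_em", "wavelength_exc", "voxel_xy", "voxel_z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(nm, " must be a single strictly positive number")
    }
  }
  structure(
    list(numerical_aperture = numerical_aperture, refr_index = refr_index,
         wavelength_em = wavelength_em, wavelength_exc = wavelength_exc,
         voxel_xy = voxel_xy, voxel_z = voxel_z),
    class = "optical_config")
}

#' Sampling lattice description
#'
#' @param shape integer vector `(nz, ny, nx)`; every size must be even and
#'   at least 4 so the centred DC bin is well defined
#' @param voxel_xy,voxel_z voxel sizes in nm
#' @return an object of class `grid_spec` with the frequency bin widths
#'   (cycles/um) precomputed as `kstep` (order z, y, x)
#' @export
grid_spec <- function(shape, voxel_xy = 40, voxel_z = 40) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L) || any(shape %% 2L != 0L)) {
    stop("shape must be three even integers >= 4, ordered (nz, ny, nx)")
  }
  if (voxel_xy <= 0 || voxel_z <= 0) stop("voxel sizes must be positive")
  vox <- c(voxel_z, voxel_xy, voxel_xy)
  structure(
    list(shape = shape, voxel_xy = voxel_xy, voxel_z = voxel_z,
         kstep = 1 / (shape * vox / 1000)),
    class = "grid_spec")
}

#' Lateral (Abbe) cutoff frequency
#'
#' `2 NA / lambda` for the selected wavelength, in cycles/um.
#'
#' @param cfg an [optical_config()]
#' @param which `"emission"` or `"excitation"`
#' @return cutoff frequency in cycles/um
#' @export
lateral_cutoff <- function(cfg, which = c("emission", "excitation")) {
  which <- match.arg(which)
  lambda_um <- switch(which,
                      emission = cfg$wavelength_em,
                      excitation = cfg$wavelength_exc) / 1000
  2 * cfg$numerical_aperture / lambda_um
}

#' Axial resolution and confocal axial cutoff (Amos formula)
#'
#' The confocal axial resolution `dz = 0.64 lambda_em / (n - sqrt(n^2 - NA^2))`
#' and the corresponding axial cutoff frequency `1/dz`. This cutoff is the
#' reference against which recovered axial frequency ranges are expressed.
#'
#' @param cfg an [optical_config()]
#' @return list with `delta_z_nm` and `cutoff_cpum` (cycles/um)
#' @export
axial_confocal_cutoff <- function(cfg) {
  na <- cfg$numerical_aperture
  n <- cfg$refr_index
  if (na >= n) stop("axial cutoff undefined for NA >= refractive index")
  dz <- 0.64 * cfg$wavelength_em / (n - sqrt(n^2 - na^2))
  list(delta_z_nm = dz, cutoff_cpum = 1000 / dz)
}

#' Scalar pupil-integral widefield PSF
#'
#' For each defocus plane the circular pupil (radius `NA/lambda_em`) is given
#' the defocus phase `exp(2 pi i z sqrt((n/lambda)^2 - kr^2))`, inverse
#' transformed, and squared in magnitude. The result is centred on the lattice
#' (peak at `floor(dim/2)+1`) and normalized to unit total intensity. Each
#' defocus plane carries (almost) the same total energy — the physical origin
#' of the missing cone.
#'
#' @param cfg an [optical_config()]
#' @param grid a [grid_spec()]; the lateral voxel size must Nyquist-sample the
#'   emission cutoff (`voxel_xy <= 1/(2 k_c)`)
#' @return real 3-D array `(nz, ny, nx)`, non-negative, summing to 1
#' @export
make_psf <- function(cfg, grid) {
  kc <- lateral_cutoff(cfg, "emission")
  nyq <- 1000 / (2 * grid$voxel_xy)  # cycles/um
  if (kc > nyq) {
    stop("grid undersamples the emission cutoff: voxel_xy = ", grid$voxel_xy,
         " nm allows ", signif(nyq, 5), " cycles/um but the cutoff is ",
         signif(kc, 5), " cycles/um")
  }
  nz <- grid$shape[1]; ny <- grid$shape[2]; nx <- grid$shape[3]
  kx <- freq_axis(nx, grid$voxel_xy)
  ky <- freq_axis(ny, grid$voxel_xy)
  kr2 <- outer(ky^2, kx^2, `+`)                 # (ny, nx), DC-centred
  lambda_um <- cfg$wavelength_em / 1000
  kn <- cfg$refr_index / lambda_um              # medium wavenumber, cycles/um
  pupil <- kr2 <= (cfg$numerical_aperture / lambda_um)^2
  kz <- sqrt(pmax(kn^2 - kr2, 0))               # propagation constant
  cz <- nz %/% 2L + 1L
  h <- array(0, c(nz, ny, nx))
  shift2 <- c(ny %/% 2L, nx %/% 2L)
  for (iz in seq_len(nz)) {
    z_um <- (iz - cz) * grid$voxel_z / 1000
    P <- pupil * exp(2i * pi * z_um * kz)
    a <- stats::fft(circshift(P, -shift2), inverse = TRUE)
    h[iz, , ] <- circshift(Mod(a)^2, shift2)
  }
  h / sum(h)
}

#' Optical transfer function of a lattice-centred PSF
#'
#' Forward transform of the PSF with the DC bin centred. For a normalized PSF
#' the DC value is 1.
#'
#' @param h PSF array from [make_psf()] (peak at the lattice centre)
#' @return complex DC-centred array
#' @export
make_otf <- function(h) {
  fftshift3(stats::fft(ifftshift3(h)))
}

#' OTF support mask
#'
#' The frequency-space set Psi where the OTF magnitude exceeds a relative
#' floor: `|H(k)| > eps * max|H|`. Separates the numerically-zero region
#' (including the missing cone) from the passband.
#'
#' @param H OTF from [make_otf()]
#' @param eps relative threshold in (0, 1); default 1e-3
#' @return logical DC-centred array, symmetric under `k -> -k`, containing DC
#' @export
otf_support <- function(H, eps = 1e-3) {
  if (!is.numeric(eps) || eps <= 0 || eps >= 1) stop("eps must lie in (0, 1)")
  m <- max(Mod(H))
  if (m == 0) stop("degenerate OTF: all values are zero")
  Mod(H) > eps * m
}
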