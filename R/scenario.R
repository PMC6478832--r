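#' Default optical configuration
#'
#' High-NA oil-immersion configuration used throughout the in-silico
#' experiments: NA 1.49, immersion index 1.518, emission 520 nm, excitation
#' 488 nm, 40 nm voxels.
#'
#' @return an [optical_config()]
#' @export
default_optical_config <- function() {
  optical_config(numerical_aperture = 1.49, refr_index = 1.518,
                 wavelength_em = 520, wavelength_exc = 488,
                 voxel_xy = 40, voxel_z = 40)
}

#' Default simulation grid
#'
#' `128 x 8 x 256` voxels (z, y, x) at 40 nm isotropic sampling: Nyquist
#' samples both the emission and excitation lateral cutoffs while keeping an
#' end-to-end simulation plus reconstruction in the seconds range.
#'
#' @return a [grid_spec()]
#' @export
default_grid <- function() grid_spec(c(128L, 8L, 256L), voxel_xy = 40, voxel_z = 40)

#' Complete in-silico study description
#'
#' Collects everything needed to run a simulated ssOS experiment: optics, grid,
#' chirp phantom, and the illumination pattern. Defaults follow the in-silico
#' validation conditions: a 15 degree tilted chirp running from zero to
#' `f_max_frac` of the confocal axial cutoff, pattern frequency at 30% of the
#' lateral excitation cutoff (snapped to an integer frequency bin), raw pattern
#' contrast `m = 1` multiplexed at anisotropy `r = 0.4` (`t = 3`), so the
#' recorded structured-illumination contrast is 0.5.
#'
#' @param cfg an [optical_config()]
#' @param grid a [grid_spec()]
#' @param tilt_deg phantom tilt from the optical axis, degrees
#' @param f_max_frac phantom maximum frequency as a fraction of the confocal
#'   axial cutoff (0.5 for the noise study; 1 for the resolution study)
#' @param pattern_freq_frac pattern frequency as a fraction of the lateral
#'   excitation cutoff; values >= 0.5 degrade sectioning and trigger a warning
#' @param raw_mod raw pattern modulation contrast m
#' @param anisotropy fluorescence anisotropy r
#' @param phase_offset global pattern phase phi0, radians
#' @return object of class `ssos_scenario`
#' @export
ssos_scenario <- function(cfg = default_optical_config(), grid = default_grid(),
                          tilt_deg = 15, f_max_frac = 0.5,
                          pattern_freq_frac = 0.3, raw_mod = 1,
                          anisotropy = 0.4, phase_offset = 0) {
  if (pattern_freq_frac >= 0.5) {
    warning("pattern frequency at ", round(100 * pattern_freq_frac),
            "% of the lateral excitation cutoff; fractions below 50% give ",
            "the best optical sectioning")
  }
  ax <- axial_confocal_cutoff(cfg)
  kc_exc <- lateral_cutoff(cfg, "excitation")
  nx <- grid$shape[3]
  freq_px <- as.integer(round(pattern_freq_frac * kc_exc /
                                grid$kstep[3]))
  if (freq_px < 1L) stop("pattern frequency snaps to zero bins on this grid")
  t_ratio <- anisotropy_ratio(anisotropy)
  params <- pattern_params(freq_px = freq_px, phase_offset = phase_offset,
                           raw_mod = raw_mod, pol_ratio = t_ratio)
  structure(
    list(cfg = cfg, grid = grid,
         chirp = chirp_spec(f_max = f_max_frac * ax$cutoff_cpum,
                            tilt_deg = tilt_deg, grid = grid),
         params = params,
         f_max_frac = f_max_frac, pattern_freq_frac = pattern_freq_frac),
    class = "ssos_scenario")
}

#' Run the forward model of a scenario
#'
#' Builds the phantom, PSF and OTF, and the noise-free polarization-mixed raw
#' pair. The heavy pieces (PSF/OTF) are computed once here so repeated noisy
#' realizations can reuse them.
#'
#' @param scenario an [ssos_scenario()]
#' @return list with `s` (ground truth), `h`, `H`, `i_p`, `i_s`, and the
#'   scenario itself
#' @export
simulate_scenario <- function(scenario) {
  s <- make_chirp_sample(scenario$chirp)
  h <- make_psf(scenario$cfg, scenario$grid)
  H <- make_otf(h)
  pair <- form_raw_pair(s, scenario$params, h, scenario$grid)
  list(s = s, h = h, H = H, i_p = pair$i_p, i_s = pair$i_s,
       scenario = scenario)
}
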