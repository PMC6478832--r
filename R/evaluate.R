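# Reconstruction quality metrics on the chirp phantom: depth-resolved stripe
# modulation, the frequency up to which modulation survives a threshold, and
# the photon-budget sweep.

# Sample a volume along the tilted chirp axis through the lattice centre
# (linear interpolation along x at the central y row). Returns one value per
# depth row.
chirp_line <- function(v, spec) {
  g <- spec$grid
  nz <- g$shape[1]; ny <- g$shape[2]; nx <- g$shape[3]
  th <- spec$tilt_deg * pi / 180
  dz <- g$voxel_z / 1000; dx <- g$voxel_xy / 1000
  cz <- nz %/% 2L + 1L
  cx <- nx %/% 2L + 1L
  cy <- max(ny %/% 2L, 1L)
  xpos <- (cx - 1) + (seq_len(nz) - cz) * dz * tan(th) / dx
  vapply(seq_len(nz), function(iz) {
    xf <- min(max(xpos[iz], 0), nx - 1)
    i0 <- floor(xf); frac <- xf - i0
    a <- v[iz, cy, i0 + 1L]
    b <- v[iz, cy, min(i0 + 2L, nx)]
    (1 - frac) * a + frac * b
  }, numeric(1))
}

# Shared profile engine. `line` is the tilted-axis profile (one value per
# depth row); `noise_sd`, when given, is the per-row standard deviation of the
# profile across noisy realizations: a row only counts as modulated if the
# stripe amplitude exceeds the noise level (amplitude >= mean noise sd in the
# window), i.e. the stripes must stand out of a single realization's noise.
profile_from_line <- function(line, spec, threshold, noise_sd = NULL) {
  g <- spec$grid
  nz <- g$shape[1]
  th <- spec$tilt_deg * pi / 180
  dz <- g$voxel_z / 1000
  zrel <- (seq_len(nz) - 1) * dz
  f <- spec$f_max * zrel / ((nz - 1) * dz)   # local frequency per depth row
  line <- pmax(line, 0)                      # clip reconstruction ringing
  period_rows <- cos(th) / (pmax(f, .Machine$double.eps) * dz)
  modulation <- rep(NA_real_, nz)
  for (iz in seq_len(nz)) {
    w <- max(8L, ceiling(period_rows[iz]))
    if (w > nz %/% 2L) next                  # local period unmeasurable
    lo <- iz - w %/% 2L
    lo <- min(max(lo, 1L), nz - w + 1L)      # keep the window inside the volume
    seg <- line[lo:(lo + w - 1L)]
    mx <- max(seg); mn <- min(seg)
    m <- if (mx + mn > 0) (mx - mn) / (mx + mn) else 0
    if (!is.null(noise_sd)) {
      amp <- (mx - mn) / 2
      if (amp < mean(noise_sd[lo:(lo + w - 1L)])) m <- 0
    }
    modulation[iz] <- m
  }
  meas <- which(!is.na(modulation))
  cutoff <- 0
  if (length(meas)) {
    below <- modulation[meas] < threshold
    run <- rle(below)
    ends <- cumsum(run$lengths)
    sustained <- which(run$values & run$lengths >= 3L)
    if (length(sustained)) {
      first_bad <- ends[sustained[1]] - run$lengths[sustained[1]] + 1L
      cutoff <- if (first_bad > 1L) f[meas[first_bad - 1L]] else 0
    } else {
      cutoff <- f[meas[length(meas)]]
    }
  }
  structure(
    data.frame(depth_nm = zrel * 1000, freq_cpum = f, modulation = modulation),
    cutoff_cpum = cutoff, threshold = threshold,
    class = c("ssos_profile", "data.frame"))
}

#' Depth-resolved modulation profile of a chirp-phantom volume
#'
#' Samples the volume along the tilted chirp axis through the lattice centre
#' and, for every depth row, measures the local stripe modulation
#' `(max - min)/(max + min)` inside a window of one local period (minimum 8
#' voxels; negative reconstruction ringing is clipped at zero first). Rows
#' whose local period does not fit in half the depth range are unmeasurable
#' and reported as `NA`.
#'
#' The cutoff is the local frequency up to which modulation stays at or above
#' `threshold`: the first *sustained* drop (at least 3 consecutive measurable
#' rows below threshold) ends the recovered range; shorter dips are ignored.
#' With no measurable row above threshold the cutoff is 0; with no sustained
#' drop it is the highest measurable frequency.
#'
#' @param v volume on the phantom grid
#' @param spec the [chirp_spec()] that generated the phantom
#' @param threshold modulation threshold defining the cutoff (default 0.25)
#' @return object of class `ssos_profile`: a data.frame with `depth_nm`,
#'   `freq_cpum`, `modulation`, plus attributes `cutoff_cpum` and `threshold`
#' @export
modulation_profile <- function(v, spec, threshold = 0.25) {
  g <- spec$grid
  if (!identical(dim(v), as.integer(g$shape))) {
    stop("volume does not match the phantom grid (expected ",
         paste(g$shape, collapse = " x "), ")")
  }
  profile_from_line(chirp_line(v, spec), spec, threshold)
}

#' Fraction of the confocal axial frequency range recovered
#'
#' The profile's cutoff frequency divided by the confocal axial cutoff `1/dz`
#' of the configuration (see [axial_confocal_cutoff()]).
#'
#' @param profile a [modulation_profile()] result
#' @param cfg an [optical_config()]
#' @return non-negative fraction (1 = full confocal range)
#' @export
recovered_fraction <- function(profile, cfg) {
  max(attr(profile, "cutoff_cpum"), 0) / axial_confocal_cutoff(cfg)$cutoff_cpum
}

#' Photon-budget noise sweep
#'
#' For each photon level: scale the noise-free raw pair, draw Poisson counts,
#' reconstruct with pattern parameters estimated from the noisy data, and
#' extract the tilted-axis line profile. Per level the sweep aggregates the
#' mean and standard deviation of the profile over the repeats and derives the
#' recovered cutoff from the mean profile, counting a depth as recovered only
#' where the stripe amplitude also exceeds the per-realization noise standard
#' deviation — stripes buried in a single exposure's noise do not count, no
#' matter how many repeats are averaged.
#'
#' Repeats use sub-seeds drawn deterministically from the master seed, so the
#' whole sweep is bit-reproducible. A repeat whose reconstruction fails (e.g.
#' pattern lost in noise) is tallied in `failures` and contributes a flat zero
#' profile.
#'
#' @param levels photon counts at the brightest voxel (sorted internally)
#' @param repeats noisy realizations per level (>= 2)
#' @param seed master seed
#' @param scenario an [ssos_scenario()]
#' @param opts a [recon_options()]; `wiener_w = NA` (the default here)
#'   estimates the regularizer per realization from the data as the
#'   noise-to-signal power ratio
#' @param threshold modulation cutoff threshold
#' @param subseeds optional integer matrix `(repeats, length(levels))`
#'   overriding the derived sub-seeds (e.g. to force identical draws)
#' @return object of class `ssos_sweep`: photon `levels`, per-level mean and
#'   sd line profiles (columns of `mean_profile`/`sd_profile`), per-level
#'   `cutoff_cpum` and `cutoff_fraction` (of the phantom maximum), failure
#'   counts, and the frequency axis `freq_cpum`
#' @export
noise_sweep <- function(levels = c(1e2, 1e3, 1e4, 1e5), repeats = 50L,
                        seed = 1L, scenario = ssos_scenario(),
                        opts = recon_options(wiener_w = NA),
                        threshold = 0.25, subseeds = NULL) {
  if (repeats < 2L) stop("repeats must be >= 2")
  levels <- sort(levels)
  fwd <- simulate_scenario(scenario)
  if (is.null(subseeds)) {
    subseeds <- with_local_seed(seed, matrix(
      sample.int(.Machine$integer.max - 1L, repeats * length(levels)),
      nrow = repeats))
  }
  stopifnot(nrow(subseeds) == repeats, ncol(subseeds) == length(levels))
  nz <- scenario$grid$shape[1]
  failures <- integer(length(levels))
  mean_prof <- sd_prof <- matrix(NA_real_, nz, length(levels))
  cutoff <- numeric(length(levels))
  profiles <- vector("list", length(levels))
  for (il in seq_along(levels)) {
    lines <- matrix(0, nz, repeats)
    for (ir in seq_len(repeats)) {
      res <- tryCatch({
        ip <- add_poisson(fwd$i_p, levels[il], subseeds[ir, il])
        is_ <- add_poisson(fwd$i_s, levels[il], subseeds[ir, il] + 1L)
        rec <- ssos_reconstruct(ip, is_, fwd$h, opts, H = fwd$H)
        # photon levels differ in absolute counts; normalize each repeat to
        # its mean so profiles are comparable across levels and repeats
        line <- chirp_line(rec$s_os, scenario$chirp)
        line / max(mean(line), .Machine$double.xmin)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[il] <- failures[il] + 1L
      } else {
        lines[, ir] <- res
      }
    }
    mean_prof[, il] <- rowMeans(lines)
    sd_prof[, il] <- apply(lines, 1, stats::sd)
    prof <- profile_from_line(mean_prof[, il], scenario$chirp, threshold,
                              noise_sd = sd_prof[, il])
    profiles[[il]] <- prof
    cutoff[il] <- attr(prof, "cutoff_cpum")
  }
  structure(
    list(levels = levels, repeats = repeats, seed = seed,
         freq_cpum = scenario$chirp$f_max * ((seq_len(nz) - 1) / (nz - 1)),
         mean_profile = mean_prof, sd_profile = sd_prof,
         profiles = profiles,
         cutoff_cpum = cutoff,
         cutoff_fraction = cutoff / scenario$chirp$f_max,
         failures = failures, scenario = scenario),
    class = "ssos_sweep")
}

#' @export
print.ssos_sweep <- function(x, ...) {
  cat("ssOS noise sweep:", x$repeats, "repeats per level\n")
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %8g photons: recovered cutoff %.3f cycles/um (%.0f%% of phantom max), %d failures\n",
                x$levels[i], x$cutoff_cpum[i],
                100 * x$cutoff_fraction[i], x$failures[i]))
  }
  invisible(x)
}
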