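# ssOS reconstruction core: deconvolve the widefield and structured spectra,
# subtract the weighted pattern-shifted widefield copies, shift the isolated
# cone components back onto the axial axis, average where both sides
# contribute, and recombine with the widefield spectrum.

#' Reconstruction options
#'
#' @param deconv_method `"wiener"` (Gaussian-noise regime) or
#'   `"richardson_lucy"` (Poisson regime)
#' @param wiener_w Wiener regularizer w (> 0). Default 1e-3 suits photon-noisy
#'   data; use ~1e-6 for noise-free validation. `NA` estimates w per call as
#'   the noise-to-signal power ratio of the (photon-count) image: flat Poisson
#'   noise power equals the total count, signal power is the mean squared
#'   spectrum magnitude over the OTF support
#' @param rl_iterations Richardson-Lucy iteration count (>= 1)
#' @param support_eps relative OTF support threshold for Psi (see
#'   [otf_support()])
#' @param n_min minimum admissible modulation contrast: below this the
#'   division by `n` in the cone recovery is numerically meaningless
#' @param enforce_real drop the (numerically tiny) imaginary part of the final
#'   inverse transform
#' @return object of class `recon_options`
#' @export
recon_options <- function(deconv_method = c("wiener", "richardson_lucy"),
                          wiener_w = 1e-3, rl_iterations = 20L,
                          support_eps = 1e-3, n_min = 0.01,
                          enforce_real = TRUE) {
  deconv_method <- match.arg(deconv_method)
  if (!is.na(wiener_w) && wiener_w <= 0) stop("wiener_w must be positive")
  if (rl_iterations < 1) stop("rl_iterations must be >= 1")
  if (n_min <= 0) stop("n_min must be positive")
  structure(list(deconv_method = deconv_method, wiener_w = wiener_w,
                 rl_iterations = as.integer(rl_iterations),
                 support_eps = support_eps, n_min = n_min,
                 enforce_real = enforce_real),
            class = "recon_options")
}

#' Widefield image from the pi-shifted raw pair
#'
#' Because the two patterns sum to a spatial constant, the average of the raw
#' pair is a plain widefield image; either raw member serves directly as the
#' structured illumination image.
#'
#' @param i_p,i_s the raw pair (same grid)
#' @return widefield volume `(i_p + i_s)/2`
#' @export
widefield_from_pair <- function(i_p, i_s) {
  if (!identical(dim(i_p), dim(i_s))) stop("raw pair grids differ")
  (i_p + i_s) / 2
}

#' Deconvolve an image against the OTF, truncated to the OTF support
#'
#' Wiener: `S = I conj(H) / (|H|^2 + w)`, zeroed outside Psi. Richardson-Lucy:
#' multiplicative updates in real space (flux-preserving, non-negative),
#' transformed and zeroed outside Psi afterwards.
#'
#' @param i image volume
#' @param H OTF from [make_otf()]
#' @param opts a [recon_options()]
#' @param psi optional precomputed support mask; computed from `H` at
#'   `opts$support_eps` when missing
#' @return complex DC-centred spectrum, zero outside Psi
#' @export
deconvolve <- function(i, H, opts = recon_options(), psi = NULL) {
  if (!identical(dim(i), dim(H))) stop("image and OTF grids differ")
  if (is.null(psi)) psi <- otf_support(H, opts$support_eps)
  if (opts$deconv_method == "wiener") {
    I0 <- vol_fft(i)
    w <- opts$wiener_w
    if (is.na(w)) {
      # Poisson noise-to-signal ratio: flat noise power = total count
      w <- max(sum(pmax(i, 0)) / mean(Mod(I0[psi])^2), .Machine$double.eps)
    }
    S <- I0 * Conj(H) / (Mod(H)^2 + w)
  } else {
    h <- pmax(Re(spec_ifft(H)), 0)
    h <- fftshift3(h)                    # lattice-centred PSF
    Hraw <- stats::fft(ifftshift3(h))
    HrawC <- Conj(Hraw)
    est <- array(mean(pmax(i, 0)), dim(i))
    obs <- pmax(i, 0)
    tiny <- .Machine$double.eps * max(obs)
    for (it in seq_len(opts$rl_iterations)) {
      blur <- pmax(conv_fft(est, Hraw), tiny)
      est <- est * pmax(conv_fft(obs / blur, HrawC), 0)
    }
    S <- vol_fft(est)
  }
  S[!psi] <- 0
  S
}

# Row-wise circular cross-correlation along kx for all lags at once:
# C[d+1] = sum_k A(k) Conj(B(k - d x_hat)). A and B are (nz, ny, nx) arrays.
xline_crosscorr <- function(A, B) {
  d <- dim(A)
  Am <- t(matrix(A, d[1] * d[2], d[3]))   # (nx, nrows)
  Bm <- t(matrix(B, d[1] * d[2], d[3]))
  cc <- stats::mvfft(stats::mvfft(Am) * Conj(stats::mvfft(Bm)),
                     inverse = TRUE) / d[3]
  rowSums(cc)
}

#' Estimate the illumination pattern from the raw pair
#'
#' Both deconvolved spectra carry identical Wiener weighting, so their
#' difference isolates the pattern-shifted spectral copies. The pattern
#' frequency is located (at integer bin precision, along kx) as the strongest
#' off-DC peak of the cross-correlation of that difference with the shifted
#' deconvolved widefield spectrum; the complex weight at the peak gives the
#' modulation contrast `n` (magnitude, clamped to `[0, 1]`) and the phase
#' offset `phi0`.
#'
#' @param i_p,i_s the raw pair
#' @param H OTF
#' @param opts a [recon_options()]
#' @return a [pattern_params()] with `freq_px`, `phase_offset` and
#'   `mod_contrast` filled from the data (`raw_mod`/`pol_ratio` are `NA`:
#'   they are not identifiable from a single arm)
#' @export
estimate_pattern <- function(i_p, i_s, H, opts = recon_options()) {
  psi <- otf_support(H, opts$support_eps)
  i0 <- widefield_from_pair(i_p, i_s)
  S0 <- deconvolve(i0, H, opts, psi)
  S1 <- deconvolve(i_p, H, opts, psi)
  D <- S1 - S0
  nx <- dim(S0)[3]
  num <- xline_crosscorr(D, S0)
  den <- Re(xline_crosscorr(array(as.double(psi), dim(psi)),
                            array(Mod(S0)^2, dim(S0))))
  # The peak is located on the raw cross-correlation |num|: the normalized
  # weight num/den is meaningless at lags where almost no shifted widefield
  # energy remains inside Psi (den ~ 0).
  cand <- 2:(nx %/% 2L)                   # positive lags, off-DC
  d_star <- cand[which.max(Mod(num[cand]))] - 1L
  if (den[d_star + 1L] <= 0) {
    stop("pattern not found: no off-DC modulation peak above the noise floor")
  }
  # Joint least squares for the two copy weights: the +p and -p copies are
  # correlated through the sample spectrum, so a single-lag correlation is
  # biased by cross-talk. Solve D ~ a S0(k-p) + b S0(k+p), restricted to bins
  # whose OTF weight is solid at k and both shifted positions — near the
  # support edge the Wiener factors of D and S0 differ and bias the weight.
  h_ok <- Mod(H) >= 10 * opts$support_eps * max(Mod(H))
  fit <- h_ok & shift_kx(h_ok, d_star) & shift_kx(h_ok, -d_star)
  X <- shift_kx(S0, d_star) * fit
  Y <- shift_kx(S0, -d_star) * fit
  D <- D * fit
  gxx <- sum(Mod(X)^2); gyy <- sum(Mod(Y)^2)
  gxy <- sum(X * Conj(Y))
  dx <- sum(D * Conj(X)); dy <- sum(D * Conj(Y))
  det <- gxx * gyy - Mod(gxy)^2
  if (Mod(det) <= .Machine$double.eps * gxx * gyy) {
    stop("pattern not found: degenerate copy overlap at the detected lag")
  }
  a <- (dx * gyy - dy * gxy) / det
  b <- (dy * gxx - dx * Conj(gxy)) / det
  # a ~ (n/2) e^{+i phi0}, b ~ (n/2) e^{-i phi0}: each pattern harmonic
  # carries half the amplitude-to-offset contrast n.
  w <- (a + Conj(b)) / 2
  n_est <- 2 * Mod(w)
  if (!is.finite(n_est) || n_est < opts$n_min) {
    stop("pattern not found: no off-DC modulation peak above the noise floor")
  }
  pattern_params(freq_px = d_star,
                 phase_offset = Arg(w),
                 raw_mod = NA, pol_ratio = NA,
                 mod_contrast = min(n_est, 1))
}

#' Subtract weighted shifted widefield copies from the SI spectrum
#'
#' `S1' = S1 - S0 - (n/2) e^{+i phi0} S0(k - p) - (n/2) e^{-i phi0} S0(k + p)`,
#' with the shifts as exact circular integer-bin shifts along kx. The weight of
#' each shifted copy is half the amplitude-to-offset contrast `n` (a pattern
#' `1 + n cos` splits into two harmonics of amplitude `n/2`). What remains is
#' the spectral content of the shifted copies that fell *outside* the OTF
#' support at its original position — the translated missing-cone information.
#'
#' @param S1 deconvolved structured-illumination spectrum
#' @param S0 deconvolved widefield spectrum
#' @param params a [pattern_params()] (needs `freq_px`, `phase_offset`,
#'   `mod_contrast`)
#' @param n_min modulation guard; contrasts below it are rejected
#' @return complex spectrum S1'
#' @export
subtract_components <- function(S1, S0, params, n_min = 0.01) {
  n <- params$mod_contrast
  if (is.na(n) || n < n_min) {
    stop("modulation contrast ", format(n), " is below n_min = ", n_min)
  }
  p <- params$freq_px
  phi <- params$phase_offset
  S1 - S0 - (n / 2) * exp(1i * phi) * shift_kx(S0, p) -
    (n / 2) * exp(-1i * phi) * shift_kx(S0, -p)
}

#' Overlap region of the shifted OTF supports
#'
#' `Omega = Psi(k - p) AND Psi(k + p)`: the region where residual fragments
#' translated beyond the cutoff have been excluded, so the cone components in
#' S1' can be trusted before shifting back.
#'
#' @param psi OTF support mask
#' @param params a [pattern_params()]
#' @return logical mask Omega
#' @export
overlap_mask <- function(psi, params) {
  p <- params$freq_px
  shift_kx(psi, p) & shift_kx(psi, -p)
}

#' Recover the missing-cone component
#'
#' The two cone copies in `S1'` are shifted back by -p and +p and unweighted
#' by `2/(n e^{+i phi0})` and `2/(n e^{-i phi0})` respectively. Each copy is
#' first restricted to the region where it is trustworthy: inside Psi (it was
#' recorded) *and* inside the other copy's shifted support (there the other
#' copy's contribution was cancelled exactly by the subtraction, so residual
#' fragments translated beyond the cutoff cannot leak through). Where both
#' shifted copies contribute after shifting back, they are averaged; where
#' only one contributes, it is taken alone. The result is finally restricted
#' to the bins *outside* Psi — its role is to fill what the widefield
#' spectrum cannot provide.
#'
#' @param S1p spectrum S1' from [subtract_components()]
#' @param psi OTF support mask
#' @param params a [pattern_params()]
#' @param n_min modulation guard for the division
#' @return complex spectrum, zero inside Psi
#' @export
recover_cone <- function(S1p, psi, params, n_min = 0.01) {
  n <- params$mod_contrast
  if (is.na(n) || n < n_min) {
    stop("modulation contrast ", format(n), " is below n_min = ", n_min)
  }
  p <- params$freq_px
  phi <- params$phase_offset
  mask_a <- psi & shift_kx(psi, -p)   # +p copy clean: k in Psi, k + p in Psi
  mask_b <- psi & shift_kx(psi, p)    # -p copy clean: k in Psi, k - p in Psi
  A <- shift_kx(S1p * mask_a, -p) * (2 / (n * exp(1i * phi)))
  B <- shift_kx(S1p * mask_b, p) * (2 / (n * exp(-1i * phi)))
  inA <- shift_kx(mask_a, -p)
  inB <- shift_kx(mask_b, p)
  both <- inA & inB
  out <- array(0 + 0i, dim(S1p))
  out[both] <- (A[both] + B[both]) / 2
  onlyA <- inA & !inB
  onlyB <- inB & !inA
  out[onlyA] <- A[onlyA]
  out[onlyB] <- B[onlyB]
  out[psi] <- 0
  out
}

#' Recombine widefield and recovered cone spectra
#'
#' `S_OS = S0 inside Psi + cone component outside Psi`; the supports are
#' disjoint by construction and this is asserted. The sectioned image is the
#' real part of the inverse transform; the relative imaginary residual energy
#' is reported as a diagnostic.
#'
#' @param S0 deconvolved widefield spectrum (zero outside Psi)
#' @param Sbar recovered cone spectrum (zero inside Psi)
#' @param psi OTF support mask
#' @return list with `S_OS`, `s_os`, and `imag_residual`
#' @export
combine_spectra <- function(S0, Sbar, psi) {
  if (any(Mod(Sbar[psi]) > 0)) {
    stop("internal error: cone component overlaps the OTF support")
  }
  if (any(Mod(S0[!psi]) > 0)) {
    stop("internal error: widefield spectrum has energy outside its support")
  }
  S_OS <- S0 + Sbar
  full <- spec_ifft(S_OS, real = FALSE)
  tot <- sum(Mod(full)^2)
  imag_res <- if (tot > 0) sum(Im(full)^2) / tot else 0
  list(S_OS = S_OS, s_os = Re(full), imag_residual = imag_res)
}

# Prefix stage names onto propagated errors.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Full ssOS reconstruction
#'
#' Orchestrates the pipeline: widefield from the pair, deconvolution of the
#' widefield and structured images, pattern estimation (unless `params` is
#' supplied), weighted spectral subtraction, overlap masking, cone recovery,
#' and recombination. Deterministic given inputs and options.
#'
#' @param i_p,i_s the pi-shifted raw pair
#' @param h PSF on the same grid (lattice-centred)
#' @param opts a [recon_options()]
#' @param params optional known [pattern_params()]; estimated from the data
#'   when missing
#' @param H optional precomputed OTF (from [make_otf()])
#' @return object of class `ssos_recon`: `s_os`, the spectra bundle
#'   (`S_0`, `S_1`, `S_1p`, `S_1bar`, `S_OS`), masks (`psi`, `omega`), the
#'   `params` used, and `diagnostics` (imaginary residual energy, cone-fill
#'   voxel count)
#' @export
ssos_reconstruct <- function(i_p, i_s, h, opts = recon_options(),
                             params = NULL, H = NULL) {
  if (!identical(dim(i_p), dim(i_s)) || !identical(dim(i_p), dim(h))) {
    stop("stage input: raw pair and PSF must share one grid")
  }
  if (is.null(H)) H <- run_stage("otf", make_otf(h))
  psi <- run_stage("support", otf_support(H, opts$support_eps))
  i0 <- run_stage("widefield", widefield_from_pair(i_p, i_s))
  S0 <- run_stage("deconvolve widefield", deconvolve(i0, H, opts, psi))
  S1 <- run_stage("deconvolve si", deconvolve(i_p, H, opts, psi))
  if (is.null(params)) {
    params <- run_stage("estimate pattern", estimate_pattern(i_p, i_s, H, opts))
  }
  S1p <- run_stage("subtract", subtract_components(S1, S0, params, opts$n_min))
  omega <- run_stage("overlap", overlap_mask(psi, params))
  Sbar <- run_stage("recover cone",
                    recover_cone(S1p, psi, params, opts$n_min))
  comb <- run_stage("combine", combine_spectra(S0, Sbar, psi))
  structure(
    list(s_os = comb$s_os,
         spectra = list(S_0 = S0, S_1 = S1, S_1p = S1p, S_1bar = Sbar,
                        S_OS = comb$S_OS),
         masks = list(psi = psi, omega = omega),
         params = params,
         diagnostics = list(
           imag_residual = comb$imag_residual,
           cone_fill = sum(Mod(Sbar) > 0 & !psi))),
    class = "ssos_recon")
}

#' @export
print.ssos_recon <- function(x, ...) {
  cat("ssOS reconstruction\n")
  cat(sprintf("  grid: %s (z, y, x)\n", paste(dim(x$s_os), collapse = " x ")))
  cat(sprintf("  pattern: p = %d bins, phi0 = %.4f rad, n = %.4f\n",
              x$params$freq_px, x$params$phase_offset, x$params$mod_contrast))
  cat(sprintf("  cone-fill: %d bins; imaginary residual energy: %.2e\n",
              x$diagnostics$cone_fill, x$diagnostics$imag_residual))
  invisible(x)
}

#' Three-phase homodyne OS-SIM baseline
#'
#' `i_OS = sqrt((i1-i2)^2 + (i1-i3)^2 + (i2-i3)^2)` for three frames under the
#' same pattern frequency at distinct phases. Non-linear: the geometric sum is
#' not shift-invariant, so no PSF can be defined for the result. Serves as the
#' classical baseline the linear ssOS pipeline is measured against.
#'
#' @param i_1,i_2,i_3 three raw frames on one grid
#' @return non-negative sectioned volume
#' @export
homodyne_os_sim <- function(i_1, i_2, i_3) {
  if (!identical(dim(i_1), dim(i_2)) || !identical(dim(i_1), dim(i_3))) {
    stop("the three frames must share one grid")
  }
  sqrt((i_1 - i_2)^2 + (i_1 - i_3)^2 + (i_2 - i_3)^2)
}

#' Emulate an ssOS raw pair from a three-phase SIM acquisition
#'
#' The phase-0 frame is used directly as `i_p`; the two remaining
#' phase-stepped frames (2pi/3 and 4pi/3) are averaged, which by
#' `cos(a + 2pi/3) + cos(a + 4pi/3) = -cos(a)` yields a frame with the same
#' wave-vector, phase shifted by pi, and modulation halved. The halved
#' modulation is returned as a diagnostic; it does not enter the
#' reconstruction because the contrast is estimated from `i_p` alone.
#'
#' @param i_1,i_2,i_3 frames at pattern phases 0, 2pi/3, 4pi/3
#' @return list with `i_p`, `i_s`, and `modulation_ratio` (0.5: the contrast
#'   of `i_s` relative to `i_p`)
#' @export
emulate_from_sim <- function(i_1, i_2, i_3) {
  if (missing(i_2) || missing(i_3)) stop("three phase frames are required")
  if (!identical(dim(i_1), dim(i_2)) || !identical(dim(i_1), dim(i_3))) {
    stop("the three frames must share one grid")
  }
  list(i_p = i_1, i_s = (i_2 + i_3) / 2, modulation_ratio = 0.5)
}
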