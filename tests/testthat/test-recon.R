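# The reduced-grid forward model is shared across blocks (deterministic).
fwd <- cached_forward()
g <- small_grid()
opts_nf <- recon_options(wiener_w = 1e-6)   # noise-free validation settings
psi <- otf_support(fwd$H)
p_true <- fwd$scenario$params$freq_px
n_true <- fwd$scenario$params$mod_contrast
scale_wf <- (fwd$scenario$params$pol_ratio + 1) /
  (1 + fwd$scenario$params$raw_mod)        # widefield scale of the raw pair

test_that("pair average is a pattern-free widefield image and is linear", {
  i0 <- widefield_from_pair(fwd$i_p, fwd$i_s)
  # the pi-shifted patterns cancel exactly: i0 is the blurred sample scaled
  wf <- scale_wf * conv_ref(fwd$s, fwd$h)
  expect_lt(max(abs(i0 - wf)) / max(i0), 1e-9)
  expect_identical(widefield_from_pair(fwd$i_p, fwd$i_p), fwd$i_p)
  expect_equal(widefield_from_pair(2.5 * fwd$i_p, 2.5 * fwd$i_s), 2.5 * i0)
  expect_error(widefield_from_pair(fwd$i_p, fwd$i_s[1:10, , ]), "grid")
})

test_that("pattern parameters are recovered exactly on noise-free data", {
  pp <- pattern_params(freq_px = 12L, phase_offset = 0.7, raw_mod = 1,
                       pol_ratio = 3)       # effective n = 0.5
  pair <- form_raw_pair(fwd$s, pp, fwd$h, g)
  est <- estimate_pattern(pair$i_p, pair$i_s, fwd$H, opts_nf)
  expect_identical(est$freq_px, 12L)
  expect_lt(abs(est$phase_offset - 0.7), 0.05)
  expect_lt(abs(est$mod_contrast - 0.5) / 0.5, 0.10)
})

test_that("pattern frequency survives photon noise at 1e4 peak counts", {
  hits <- 0L
  opts <- recon_options(wiener_w = NA)
  for (r in seq_len(50)) {
    ip <- add_poisson(fwd$i_p, 1e4, seed = r)
    is_ <- add_poisson(fwd$i_s, 1e4, seed = 5000L + r)
    est <- tryCatch(estimate_pattern(ip, is_, fwd$H, opts),
                    error = function(e) NULL)
    if (!is.null(est) && est$freq_px == p_true) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("unmodulated input raises a pattern-not-found error", {
  flat <- pattern_params(freq_px = 9L, raw_mod = 0, pol_ratio = 3)
  pair <- form_raw_pair(fwd$s, flat, fwd$h, g)
  expect_error(estimate_pattern(pair$i_p, pair$i_s, fwd$H, opts_nf),
               "pattern not found")
})

test_that("Wiener deconvolution inverts the blur inside the support", {
  strong <- Mod(fwd$H) >= 0.01
  set.seed(5)
  v0 <- array(runif(prod(g$shape)), g$shape)
  V <- vol_fft(v0); V[!strong] <- 0
  v <- spec_ifft(V); v <- v - min(v) + 0.05 * diff(range(v))
  i <- conv_ref(v, fwd$h)
  S <- deconvolve(i, fwd$H, opts_nf, psi)
  expect_lt(rel_l2(S, vol_fft(v), strong), 0.01)
  expect_true(all(Mod(S[!psi]) == 0))
  # a delta PSF is an identity filter
  hd <- array(0, g$shape); hd[33, 5, 65] <- 1
  Sd <- deconvolve(i, make_otf(hd), recon_options(wiener_w = 1e-9))
  expect_lt(rel_l2(Sd, vol_fft(i)), 1e-6)
})

test_that("Richardson-Lucy stays non-negative and conserves flux", {
  i0 <- widefield_from_pair(fwd$i_p, fwd$i_s)
  opts_rl <- recon_options(deconv_method = "richardson_lucy",
                           rl_iterations = 15L)
  S <- deconvolve(i0, fwd$H, opts_rl, psi)
  dc <- dim(S) %/% 2L + 1L
  expect_equal(Re(S[dc[1], dc[2], dc[3]]) / sum(i0), 1, tolerance = 1e-3)
  expect_gt(min(spec_ifft(S)), -1e-6 * max(i0))
  expect_true(all(Mod(S[!psi]) == 0))
})

test_that("subtraction cancels everything a band-limited sample can offer", {
  pp <- fwd$scenario$params
  Z <- array(0 + 0i, g$shape)
  expect_true(all(Mod(subtract_components(Z, Z, pp)) == 0))
  # sample whose spectrum lies in Psi and both p-shifted supports: S1' ~ 0
  strong <- Mod(fwd$H) >= 0.01
  trip <- strong & shift_kx(strong, p_true) & shift_kx(strong, -p_true)
  set.seed(7)
  V <- vol_fft(array(runif(prod(g$shape)), g$shape))
  V[!trip] <- 0
  v <- spec_ifft(V); v <- v - min(v) + 0.05 * diff(range(v))
  pair <- form_raw_pair(v, pp, fwd$h, g)
  S0 <- deconvolve(widefield_from_pair(pair$i_p, pair$i_s), fwd$H, opts_nf, psi)
  S1 <- deconvolve(pair$i_p, fwd$H, opts_nf, psi)
  S1p <- subtract_components(S1, S0, pp)
  expect_lt(sum(Mod(S1p)^2) / sum(Mod(S1)^2), 1e-4)
  weak <- pattern_params(freq_px = p_true, raw_mod = 0.01, pol_ratio = 1.01)
  expect_error(subtract_components(S1, S0, weak), "n_min")
})

test_that("S1' carries exactly the translated out-of-support content", {
  S0 <- deconvolve(widefield_from_pair(fwd$i_p, fwd$i_s), fwd$H, opts_nf, psi)
  S1 <- deconvolve(fwd$i_p, fwd$H, opts_nf, psi)
  pp <- fwd$scenario$params
  S1p <- subtract_components(S1, S0, pp)
  # mask-constructed oracle: the +/-p copies where the unshifted position
  # falls outside Psi, weighted as the pattern harmonics
  Strue <- vol_fft(fwd$s) * scale_wf
  phi <- pp$phase_offset
  oracle <- (n_true / 2) * exp(1i * phi) * shift_kx(Strue, p_true) *
    shift_kx(!psi, p_true) * psi +
    (n_true / 2) * exp(-1i * phi) * shift_kx(Strue, -p_true) *
    shift_kx(!psi, -p_true) * psi
  strong <- Mod(fwd$H) >= 0.01
  expect_lt(rel_l2(S1p * strong, oracle * strong), 0.05)
  # off the oracle support (and away from edge bins) S1' is empty
  osup <- Mod(oracle) > 0
  expect_lt(sum(Mod(S1p[strong & !osup])^2) / sum(Mod(S1p)^2), 0.01)
})

test_that("overlap mask is the intersection of the shifted supports", {
  pp <- fwd$scenario$params
  om <- overlap_mask(psi, pp)
  expect_true(all(om <= shift_kx(psi, p_true)))
  expect_true(all(om <= shift_kx(psi, -p_true)))
  expect_identical(overlap_mask(psi, pattern_params(0L)), psi)
  refl <- ssos:::ifftshift3(om)
  d <- dim(om)
  expect_identical(ssos:::ifftshift3(om),
                   refl[c(1, d[1]:2), c(1, d[2]:2), c(1, d[3]:2)])
})

test_that("cone recovery restores the true spectrum outside the support", {
  rec <- ssos_reconstruct(fwd$i_p, fwd$i_s, fwd$h, opts_nf, H = fwd$H)
  Strue <- vol_fft(fwd$s) * scale_wf
  Sbar <- rec$spectra$S_1bar
  cone <- Mod(Sbar) > 0 & !psi
  expect_gt(sum(cone), 0)
  # judge accuracy away from division-amplified OTF-edge source bins
  Hm <- Mod(fwd$H)
  strong_src <- pmax(shift_kx(Hm, -p_true), shift_kx(Hm, p_true)) >= 0.01
  expect_lt(rel_l2(Sbar, Strue, cone & strong_src), 0.02)
  expect_lt(ssos:::conj_symmetry_residual(Sbar), 1e-9)
  expect_true(all(Mod(Sbar[psi]) == 0))
  # zero input recovers nothing
  z <- recover_cone(Sbar * 0, psi, fwd$scenario$params)
  expect_true(all(Mod(z) == 0))
})

test_that("recombination keeps supports disjoint and energies additive", {
  rec <- ssos_reconstruct(fwd$i_p, fwd$i_s, fwd$h, opts_nf, H = fwd$H)
  S0 <- rec$spectra$S_0
  Sbar <- rec$spectra$S_1bar
  comb <- combine_spectra(S0, Sbar, psi)
  expect_equal(sum(Mod(comb$S_OS)^2),
               sum(Mod(S0[psi])^2) + sum(Mod(Sbar[!psi])^2))
  expect_lt(comb$imag_residual, 1e-6)
  # degenerate cone: the result is exactly the deconvolved widefield image
  comb0 <- combine_spectra(S0, Sbar * 0, psi)
  expect_equal(comb0$s_os, spec_ifft(S0))
  # overlapping contributions are a programming error and must be caught
  bad <- Sbar; bad[psi] <- 1 + 0i
  expect_error(combine_spectra(S0, bad, psi), "overlap")
})

test_that("the pipeline is linear and shift-covariant", {
  pp <- fwd$scenario$params
  rec <- ssos_reconstruct(fwd$i_p, fwd$i_s, fwd$h, opts_nf, params = pp,
                          H = fwd$H)
  rec_scaled <- ssos_reconstruct(2.5 * fwd$i_p, 2.5 * fwd$i_s, fwd$h,
                                 opts_nf, params = pp, H = fwd$H)
  expect_lt(max(abs(rec_scaled$s_os - 2.5 * rec$s_os)) / max(abs(rec$s_os)),
            1e-6)
  # shifting the sample by one full pattern period shifts the reconstruction
  pp16 <- pattern_params(freq_px = 16L, phase_offset = 0.2, raw_mod = 1,
                         pol_ratio = 3)     # period = 128/16 = 8 voxels
  pair1 <- form_raw_pair(fwd$s, pp16, fwd$h, g)
  pair2 <- form_raw_pair(circshift(fwd$s, c(0, 0, 8)), pp16, fwd$h, g)
  r1 <- ssos_reconstruct(pair1$i_p, pair1$i_s, fwd$h, opts_nf, H = fwd$H)
  r2 <- ssos_reconstruct(pair2$i_p, pair2$i_s, fwd$h, opts_nf, H = fwd$H)
  expect_lt(max(abs(r2$s_os - circshift(r1$s_os, c(0, 0, 8)))) /
              max(abs(r1$s_os)), 1e-6)
})

test_that("pipeline errors carry their stage name", {
  expect_error(ssos_reconstruct(fwd$i_p, fwd$i_s[1:10, , ], fwd$h),
               "stage input")
  flat <- form_raw_pair(fwd$s, pattern_params(9L, raw_mod = 0), fwd$h, g)
  expect_error(ssos_reconstruct(flat$i_p, flat$i_s, fwd$h, opts_nf, H = fwd$H),
               "stage estimate pattern")
})

test_that("homodyne OS-SIM matches its closed form on a uniform sample", {
  m <- 0.5; p <- 10L
  mk <- function(phase) {
    e <- excitation_patterns(pattern_params(p, phase, raw_mod = m), g)$e_p
    conv_ref(e, fwd$h)
  }
  i1 <- mk(0); i2 <- mk(2 * pi / 3); i3 <- mk(4 * pi / 3)
  os <- homodyne_os_sim(i1, i2, i3)
  dc <- dim(fwd$H) %/% 2L + 1L
  amp <- m * Mod(fwd$H[dc[1], dc[2], dc[3] + p]) / (1 + m)
  # three 120-degree phases: the root-sum-square is the constant 3/sqrt(2) amp
  expect_lt(stats::sd(os) / mean(os), 1e-9)
  expect_equal(mean(os), amp * 3 / sqrt(2), tolerance = 1e-9)
  expect_true(all(homodyne_os_sim(i1, i2, i3) >= 0))
  expect_equal(max(homodyne_os_sim(i1, i1, i1)), 0)
  expect_error(homodyne_os_sim(i1, i2, i3[1:10, , ]), "grid")
})

test_that("three-phase emulation yields a pi-shifted half-modulation mate", {
  m <- 0.5; p <- 10L; phi <- 0.3
  mk <- function(phase) {
    e <- excitation_patterns(pattern_params(p, phase, raw_mod = m), g)$e_p
    conv_ref(fwd$s * e, fwd$h)
  }
  i1 <- mk(phi); i2 <- mk(phi + 2 * pi / 3); i3 <- mk(phi + 4 * pi / 3)
  em <- emulate_from_sim(i1, i2, i3)
  expect_identical(em$i_p, i1)
  expect_equal(em$modulation_ratio, 0.5)
  # cos(a + 2pi/3) + cos(a + 4pi/3) = -cos(a): same wave-vector, phase + pi,
  # modulation halved
  nx <- g$shape[3]
  x <- seq_len(nx) - 1
  line <- (1 - (m / 2) * cos(2 * pi * p * x / nx + phi)) / (1 + m)
  ref <- array(0, dim(fwd$s))
  for (iz in seq_len(g$shape[1])) {
    ref[iz, , ] <- matrix(line, g$shape[2], nx, byrow = TRUE)
  }
  expect_lt(rel_l2(em$i_s, conv_ref(fwd$s * ref, fwd$h)), 1e-9)
  # the emulated pair keeps the original wave-vector
  est <- estimate_pattern(em$i_p, em$i_s, fwd$H, opts_nf)
  expect_identical(est$freq_px, p)
  # constant frames collapse to identical members
  u <- array(1, dim(fwd$s))
  emc <- emulate_from_sim(u, u, u)
  expect_identical(emc$i_p, emc$i_s)
  expect_error(emulate_from_sim(i1, i2), "three")
})

test_that("spectra of real volumes stay conjugate-symmetric at every stage", {
  rec <- ssos_reconstruct(fwd$i_p, fwd$i_s, fwd$h, opts_nf, H = fwd$H)
  for (S in rec$spectra) {
    expect_lt(ssos:::conj_symmetry_residual(S), 1e-9)
  }
})
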