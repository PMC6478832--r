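# ssos — single-shot optical sectioning for structured illumination microscopy

Deconvolving a widefield fluorescence stack can only *guess* axial structure:
the 3-D optical transfer function (OTF) is zero inside a double cone around
the axial frequency axis (the **missing cone**), so out-of-focus haze is
mathematically indistinguishable from in-focus planes. `ssos` implements a
reconstruction that fills the missing cone from a **single exposure**: two
sinusoidal excitation patterns, π out of phase and coded in orthogonal
polarizations, are projected simultaneously; fluorescence anisotropy keeps
them distinguishable in the emission and a polarizing beam splitter records
the raw pair `i′`, `i″` at once. The package is aimed at microscopy-methods
researchers who want to study, validate, or extend this reconstruction in
silico, or run it on emulated data from a conventional 3-phase SIM
microscope.

## The model in brief

The average of the raw pair is a widefield image (the π-shifted patterns sum
to a constant); either member alone is a structured-illumination image. In
frequency space, after Wiener (or Richardson–Lucy) deconvolution and
truncation to the OTF support Ψ,

    S₀(k) = S(k)            on Ψ
    S₁(k) = S(k) + (n/2) e^{+iφ₀} S(k−p) + (n/2) e^{−iφ₀} S(k+p)   on Ψ,

where `p` is the pattern frequency, `φ₀` its phase, and
`n = m(t−1)/(t+1)` the recorded modulation contrast for raw grating contrast
`m` and polarization intensity ratio `t = (1+2r)/(1−r)` (anisotropy `r`;
`r = 0.4` gives the classic `t = 3` and, with `m = 1`, `n = 0.5`). The
pipeline subtracts the weighted, `±p`-shifted copies of `S₀` from `S₁`,
leaving exactly the sample content whose unshifted position fell *outside*
Ψ — translated missing-cone information — then shifts it back, unweights by
`2/(n e^{±iφ₀})`, averages where both copies contribute, and recombines:

    S_OS = S₀ |∈Ψ  +  S̄₁′ |∉Ψ .

Every step is linear; `p`, `φ₀`, `n` are estimated from the raw data at
frequency-bin precision. The three-phase homodyne baseline
`√((i₁−i₂)² + (i₁−i₃)² + (i₂−i₃)²)` and an emulation path that turns 3-phase
SIM stacks into ssOS pairs are included, as are the forward simulator
(scalar pupil-integral PSF/OTF, anisotropy mixing, Poisson noise) and the
evaluation tools (tilted frequency-chirp phantom, depth-resolved modulation
profiles with a 25% cutoff, photon-budget sweeps).

## Worked example

```r
library(ssos)
cfg <- default_optical_config()     # NA 1.49 oil, 520/488 nm, 40 nm voxels
ax  <- axial_confocal_cutoff(cfg)
# confocal axial resolution: 271.1 nm ; cutoff: 3.689 cycles/um

scen <- ssos_scenario()             # tilted chirp phantom + 50%-contrast pattern
fwd  <- simulate_scenario(scen)     # ground truth, PSF/OTF, noise-free raw pair
rec  <- ssos_reconstruct(fwd$i_p, fwd$i_s, fwd$h,
                         recon_options(wiener_w = 1e-6), H = fwd$H)
rec
#> ssOS reconstruction
#>   grid: 128 x 8 x 256 (z, y, x)
#>   pattern: p = 19 bins, phi0 = -0.0030 rad, n = 0.4999
#>   cone-fill: 1238 bins; imaginary residual energy: 1.94e-30
```

The pattern parameters were recovered from the raw pair alone (true values:
19 bins, 0 rad, 0.5) and 1238 frequency bins outside the OTF support were
filled. Profiling the phantom's stripes depth by depth turns that into an
axial-resolution statement:

```r
prof_os <- modulation_profile(rec$s_os, scen$chirp)
prof_wf <- modulation_profile(spec_ifft(rec$spectra$S_0), scen$chirp)
recovered_fraction(prof_os, cfg)    # 0.50  — the phantom's full range
recovered_fraction(prof_wf, cfg)    # 0.36  — deconvolved widefield alone
```

The phantom's stripe frequency ramps from zero to half the confocal axial
cutoff: ssOS recovers all of it (fraction 0.50 of the confocal limit), plain
deconvolution only a part. `noise_sweep()` repeats this under Poisson noise
at 10²–10⁵ peak photons and shows full recovery from 10⁴ photons upward,
partial recovery at 10³, and failure at 10².

A thin CLI wraps the same functions
(`Rscript $(Rscript -e 'cat(system.file("cli","ssos.R",package="ssos"))') simulate --out sim/`,
plus `reconstruct`, `emulate`, `baseline-ossim`, `evaluate`, `noise-sweep`,
`cutoffs`); volumes travel as 32-bit multi-page TIFFs with JSON sidecars
recording geometry, intensity scaling, seeds, and configuration.

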