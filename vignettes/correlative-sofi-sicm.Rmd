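---
title: "Models and methods: cumulant imaging, conductance topography, and their correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cumulant imaging, conductance topography, and their correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cumulantscope)
```

## The problem

Widefield fluorescence microscopy is diffraction limited: a point emitter
appears as a point-spread function (PSF) of width $\sigma \approx$ 100–200 nm.
Super-resolution optical fluctuation imaging (SOFI) exploits the statistical
independence of blinking fluorophores: the order-$n$ spatio-temporal cumulant
of the pixel fluctuations carries the PSF raised to the $n$th power, i.e. a
Gaussian PSF of width $\sigma/\sqrt{n}$. Scanning ion-conductance microscopy
(SICM) maps the topography of the same (living) cell without contact by
detecting the drop of the ionic current through a nanopipette as it approaches
the membrane. This package implements the desk-scale analysis chain that
connects the two channels, together with a synthetic-data generator rich
enough to exercise every stage with known ground truth.

## Blinking model and image formation

Each emitter is a stationary two-state Markov chain (telegraph process) with
mean dwell times $\tau_\mathrm{on}, \tau_\mathrm{off}$ in frames and duty
cycle $p = \tau_\mathrm{on}/(\tau_\mathrm{on}+\tau_\mathrm{off})$. A
continuous-time refinement would only change the effective per-frame duty
statistics and is not needed for cumulant tests. For a brightness-$\varepsilon$
two-state signal the cumulants have Bernoulli closed forms,

$$\kappa_2 = \varepsilon^2 p(1-p),\qquad
  \kappa_3 = \varepsilon^3 p(1-p)(1-2p),\qquad
  \kappa_4 = \varepsilon^4 p(1-p)(1-6p+6p^2),$$

which the test suite checks against block-averaged empirical cumulants of the
generated traces.

The camera model: an isotropic Gaussian PSF evaluated at pixel centers times
pixel area (error < 0.5% for $\sigma \gtrsim$ pixel size — a documented
approximation to true pixel integration), Poisson shot noise, and additive
Gaussian read noise clipped at zero (default $\sigma_\mathrm{read} = 1.6$
photons, a typical sCMOS figure; user-settable). Multiplane stacks place
`n_planes` detection planes `plane_spacing` nm apart (default 350 nm, an
8-plane image-splitting-prism geometry), and defocus grows the PSF width
linearly, $\sigma(z) = \sigma_0 + s\,|z - z_\mathrm{plane}|$ with $s = 0.3$
by default — a first-order stand-in for the true defocus law, adequate
because downstream code never assumes a particular axial profile.
Coordinates: pixel (1,1) has its center at (pixel_size/2, pixel_size/2); all
positions are in nm. Dye photophysics for specific labels are not fixed by
the source material; dwell-time defaults are placeholders and every generator
accepts them as parameters.

## Cross-cumulants and virtual pixels

The order-$n$ joint cumulant of $n$ pixel time series (all time lags zero) is
computed from the zero-mean fluctuations; cross-cumulants between *different*
pixels are assigned to the centroid of the contributing pixels, refining the
grid $n$-fold. The canonical combination for refined index $u$ along an axis
is $(n-r)$ copies of pixel $q$ and $r$ copies of $q+1$ where $q = u \div n$,
$r = u \bmod n$ — the nearest real pixels whose centroid lands exactly on the
virtual position — with per-axis offset lists paired slot-by-slot in
ascending order. This fixes one deterministic, reproducible scheme; the
original implementation this emulates is not public, so the scheme is
documented rather than guessed. Virtual pixels whose combination would need
pixels outside the detector are masked invalid (never zero-filled), and the
output is padded to $nY \times nX$ with that mask.

A cross-cumulant is attenuated relative to the auto-cumulant by the distance
factor $D = \prod_{i<j} \exp(-|r_i - r_j|^2 / (2 n \sigma^2))$, an exact
identity for Gaussian PSFs. Dividing it out ("flattening") removes the
$n \times n$ brightness checkerboard. Two deliberate choices:

* **Lateral only.** For multiplane volumes the axial falloff between planes
  follows the defocus law of the optics, which is not Gaussian in $z$; using
  the lateral $\sigma$ there would over-amplify cross-plane terms (we
  observed the axial maximum jumping to a virtual plane). D therefore uses
  in-plane distances only.
* **$\sigma$ from metadata.** Flattening takes the PSF width from the optics
  metadata/configuration rather than estimating it from the image.

Shot noise contributes its own cumulants to auto-pixel combinations (Poisson
$\kappa_n = \lambda$ for all $n$) but cancels from true cross-pixels; the
package does not subtract this bias, so a small auto/cross imbalance remains
in noisy data. Tests of the flattening identity therefore run noise-free.

Axially, $P$ physical planes at order $n$ give $n(P-1)+1$ virtual planes
spaced `plane_spacing`$/n$: 8 planes at order 3 produce 22 planes at
116.67 nm (the value is conventionally printed truncated, 116 nm), spanning
$7 \times 350\,\mathrm{nm} = 2.45\ \mu m$.

## Post-processing

Pipeline order is fixed and recorded: **flatten → linearize → deconvolve**.
Linearization takes $|v|^{1/n}$ so brightness scales as $\varepsilon$ rather
than $\varepsilon^n$; it also guarantees the nonnegative input that
Lucy–Richardson deconvolution requires (the source procedure lists
deconvolution without fixing its position relative to linearization — doing
it after is this package's choice). LR uses a Gaussian kernel of width
$\sigma_0/\sqrt{n}$ truncated at $4\sigma$, circular FFT convolution (exact
flux conservation), 20 iterations by default; `optimize_deconvolution()`
exposes the pick-iterations-by-decorrelation-resolution loop. Volumes are
deconvolved per plane: the axial spacing differs from the lateral spacing
and no anisotropic 3D kernel is specified by the source procedure.

## Decorrelation resolution estimation

The resolution of a single image is estimated from
$$d(r) = \frac{\mathrm{Re}\sum_k I(k)\,\overline{I(k)/|I(k)|}\;M_r(k)}
  {\sqrt{\sum_k |I(k)|^2 \sum_k |M_r(k) I(k)/|I(k)||^2}},$$
with $M_r$ a centered disk of normalized radius $r$ ($r = 1$ at Nyquist),
computed on the raw image and on 10 Gaussian high-pass variants with widths
log-spaced over $[0.15, 1]$ in normalized frequency; each curve's local peaks
(prominence $\ge 0.01$) are collected and the cutoff $k_c$ is the largest
peak position, giving resolution $2\,\Delta x / k_c$. Images are mean-
subtracted and edge-apodized with a raised cosine over 10% of each dimension.
White noise and empty images yield an explicit "undefined" result, not an
exception. Per-image values only are reported; any grouping into
mean ± s.d. over image sets is left to the caller.

## Hopping-mode topography simulation

The normalized current follows $I(z)/I_\infty = 1/(1 + c_s r_p / z)$ — a
one-parameter monotone law chosen so the sensing distance tracks the pore
radius; with the default $c_s = 0.01$ the 1% drop happens at $z \approx r_p$,
and the 99% setpoint corresponds to a constant detection gap
$z^* = 99\,c_s r_p$. At each pixel the simulated pipette descends
quasi-statically in 0.1 nm steps (well below the ~10 nm axial-resolution
scale) from `hopping_height` above the highest point; the surface sensed
under the tip is the *mean* height over a uniform disk of radius
$1.5\,r_p$ — mean rather than max, because it reproduces the empirical
$\approx 3 r_p$ lateral resolution rule for the 10–90% step-edge width.
Fixed-height hopping only: the adaptive per-region hop optimization used by
some instruments is intentionally out of scope. Because $z^*$ is constant
across pixels, relative topography is independent of the setpoint; leveling
(least-squares plane subtraction) and a difference-of-Gaussians band-pass
(blur $\sigma = \lambda/4$ per cutoff wavelength, zero-mean output) mirror
the standard height-map processing chain. Ideal scan time
(pixels / pixel rate) is reported; instrument overhead is an explicit,
separate parameter in the time-lapse schedule.

## Registration and correlation statistics

Control points are user-supplied (the workflow hand-selects corresponding
features); `fit_affine()` is a plain least-squares estimate with a collinear-
geometry error, `warp_image()` resamples bilinearly through the inverse map
with an out-of-source mask. Cross-sections sample both channels along a
polyline (averaged across an odd number of parallel lines), min–max
normalize each profile (a z-score alternative could be added; min–max is the
plain reading of "normalized profiles"), and `pearson()` returns the plain
product-moment r — no further normalization of r itself is applied, since
any such step is ambiguous. Group comparison uses Welch's unequal-variance
two-sided t-test on Fisher-z transformed r values (r is bounded, so the
transform stabilizes variance; a raw-r flag is available); Welch rather than
pooled because equal variances cannot be assumed between matched and
mismatched section sets.

## Synthetic data: what a green test establishes

The generator emulates: independent telegraph blinking, Gaussian-PSF image
formation with shot/read noise, defocused multiplane detection, cell-like
topographies (smooth dome + microvilli bumps + filopodia ridges) and
constant-gap hopping detection with axial noise. It does **not** emulate:
dipole/vectorial PSFs, chromatic effects, within-frame motion blur, detector
fixed-pattern noise, pipette geometry artifacts or electrochemical surface
effects. Green tests therefore establish the correctness of the *algorithms*
under the stated model, and the printed arithmetic of the acquisition
geometry; they do not certify instrument-level resolution figures, which
belong to real data.

Two test-design notes. The odd-order null ($\kappa_3 = 0$ at $p = 0.5$)
holds in expectation over trace realizations: a single finite trace has an
empirical duty cycle slightly off 0.5 and hence a genuine $(1-2\hat p)$
residual, so the test averages the image mean over independent seeds. And
the $\sqrt{n}$-narrowing check runs order 3 at $p = 0.25$, because at
$p = 0.5$ the third-order cumulant vanishes identically and no PSF width
exists to measure.

## Numerical choices and limitations

* Cumulants use a single full-length time average; block averaging is the
  drift-correction module's job (default sub-sequence length 500 frames,
  3-point quadratic sub-pixel peak fit, linear interpolation between block
  centers — all defaults, since the source procedure does not state them).
* Bleaching is reported as a single-exponential lifetime fit
  ($I(t) = A e^{-t/\lambda} + c$, Gauss–Newton with a log-linear start); no
  cumulant bleaching correction is applied, consistent with operating in a
  minimal-photobleaching regime. Non-decaying traces return an infinite-
  lifetime flag. A lifetime is only identifiable when the trace spans a
  time comparable to $\lambda$.
* TIFF I/O is a minimal built-in baseline codec (uncompressed, grayscale,
  multi-page, uint8/16/32 + float32/64) with a JSON sidecar for metadata —
  written because no TIFF-capable R package is available in the target
  environment — and is cross-validated against Python's `tifffile`.
* The descent step (0.1 nm) and the LR iteration default (20) are
  conservative; both are configurable.
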