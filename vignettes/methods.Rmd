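---
title: "Methods: multispectral SFDI processing with RGB cross-channel bands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral SFDI processing with RGB cross-channel bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rgbsfdi)
```

# The measurement model

Spatial frequency domain imaging projects sinusoidal intensity patterns
$P(x) = \mathrm{dc} + \mathrm{ac}\cos(2\pi f_x x + \phi)$ onto a turbid
sample and images the diffusely remitted light. The sample acts as a
low-pass filter in spatial frequency: its diffuse modulation transfer
$R_d(f_x)$ falls with $f_x$, and the *shape* of that fall-off separates
absorption from scattering — absorption suppresses mainly the DC and low
frequencies (long photon paths), scattering controls the roll-off. Two
spatial frequencies are the theoretical minimum for a two-parameter
$(\mu_a, \mu_s')$ inversion; the default acquisition uses four
$(0, 0.0333, 0.05, 0.1\ \mathrm{mm^{-1}})$ and fits on the subset
$(0, 0.05, 0.1)$.

Processing has three stages, applied per pixel, per band and per frequency:

1. **Demodulation.** Three frames phase-shifted by 120° give the AC
   amplitude
   $M_{AC} = \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2}$,
   exactly, for any offset and any global phase — properties the tests
   verify to $10^{-10}$ relative against a least-squares sinusoid fit.
   $f_x = 0$ is handled by the same identity: the three "phases" are
   projected as three uniform fields at $\mathrm{dc} +
   \mathrm{ac}\cos(0°/120°/240°)$.
2. **Calibration.** An identical acquisition on a reference phantom of
   known optical properties gives $M_{AC,\mathrm{ref}}$, and
   $R_{d} = (M_{AC}/M_{AC,\mathrm{ref}})\,R_{d,\mathrm{ref}}$, where
   $R_{d,\mathrm{ref}}$ comes from the forward model. Source intensity and
   the system transfer function cancel in the ratio and are never
   represented. Acquisitions made at different exposures are comparable
   because $M_{AC}$ is linear in exposure; the recorded exposure factor is
   divided out first.
3. **Inversion.** Nelder–Mead minimization of
   $\sum_{f_x} (R_d^{meas} - R_d^{model}(\mu_a, \mu_s'))^2$ against the
   tabulated forward model, independently per pixel.

# The forward model

## White Monte Carlo

`run_white_mc()` simulates photon random walks in a homogeneous
semi-infinite medium with **no absorption**: each photon records its exit
radius and total pathlength $L$, and absorption is applied afterwards as
$\exp(-\mu_a L)$ (`apply_absorption()`). One scattering-only run therefore
serves every $\mu_a$ on the grid — the "white" trick that makes a
$12\times 8$ table cost 8 runs instead of 96.

Choices the simulation makes (none of which are prescribed by the
processing equations, so they are package decisions):

- **Phase function** Henyey–Greenstein, default $g = 0.8$, $n = 1.4$
  (tissue/phantom-like). A $g = 0$, $\mu_s = \mu_s'$ similarity mode is
  about 5× faster and agrees with the anisotropic run at low frequency,
  but drifts above ~3% for $f_x \gtrsim 0.1\,\mu_s'$, so the anisotropic
  mode is the default everywhere.
- **Boundary.** Unpolarized Fresnel reflection at the top surface, sampled
  *probabilistically*: at each boundary hit the photon either escapes
  (recorded with weight 1) or is specularly re-injected. This keeps at most
  one exit record per photon (bounded memory at $10^6$ photons) and leaves
  nothing for Russian roulette to do; the alternative deterministic
  weight-splitting scheme would produce ~13 records per photon at
  $n = 1.4$. Specular entry is excluded — physical systems remove it with
  crossed polarizers.
- **Truncation.** `max_path = 4000` mm. In a non-absorbing half space the
  walk is recurrent but heavy-tailed; truncation loses ~2–4% of photons,
  all with $L \ge 4000$ mm, which even at the table's smallest
  $\mu_a = 0.005\ \mathrm{mm^{-1}}$ carry relative weight
  $e^{-20} \approx 10^{-9}$ after absorption — invisible everywhere except
  *exactly* at $\mu_a = 0$, where the total-reflectance deficit is a few
  percent and documented.
- **Binning.** 512 annuli at $\Delta r = 0.1$ mm (radius 51.2 mm), photons
  beyond the last edge dropped. Annulus areas are exact
  ($\pi(r_2^2 - r_1^2)$), which makes the $f_x = 0$ Hankel value equal the
  binned total to machine precision, since
  $\pi(r_2^2-r_1^2) = 2\pi r_c \Delta r$.
- **RNG.** A self-contained xoshiro256** generator seeded via splitmix64,
  so identical seeds give bit-identical tables across platforms and
  compilers (C++ `std::` distributions are implementation-defined and
  would not).

`hankel_to_fx()` applies the zeroth-order Hankel transform
$R_d(f_x) = 2\pi \sum_i R_d(r_i) J_0(2\pi f_x r_i)\, r_i \Delta r_i$ at
bin centers.

## Diffusion oracle and its validity

`diffusion_rd()` implements the standard spatial-frequency diffusion
approximation with internal-reflection parameter $A$ from
$R_{\mathrm{eff}} = 0.0636 n + 0.668 + 0.710/n - 1.440/n^2$. It is an
independent check on the Monte Carlo, not part of the pipeline. Measured
agreement at $\mu_s'/\mu_a \ge 50$: about 1% for $f_x \le 0.05\ \mathrm{mm^{-1}}$,
within 10% for $f_x \lesssim 0.13\,\mu_s'$. Beyond that the *oracle* is
wrong, not the Monte Carlo: at $\mu_s' = 1\ \mathrm{mm^{-1}}$,
$f_x = 0.2\ \mathrm{mm^{-1}}$ the dimensionless modulation frequency leaves the
diffusive regime and the disagreement reaches 11–12% regardless of photon
count. The oracle-agreement test is therefore scoped to
$f_x \le 0.13\,\mu_s'$; the headline 1e6-photon comparison at
$\mu_s' = 1.5\ \mathrm{mm^{-1}}$ covers the full $f_x \le 0.2$ range within 10%.

## Lookup

`lookup_rd()` interpolates bilinearly in $(\log\mu_a, \log\mu_s')$ at each
tabulated $f_x$ — log axes because $R_d$ is closer to linear there over
the two-decade $\mu_a$ range. Off-grid queries agree with direct
simulation within 3% on the default grids. Because the synthetic
instrument *and* the inverse solver share one table, table interpolation
and Monte Carlo noise cancel in end-to-end recovery tests; table fidelity
itself is established separately against the diffusion oracle.

# Spectral bands

The nine responsivities are pointwise products of the three LED emission
curves and three camera filter curves, each set normalized to its own
global maximum first. Band centers are **intensity-weighted means**
$\lambda_0 = \sum \lambda s(\lambda)/\sum s(\lambda)$ rather than Gaussian
fits, because cross-channel bands can be asymmetric or multi-lobed; FWHM
is the distance between the *outermost* half-maximum crossings with linear
interpolation (the conservative choice for multi-lobed shapes, where inner
crossings would understate the width).

Cross-channel selection keeps the primaries (BB, GG, RR) always, and adds
a cross-channel when (a) its integral is at least 5% of the strongest
band's (an SNR proxy — no quantitative threshold is established in the
literature for this cut, so 0.05 is a package default, chosen well below
the strong GB/GR cross-channels and above the negligible BR/RB/RG ones)
and (b) its center is ≥ 500 nm, encoding the rejection of blue-centered
bands: blue light is so strongly absorbed in tissue that the *detected*
SNR of such a band is poor even when its optical throughput is fine.
On the synthetic curves this selects exactly BB, GB, GG, GR, RR with
centers 460, 517, 536, 558, 626 nm.

The packaged LED/filter curves are **synthetic** Gaussian stand-ins (the
green filter gets a blue shoulder, as real Bayer filters have) shaped to
reproduce the qualitative cross-talk pattern of a characterized consumer
projector/camera pair: strong GB/GR, moderate BG, negligible BR/RB/RG.
They are not measurements, and tests against them establish the band
*arithmetic*, not any physical device's spectra.

# Synthetic instrument

`simulate_acquisition()` chains: pattern → 8-bit gamma pre-compensation →
projector gamma distortion (power law, default 2.2) → image formation →
camera noise → 8-bit quantization → BMP on disk. Image formation is
first-harmonic: the emitted pattern's DC component is multiplied by
$R_d(0)$ and its residual (the sinusoid plus any quantization/gamma
leftovers) by $R_d(f_x)$, with $R_d$ evaluated at the band's center
wavelength (delta-band approximation; a full responsivity-weighted
integration mode exists for studying band-averaging bias, which is < 1%
for the smooth power-law spectra used here). Auto-exposure scales each
band's frames so the brightest frame peaks at 240 counts, mirroring
real practice of filling the dynamic range without saturating; the factor
is stored in the manifest and divided out of MAC downstream.

What it does **not** emulate: speckle, vignetting, lens distortion,
projector pixelation, polarization leakage, layered media, or surface
curvature. A green end-to-end test therefore establishes the correctness
of the *processing arithmetic* under realistic quantization, gamma and
noise — not robustness to the optical artifacts of a physical instrument.

The 16-phantom grid crosses four Intralipid levels (0.5–2%) with four
India-ink levels (13–53 mg/L). Anchors at 625 nm span
$\mu_s' = 0.5$–$2.5$ and $\mu_a = 0.025$–$0.25\ \mathrm{mm^{-1}}$, interpolated
*affinely in concentration* between the measured endpoints (proportional
scaling through zero cannot reproduce both endpoints of either published
range; per-phantom tabulated values are not available). Scattering follows
$\mu_s'(\lambda) = a\lambda^{-b}$ with $b = 1.2$ (Intralipid-like) and $a$
solved from the anchor; ink absorption is flat by default (a near-neutral
absorber), with an optional spectral template anchored at 625 nm.

# Validation study

`run_phantom_study()` simulates the full grid plus a reference, runs the
complete pipeline, FOV-averages the per-pixel maps (phantoms are
homogeneous), and compares against band-emulated ground truth obtained the
way a spectroscopic reference instrument would be used: the continuous
$\mu_a(\lambda), \mu_s'(\lambda)$ spectra (fitted per wavelength from the
idealized point measurement) are collapsed onto the five bands by
responsivity-weighted averaging. Both arms use the shared frequency subset
$(0, 0.05, 0.1)\ \mathrm{mm^{-1}}$.

`regression_stats()` reports OLS slope/intercept/$R^2$ and an RMSE. The
RMSE is computed about the **identity line** $y = x$ by default — the
study asks "do two methods agree?", for which residuals about $y=x$ are
the meaningful agreement metric; residuals about the fitted line
(`rmse_about = "fit"`) are also available since either convention appears
in method-comparison figures.

# Numerical choices and tolerances

- Inversion: initial guess $(0.1, 1.5)\ \mathrm{mm^{-1}}$ (center of the
  physiological range), bounds $[0.005, 0.5] \times [0.3, 5]$, objective
  tolerance $10^{-10}$, parameter tolerance $10^{-6}$, 500 iterations max,
  out-of-bounds handled by a large finite penalty (a hard clamp would
  flatten the simplex against the boundary). Non-convergence flags the
  pixel; it never throws.
- Objective: squared *absolute* residuals. With 2–3 frequencies of
  comparable $R_d$ magnitude the choice between absolute and relative
  weighting moves fits by far less than the noise floor; absolute was
  chosen and exposed as the single convention.
- Reference MAC is 5×5 median-smoothed before division (division noise
  amplification); per-pixel division is available and used where exact
  self-calibration identities are tested.
- Gamma curves are stored as monotone lookup tables (isotonic regression
  cleans measurement noise); pre-compensation inverts by interpolation
  and quantizes to 8-bit levels, so a gamma-$\gamma$ device bounds the
  round-trip error by $\gamma/255$ (the output step near full scale).
- Phantom-study tolerances: the noiseless quantization-free chain must
  recover within 2%; the 8-bit chain gets an explicit additive allowance
  of $2 \cdot \frac{2}{3}\sqrt{3}/60 \approx 0.039$ derived from ±0.5-count
  frame rounding propagated through the demodulation formula and the
  calibration ratio at the study's minimum ~60-count amplitude.

# Known limitations

- Homogeneous, semi-infinite, single-layer media only; no curvature or
  surface-profile correction; no chromophore unmixing.
- The diffusion oracle (and hence the cross-validation of the Monte
  Carlo) is restricted to the diffusive regime described above.
- Synthetic spectra stand in for device characterization data; band
  centers and widths resemble, but are not, measured values.
- The acceptance-grade $R^2$ values from the synthetic study are upper
  bounds relative to physical hardware, whose additional noise sources
  the simulator deliberately omits.
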