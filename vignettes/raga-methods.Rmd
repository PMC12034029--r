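---
title: "Rational approximation of golden-angle radial sampling: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational approximation of golden-angle radial sampling: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raga)
```

## The sampling problem

Radial MRI acquires k-space along spokes through the origin. Dynamic
applications favour golden-ratio ordering: consecutive spokes are separated
by an irrational angle $\psi_N = 180^\circ/(\tau + N - 1)$ with
$\tau = (1+\sqrt 5)/2$, so that *any* window of consecutive spokes covers
k-space close to uniformly and the temporal resolution can be chosen
retrospectively. The price of irrationality is that no projection angle ever
repeats: per-frame quantities (point-spread functions, Toeplitz kernels,
gridding weights) cannot be precomputed and shared, the trajectory must be
carried alongside the data, and naive angle accumulation drifts in floating
point.

This package implements the rational-approximation alternative (RAGA). The
generalized Fibonacci series $G_i^N$ ($G_1 = 1$, $G_2 = N$,
$G_i = G_{i-1} + G_{i-2}$) yields convergents
$\psi_i^N = 180^\circ \cdot G_{i-1}^1 / G_i^N$ of $\psi_N$. Taking
$S = G_i^N$ equidistant angles with base angle $180^\circ/S$ and stepping
through them with index increment $G_{i-1}^1$ gives a sampling order whose
consecutive-spoke angle is $\psi_i^N \approx \psi_N$, while every acquired
angle belongs to a *finite* equidistant set. Because
$\gcd(G_{i-1}^1, G_i^N) = 1$ the temporal index map
$t \mapsto (t \cdot G_{i-1}^1) \bmod S$ is a bijection per period: any $S$
consecutive spokes form a *full frame* covering each angle exactly once.

## Scheme variants

`raga_scheme()` resolves three conventions:

* **half_circle** — indices $0\ldots S-1$, base angle $180^\circ/S$. The
  mathematically minimal pattern; reordering full-circle data into it flips
  half of the readouts.
* **extended** — indices $0\ldots 2S-1$ with the same base angle, covering
  the full circle; indices $n$ and $n+S$ are the same projection with
  opposite readout direction. With an even increment (for example
  $G_{12}^1 = 144$ against $S = 233$) only even indices are reachable; the
  package accepts this with a warning because the published reference angles
  follow exactly this convention, and reports period $S$.
* **doubled** — odd $S$ with base angle $360^\circ/S$, approximating the
  doubled angle $2\psi_N$ and covering the full circle without an enlarged
  index space.

`auto_order()` removes the order $i$ as a user degree of freedom: it selects
the smallest $i$ whose $S$ satisfies the radial Nyquist bound
($S \ge \pi m/2$ for half-circle or odd full-circle patterns,
$S \ge \pi m$ for even full-circle patterns, `m` the base resolution). The
bound's printed form in the literature is the nearest integer (314 for
$m = 200$); `nyquist_min_spokes()` returns the mathematically safe ceiling
(315) and `nyquist_as_printed()` the nearest-integer reading. Both
thresholds select the same Fibonacci frame sizes (for $m = 200$: 377 spokes
for $N = 1$, 419 for the doubled $N = 7$ scheme), because consecutive
Fibonacci numbers straddle the bound comfortably.

## Exactness choices

All index arithmetic is exact: temporal indices are reduced modulo the index
space before multiplication so every intermediate stays inside the exactly
representable integer range of doubles, making `spoke_index()` bitwise
reproducible. Generalized Fibonacci values use an internal little-endian
base-$10^4$ big-integer layer (no external bignum dependency is available in
the target environment), so `fibonacci_general(N, i)` is exact at any order;
values beyond $2^{53}$ are returned as decimal strings on request rather
than silently rounded.

Angles are held in degrees at interfaces and printed-table comparisons round
half away from zero, matching typesetting conventions; R's own `round()`
rounds half to even and would disagree on exact .0005 cells.

## The drift audit

`drift_table()` compares four update rules in emulated IEEE single and
double precision against an extended-precision reference:

* multiplicative: $\phi_t = (t\,\psi_1) \bmod 2\pi$, one rounded product and
  one exact-remainder reduction by the rounded $2\pi$ constant;
* additive: $\phi_t = \phi_{t-1} + \psi_1$, strictly sequential rounding;
* additive with modular reduction after every update;
* RAGA: exact integer index times the rounded base angle $\pi/S$.

The reference evaluates $(t \cdot 180^\circ/(\tau + N - 1)) \bmod 360$ in
fixed-point arithmetic at 50 decimal digits; $\tau$ comes from an
arbitrary-precision integer square root (Newton iteration), and the tests
cross-check it against the independent Fibonacci-convergent route
$\tau = \lim F_{n+1}/F_n$. Emulated values are converted to a fixed-point
representation *exactly* (a double is a dyadic rational) before the
subtraction, so error cells down to $10^{-15}$ degrees are meaningful.

Three conventions in this pipeline are deliberate reverse-engineering of the
published comparison and are worth recording:

* the error is reported as `(reference mod 360) - (emulated mod 360)`
  *without* re-wrapping into $(-180, 180]$, which is why a large
  single-precision error can print as $-2.7\cdot 10^2$ degrees;
* the double-precision golden constant is the double evaluation of
  $\pi/((1+\sqrt 5)/2)$, while the single-precision constant is computed
  entirely in float32 as $\pi\,(\sqrt 5 - 1)/2$ — with these two
  constructions every printed golden-row error cell reproduces at the
  printed precision, which pins down the conventions used;
* the radian-to-degree conversion of the emulated angle is a single double
  multiplication by `180/pi`.

Last-bit evaluation order is otherwise unspecified in the source material;
the double-precision RAGA row therefore reproduces in sign and
machine-epsilon bound rather than digit-for-digit, and the tests assert
exactly that (plus the absence of growth over $5\cdot 10^5$ repetitions).

## PSF and sidelobe-to-peak analysis

The PSF of a spoke window is the adjoint non-uniform Fourier transform of
unit data, $|\sum_j e^{2\pi i k_j \cdot x}|$, evaluated on a pixel grid. The
sidelobe-to-peak ratio (SPR) is the maximum PSF magnitude outside an
exclusion disc around DC divided by the DC value. The source material does
not define "off-center" or the PSF grid; the package defaults to a grid of
twice the base resolution (so a Nyquist-sampled frame's mainlobe spans about
two pixels) and an exclusion radius of two grid pixels, both configurable
arguments of `psf()`/`spr()`.

Two evaluation paths are provided and cross-checked: Kaiser–Bessel gridding
(oversampling factor 2, kernel width 4, Beatty $\beta$; relative accuracy
about $10^{-4}$) and a brute-force DFT oracle used on small grids. Samples
are brought into a canonical order before accumulation, so any permutation
of the same sample multiset — a RAGA full frame versus its equidistant
twin — yields bit-identical PSFs and exactly equal SPR values. PSF
magnitude rather than real part is used since golden-angle windows are not
symmetric.

`sliding_window_spr()` reproduces the worst-case analysis: windows of 5–60
consecutive spokes slide (stride 1) over the temporal sequence and the
per-size maximum SPR is the summary curve. The full published sweep
(every start of roughly 700 per size, two schemes, a $400^2$ PSF grid) is
more CPU than a test budget should spend; the acceptance test therefore
subsamples window starts (`max_windows = 6`, identical starts for the RAGA
and golden curves) at the full base resolution of 200. The compared
quantities remain per-size maxima over the same start sets, and the
qualitative structure — monotone decrease along Fibonacci sizes, local
minima at Fibonacci window sizes, pointwise agreement of the two curves
within 2% — is insensitive to the subsampling (stride-1 checks at smaller
grids back this up in the unit tests).

## Synthetic data and reconstruction demo

`shepp_logan()` is the classic ten-ellipse head phantom scaled to the unit
FOV, and `analytic_kspace()` evaluates its closed-form Fourier transform
(jinc kernel per ellipse with rotation/translation phases) directly at the
trajectory's sample positions — no rasterization or gridding enters the
simulation, so reconstruction tests are free of an inverse crime. The
k-space value at the origin equals the phantom's integrated intensity
$\sum_e \pi a b A$, which the tests verify against a $512^2$ rasterization.

`adjoint_reconstruct()` is a density-compensated adjoint NUFFT: ramp weights
$|k|\,\Delta k\,\Delta\theta$ (the polar area element), with the DC sample
at 1/8 of the first ring — a standard radial heuristic; the reference
reconstructions in the source material rely on unspecified library
defaults, and the demo needs qualitative fidelity only, so the weight is an
exposed argument. Optional complex white Gaussian noise requires an explicit
seed and is off by default; the generator's default state is the noiseless
single-coil simulation at base resolution 200 with 377 spokes that the
published phantom experiment uses. What a green reconstruction test
establishes is therefore: equality of full-frame RAGA and equidistant
reconstructions (same sample multiset), monotone NRMSE improvement with
spoke count, and agreement of gridded and direct adjoints — not the
perceptual image quality of an in-vivo scan, which involves coil arrays,
motion, gradient imperfections and iterative reconstruction outside this
package's scope.

## Known limitations

* The golden-rule emulation implements the classic $N = 1$ constant only;
  the RAGA rule works for any scheme.
* The adjoint-plus-ramp reconstruction is a demonstration, not a clinical
  reconstruction; no coil sensitivities, no iterative regularization.
* Three-dimensional (stack-of-stars, kooshball) extensions are out of
  scope.
* CFL interchange stores 32-bit floats, as the de-facto format prescribes;
  round trips are bit-exact only at that storage precision.
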