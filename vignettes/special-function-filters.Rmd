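---
title: "Special-function image filters: models, parameters, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Special-function image filters: models, parameters, and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperfilter)
```

This vignette is the package's own account of what its filters compute, why
the defaults are what they are, and what the synthetic evaluation can and
cannot show. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The image model

Everything operates on a `gray_image`: a double-precision matrix of
intensities with nominal range [0, 1], at least 3 × 3. Color inputs are
collapsed with ITU-R BT.601 luma weights (0.299/0.587/0.114) — a
convention, chosen because it is the most widely implemented single-number
"gray" and the filters are insensitive to the exact weighting. Filter
outputs are deliberately **not** clipped or rescaled: the nonlinearities
produce values outside [0, 1] by design, and normalising early would
corrupt downstream statistics (brightness means, PSNR). `rescale_for_display()`
is the single, explicit min–max normalisation applied at save/display time
and before mask binarisation; a constant image maps to all zeros so the map
is total.

## The two pointwise filters

**exp.** `u = a · exp(−q (tt − b)^{n₂} / c²)` with `a` the output scale,
`b` the band centre (default 0.5, the middle of the intensity range), `q > 0`
the decay rate, `c ≠ 0` a width constant, and `n₂` a positive integer.
Parity of `n₂` is the interesting control:

* even `n₂`: the exponent is `≤ 0` everywhere, `0 < u ≤ a`, with the
  maximum attained exactly at `tt = b` — an intensity band selector. Most
  pixels of a natural image sit away from `b`, so the display-rescaled
  result is dark.
* odd `n₂`: for `tt < b` the exponent is positive, so darker-than-`b`
  pixels are amplified above `a` and the rescaled rendering is bright.

The testable form of that claim, asserted in the suite, is that the mean
brightness with `n₂ ∈ {9, 29}` strictly exceeds the mean with the adjacent
even values `{8, 28}` on the shapes phantom. At `n₂ = 28/29` the gap is
real but tiny (≈ 2 × 10⁻¹¹ on a [0,1] scale): `(tt − b)^{28}` underflows
toward zero for most pixels. That is also why two properties are stated
"up to round-off": pixels with `|tt − b|` small enough that the power
underflows produce ties at `u = a`, and monotonicity in `q` is strict only
where the power is above double-precision round-off.

Defaults `a = 1, q = 2, b = 0.5, c = 1, n₂ = 8`: unit scales centred on the
nominal intensity range. No published parameter values exist for these
filters' figures, so the defaults are chosen once on that dimensional
argument and never fitted.

Two numerical policies: odd exponents can drive `exp()` past the double
range, in which case values saturate to the largest finite double with a
warning (never NaN/Inf); and the historical formulation iterated only over
rows/columns `3 … n−1`, which for a pointwise map is a border quirk — the
filter applies to every pixel by default, with `paper_loop = TRUE`
reproducing the literal interior-only behaviour for fidelity comparisons.

**sinh-asinh-r.** `r = tt/η`, `z = sinh(a₁ · asinh(r + a₂) · r^{a₃})`,
`u = z^{a₄}`. The composition is typeset ambiguously in its source; the
adopted grouping multiplies all three factors inside `sinh`, matching the
procedural rendering of the algorithm. All powers of possibly-negative
bases are evaluated sign-preservingly (`sign(x)·|x|^p`) so fractional
exponents never leave the reals. Defaults `η = 1, a₁ = 1, a₂ = 0.1, a₃ = 2,
a₄ = 1`, again unit scales; `a₃` is the one constant with a strong visible
effect on the extracted margins.

## The two frequency-domain filters

Both act multiplicatively on the centred 2D spectrum:
forward FFT → pointwise product with a real gain grid `H` → inverse FFT →
real part. The pipeline asserts that the imaginary residue is below 10⁻⁹
of the real magnitude; this is guaranteed when `H` is symmetric under
180° rotation about the grid centre, which holds by construction because
`H` depends on the frequency plane only through the distance map

`D(i, j) = |i − m₁|^{n₃} + |j − n₁|^{n₃}`, `m₁ = ⌊h/2⌋, n₁ = ⌊w/2⌋`

(0-based indices, default `n₃ = 2`). Absolute values keep `D` a
nonnegative distance for odd `n₃`; signed powers would make `D₀/D`
meaningless. The centre pixel has `D = 0` and is guarded by flooring `D`
at `D₀·10⁻¹²`, which preserves the analytic limit (gain → 0 at DC for
cosh-acosh).

**Chebyshev continuation.** Both gains are built from
`chebyshev_cosh(N, u)`, i.e. `cosh(N·acosh(u))` for `u ≥ 1` continued as
`cos(N·acos(u))` for `0 ≤ u < 1`. At integer `N` both branches coincide
with the Chebyshev polynomial `T_N(u)`; the suite verifies this against a
three-term-recurrence oracle to 10⁻⁹ over `u ∈ [0, 3]`, `N = 1…5`.
Magnitudes are taken before the fractional outer powers (`n₅`, `nn`) so the
gain stays real and in (0, 1].

**cosh-acosh.** `H = 1/(1 + ε²·CNx^{n₄})`, `CNx = |T_order(D₀/D)|^{n₅}`.
Two resolved ambiguities deserve a note. First, the source notation reuses
one symbol both for the grid half-width and for the order inside `cosh`;
treating the half-width (hundreds) as the order would drive `CNx` so large
that `H ≡ 0`, so the order is an independent parameter (default 4).
Second, the reference distance is specified as "0.05" in pixel terms;
interpreted literally (0.05 of one pixel) the filter would be a
near-identity, so it is read as 5% of the half-height, `D₀ = 0.05·m₁`,
configurable via `d0`.

The resulting radial structure, which the suite checks on a fine 1D grid:
on the cosh branch (`D ≤ D₀`, `u = D₀/D ≥ 1`) the gain falls monotonically
from `1/(1+ε²)` at the cutoff towards 0 at DC — a monotone high-pass
stopband, the mechanism behind the edge extraction and the "printmaking"
rendering. Beyond the cutoff (`D > D₀`) the cosine branch makes `H`
oscillate between `1/(1+ε²)` and 1, with extrema pinned to the zeros and
extrema of `T_order`; for order 4 and the default `ε = 1` that passband
ripple has amplitude 0.5, and only the tail beyond the innermost polynomial
zero (`D > D₀/x₁`, `x₁ = cos(3π/8) ≈ 0.38`) is again monotone. The
acceptance checks assert exactly this structure (monotone cosh branch,
monotone far tail) rather than global passband monotonicity, which the
closed form rules out.

**sech-asech.** `H = 1/(1 + ε²·CNx₂²)`,
`CNx₂ = |sech(λ·asech(D₀/D))|^{nn} = |1/T_λ(D/D₀)|^{nn}` via the
reciprocal continuation. Far from the centre the gain tends to 1 (high
frequencies pass); inside `D < D₀` the cosine branch puts zeros of `T_λ`
in the denominator, so the gain oscillates between ~0 and `1/(1+ε²)` —
the rippled, "corrugated" rendering. Zeros of the cosine branch make
`CNx₂` overflow; those gains saturate to the largest finite double
(gain ≈ 0) rather than failing. With `λ = 3, nn = 2, ε = 1` the radial
profile below `D₀` shows at least two derivative sign changes, the
package's operational definition of ripple. Defaults `order = 4, n₅ = 1,
n₄ = 2, ε = 1` and `λ = 4, nn = 24, ε = 1` give clearly-resolved versions
of both behaviours at 256 × 256.

`ε = 0` turns both filters into exact all-passes — the end-to-end identity
that anchors the FFT plumbing (verified to 10⁻⁸).

## Noise model

The robustness studies use impulse ("salt-and-pepper") noise: each pixel is
independently replaced with probability `density`, half of the replacements
by 0 and half by 1. The motivating description of the degradation mixes
vocabularies — "Gaussian noise" parameterised by a *density*, with white
impulse spots — so both families are implemented: salt-and-pepper is the
default reading (it matches the visual signature and the density
parameterisation), and `family = "gaussian"` with a density-as-variance
mapping covers the literal reading. Noise is deterministic given the seed
in its `noise_spec`, byte for byte, and the caller's RNG state is left
untouched. The realised altered-pixel fraction concentrates around the
density at the binomial rate, which the suite checks at 3σ over 20 seeds.

## Phantoms: what they emulate, and what they do not

No photographic test material ships with the package; all inputs are
generated:

* `make_shapes_phantom()`: 3–6 non-overlapping rectangles and disks with
  distinct gray levels in [0.2, 0.9] on a 0.1 background. The edge mask
  follows one rasterisation rule used everywhere: a pixel is an edge pixel
  iff it carries a shape label and a 4-neighbour carries a different label
  (so a 20 × 20 square contributes exactly 76 edge pixels).
* `make_step_edge()`: the analytic unit test surface for gradient
  operators; the mask marks the two columns at the discontinuity.
* `make_nir_tube_phantom()`: a rotated bright rectangle over a dim
  background with mild seeded multiplicative texture, Gaussian-blurred to
  mimic tissue scattering — a stand-in for a fluorescence image of a
  dye-filled tube under tissue. Its edge mask is the pre-blur tube
  boundary.

These phantoms have piecewise-constant regions, exact boundaries, and
stationary noise. Real NIR frames have depth-dependent blur, structured
background, photon noise, and no ground truth; a filter ranking measured
here demonstrates the claimed mechanisms (band selection, DC suppression,
impulse collapse) on controlled inputs, not field performance.

## Scoring design

Every method is reduced to a binary mask by one rule — threshold at
`mean + 1·sd`, strict inequality — applied to the operator's response
magnitude, or to the min–max-rescaled output for enhancement filters. The
strict inequality is deliberate: a flat zero response must yield an empty
mask even when the automatic threshold degenerates to zero. `edge_f1()`
then matches predicted to true boundary pixels greedily, without
replacement, within a Chebyshev radius of 1 pixel (so over-prediction
cannot inflate precision, and the score is symmetric at radius 0). PSNR is
`10·log₁₀(1/MSE)` on the [0,1] scale, capped at 99 dB.

One measured limitation is worth stating plainly: at impulse density 0.9
only ~10% of pixels survive, at uniformly random locations. The exp filter
genuinely collapses both impulse extremes to a common floor — its
binarised mask is exactly the surviving-pixel set — but that set is
spatially random, so its edge-F1 sits at the same random-overlap floor as
a gradient operator's (≈ 0.045 on the 256² shapes phantom), and mask-based
scoring cannot resolve the two. The separation the mechanism predicts
appears one density step down: at density 0.5 the exp filter's edge-F1 is
roughly seven times Sobel's under identical scoring, and the oriented
matched filter likewise recovers (its F1 at 0.5 exceeds its own at 0.9).
The acceptance suite asserts the 0.9-density ordering as claimed and the
script reports both densities, so this saturation is visible in the
numbers rather than hidden by a weakened check.

## Problem sizes and determinism

Tests and the acceptance script run on 256 × 256 phantoms (large enough to
resolve the frequency-domain behaviour, small enough for sub-second
filtering), 10-seed noise families for the robustness comparisons, 20
seeds for noise calibration, 50 random parameter draws for the
transfer-function contracts, and 301-point grids for the Chebyshev oracle
— sizes chosen as the smallest at which each behaviour is
well-resolved. All randomness flows through explicit integer seeds
(`withr::with_seed`), so every reported number is reproducible bit for
bit.

## Known limitations

* The constants behind the original filters' published renderings are not
  recoverable, so only qualitative/ordering behaviours are testable;
  figure-faithful reproduction is out of reach by construction.
* The frequency filters assume the centred-spectrum convention; quadrant
  (non-shifted) transfer functions and separable 1D variants are not
  implemented.
* Color is reduced to luma before filtering; there is no color-preserving
  enhancement path.
* JPEG input requires the optional EBImage dependency, and JPEG output is
  not offered (lossy round-trips would invalidate the metric guarantees).
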