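# hyperfilter

Nonlinear image-enhancement filters built from special functions, with the
quantitative scaffolding needed to score them instead of eyeballing them.

Low-contrast, noisy grayscale images — near-infrared fluorescence frames of
dye-filled vessels under tissue being the motivating case — often need a
strong nonlinear enhancement step before their structures can be seen or
segmented. This package implements four such filters:

- **exp** (pointwise): `u = a · exp(−q (tt − b)^{n₂} / c²)`. With even
  `n₂` this is a Gaussian-kernel-like band selector around intensity `b`;
  region interiors at distinct gray levels separate into bands and the
  rendering is dark. With odd `n₂` the exponent changes sign across `b` and
  the rendering is bright — the progression-parity effect.
- **sinh-asinh-r** (pointwise): `r = tt/η`,
  `z = sinh(a₁ · asinh(r + a₂) · r^{a₃})`, `u = z^{a₄}` with sign-preserving
  powers, a flexible contrast law whose `a₃` controls the extracted margins.
- **cosh-acosh** (frequency domain): a Chebyshev-type transfer function
  `H = 1 / (1 + ε² · |cosh(N·acosh(D₀/D))|^{n₅·n₄})` on the centred 2D
  spectrum, evaluated through the real continuation
  `cosh(N·acosh(u)) = cos(N·acos(u)) = T_N(u)`. Low frequencies are
  monotonically suppressed (high-pass edge extraction, with the
  characteristic "printmaking" rendering); the passband carries bounded
  Chebyshev ripple.
- **sech-asech** (frequency domain):
  `H = 1 / (1 + ε² · |sech(λ·asech(D₀/D))|^{2nn})` via the reciprocal
  continuation `sech(λ·asech(u)) = 1/cosh(λ·acosh(1/u))`; high frequencies
  pass, and below the reference distance the cosine branch produces the
  rippled ("corrugated") rendering.

Because enhancement quality is usually judged visually, the package also
ships the pieces that turn those judgments into numbers: seeded impulse and
Gaussian noise injection (the stress densities of interest are 0.5 and 0.9),
classical baselines (Sobel, Prewitt, Roberts, Laplacian-of-Gaussian, a Gabor
bank, an oriented matched filter), deterministic phantoms with analytic edge
masks (geometric shapes, step edges, a blurred NIR tube-in-tissue analog),
and metrics (PSNR, boundary precision/recall/F1 within a pixel tolerance).

## Worked example

```r
library(hyperfilter)

ph <- make_shapes_phantom(256, 256, seed = 1)
ph
#> <phantom:shapes> 256 x 256, 464 edge pixel(s)

# score the enhancement filters against classical operators under
# salt-and-pepper noise at density 0.5
df <- compare_methods(ph, c("exp", "cosh_acosh", "sobel", "none"),
                      noise = noise_spec("salt_pepper", density = 0.5,
                                         seed = 0))
print(df, digits = 3)
#>       method noise_family noise_level psnr precision recall     f1
#> 1        exp  salt_pepper         0.5 5.63    0.1298  0.901 0.2269
#> 2 cosh_acosh  salt_pepper         0.5 7.56    0.0214  0.746 0.0415
#> 3      sobel  salt_pepper         0.5 9.05    0.0181  0.545 0.0350
#> 4       none  salt_pepper         0.5 7.09    0.0214  0.746 0.0415
```

At density 0.5 the exp filter's edge-F1 (0.23) is roughly seven times
Sobel's (0.035): the filter maps both impulse extremes (0 and 1) to a common
dark floor, so the surviving structure dominates the rescaled output, while
the gradient operator's magnitude is still noise-driven. On the clean
phantom the same scoring gives Sobel the advantage — the filters' value is
specifically their behavior under heavy noise:

```r
em <- gradient_edge(ph$image, "sobel")
em
#> <edge_map> 256 x 256, threshold 0.1881, 1228 edge pixel(s) (1.87%)
edge_f1(em$mask, ph$edge_mask, tolerance_px = 1)
#> <edge_score> precision 0.378, recall 1.000, F1 0.548 (tolerance 1 px)
```

All masks here come from one shared rule (threshold = mean + 1 sd, strict;
filter outputs are min–max rescaled first), and `edge_f1` matches predicted
to true boundary pixels greedily within a 1-pixel Chebyshev radius, so
filters and operators are compared on equal footing.

A command-line front end over the same functions lives at
`inst/cli/hyperfilter.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hyperfilter.R",
                                       package = "hyperfilter"))')" \
  synth --kind nir-tube --seed 1 --out tube
# -> tube.png, tube_edges.png, tube.json
```

with subcommands `enhance`, `add-noise`, `synth`, `baseline`, `compare`
(exit codes: 0 success, 2 parameter error, 3 I/O error, 4 internal numeric
assertion).

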