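# rodcoords

Single-molecule and widefield fluorescence microscopy of rod-shaped
bacteria (E. coli and friends) produces data in Cartesian image
coordinates, but the questions are asked in *cell* coordinates: how far
from the midline is this protein, is it at a pole, does it sit on the
membrane? `rodcoords` builds a per-cell curvilinear coordinate system that
answers these questions, for image data (binary masks, brightfield,
fluorescence) and for sparse SMLM/STORM localization tables alike, and
lets many cells be combined into one statistically powerful picture.

## The coordinate system

Each cell is described by six parameters: a quadratic midline
p(x) = a₀ + a₁x + a₂x² on the domain [x_l, x_r], and a radius r. A
Cartesian point (x_p, y_p) (pixel centers at half-integers, y down) maps
to cellular coordinates (l_c, r_c, φ):

- **x_c** — abscissa of the closest midline point, found by solving the
  cubic ∂/∂x[(x−x_p)² + (p(x)−y_p)²] = 0 in closed form and clamping to
  [x_l, x_r] (points beyond the endpoints belong to the hemispherical
  poles);
- **l_c** — arc length ∫√(1+p′²) dx from x_l to x_c (closed form for a
  quadratic), so l_c ∈ [0, L] with L the cell length;
- **r_c** — Euclidean distance to (x_c, p(x_c));
- **φ** — 0 at the top of the cell, 180 at the bottom, running 0→180
  clockwise around the right pole and 180→0 around the left.

The transform is invertible (`map_to_cartesian()`), which is what makes
multi-cell alignment onto a model cell possible.

The six parameters are refined per cell by minimizing a χ² objective with
a Nelder–Mead search, against whichever data element is most trusted:

| method | objective |
|---|---|
| `binary` | disagreeing pixels between the mask `r_c ≤ r` and the measured binary |
| `image` | Σ(measured − angularly-averaged simulation)², then r from the half-maximum of the radial profile |
| `localizations` | Σᵢ(r_cᵢ − r)² over membrane-marker localizations |

On top of the transform the package provides radial / longitudinal /
angular distributions, ensemble radial profiles (membrane radius
normalized to 1), alignment and Gaussian rendering of many cells onto a
model cell, and a membrane-periodicity pipeline (perimeter trace →
detrended spatial autocorrelation → Fourier transform).

A fully seeded synthetic benchmark (`synthetic_cell()`, `compose_field()`,
`run_benchmark()`) generates ground-truth cells with exact binaries, noisy
brightfield images (Poisson shot noise at 500/1000/10000 photons plus
Gaussian read noise, sd 20) and membrane-localized STORM tables
(radial scatter σ = 0.25 px ≈ 20 nm), so every stage is testable without
real microscopy data.

## Worked example

```r
library(rodcoords)

set.seed(1)
# a synthetic ground-truth cell: known geometry, 200 membrane localizations
gt <- synthetic_cell(photons = 10000, n_locs = 200, id = "demo")
gt$params
#> <coord_params> p(x) = 6.823 + 0.138 x + -0.003343 x^2 on [7.687, 33.6], r = 4.687

# emulate imperfect segmentation, guess coordinates from the rough mask
seg   <- degrade_binary(gt$elements$binary, gt$params)
cell  <- new_cell("demo", coords = initial_coordinate_guess(seg),
                  elements = list(binary = seg,
                                  storm = gt$elements$storm_inner))

# refine against the membrane-marker localizations
fit <- optimize_cell(cell, "storm", method = "localizations")
fit
#> <cc_fit localizations> chi2 13.36 (start 59.95), 766 evals, converged: TRUE

c(r_fitted = fit$params$r, r_true_inner = gt$r_inner)
#>     r_fitted r_true_inner
#>     4.219186     4.218096
```

The fitted radius lands on the inner-membrane radius (here within 0.03%),
and the χ² drops from the rough initial guess to roughly
n·σ² = 200·0.0625 ≈ 12.5 — the scatter floor of the localizations
themselves.

A shell entry point wraps the same functions:

```sh
Rscript inst/cli/rodcoords.R synth --seed 1 --out-dir fields/
Rscript inst/cli/rodcoords.R extract --mask fields/mask.tif \
    --locs fields/localizations.csv --out cells.rds
Rscript inst/cli/rodcoords.R optimize --cells cells.rds \
    --element localizations --method storm --out cells_opt.rds
```

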