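---
title: "Curvilinear cell coordinates for rod-shaped bacteria: model, objectives and benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvilinear cell coordinates for rod-shaped bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodcoords)
```

## The model

A rod-shaped bacterium is described by six scalars: the coefficients of a
quadratic midline $p(x) = a_0 + a_1 x + a_2 x^2$, the midline domain
endpoints $x_l < x_r$, and a radius $r$. The cell body is the set of
points within distance $r$ of the midline over its domain; the poles are
the hemispherical caps beyond $x_l$ and $x_r$. All coordinates are in
pixels, y-down, with the center of the top-left pixel at $(0.5, 0.5)$ —
the ImageJ convention, so localization tables and pixel grids share one
frame.

A Cartesian point $(x_p, y_p)$ is transformed by first finding the
abscissa $x_c$ of the closest midline point. Setting the derivative of
the squared distance to zero gives the cubic

$$2a_2^2\,x^3 + 3a_1a_2\,x^2 + \bigl(1 + a_1^2 + 2a_2(a_0-y_p)\bigr)x +
\bigl(a_1(a_0-y_p) - x_p\bigr) = 0,$$

solved in closed form (not iteratively — the transform is applied to
every pixel of every cell at every optimizer step). For strongly curved
midlines the cubic can have three real roots; we evaluate the squared
distance at every real root and at both endpoints, each clamped to
$[x_l, x_r]$, and keep the arg-min. This is exact constrained
minimization: an interior candidate set plus the boundary. Below
$|a_2| < 10^{-10}\,\mathrm{px}^{-1}$ the leading coefficient $2a_2^2$ is
numerically useless and the exact linear-midline projection takes over;
results at $a_2 = 10^{-12}$ agree with the $a_2 = 0$ branch to well below
$10^{-6}$ px (tested).

From $x_c$ follow the cellular coordinates: the longitudinal position
$l_c$ is the arc length $\int_{x_l}^{x_c}\sqrt{1+p'(x)^2}\,dx$, evaluated
with the closed form $[u\sqrt{1+u^2} + \operatorname{asinh} u]/(4a_2)$,
$u = a_1+2a_2x$; the radial distance $r_c$ is the Euclidean distance to
$(x_c, p(x_c))$; and the angle $\varphi$ (degrees) is 0 on the top side
of the midline ($y_p < p(x_p)$ in the y-down convention), 180 on the
bottom, and interpolates around the poles — at a clamped endpoint,
$\varphi$ is the angle between the top-side normal and the segment from
the endpoint to the point. Because a point only clamps to an endpoint
when its outward tangent component is non-negative (a consequence of the
sign of the distance derivative at the boundary), this pole angle runs
continuously 0→180 around the right pole and 180→0 around the left, and
joins the body values continuously at the seam. On the midline itself
($r_c = 0$) the angle is geometrically undefined; we fix it to 0 to keep
the transform total.

The inverse transform recovers $x_c$ from $l_c$ by Newton iteration on
the monotone closed-form arc length (tolerance $10^{-9}$ px; the
derivative $\sqrt{1+p'^2}\ge 1$ makes the iteration unconditionally
stable) and places the point along the body normal or rotated pole
normal. Forward-then-inverse reproduces points to $10^{-6}$ px wherever
$r_c > 0$; the property suite checks this over random geometries.

## From mask to cells

Cell extraction takes an integer-labelled mask (0 background, $k>0$ cell
$k$ — segmentation itself is deliberately out of scope; any external
tool can produce the mask). Each label is cropped with a 3 px pad, its
principal-axis angle computed from second-order central image moments,
$\theta = \tfrac12\operatorname{atan2}(2\mu_{11}, \mu_{20}-\mu_{02})$,
and every data element rotated by $-\theta$ about the crop center so the
long axis is horizontal. One affine point transform is shared between
image resampling (bilinear for intensities, nearest-neighbour for
binaries, which therefore stay strictly 0/1) and localization
coordinates; a marker pixel and a co-located localization stay within
interpolation tolerance of each other after extraction. Second-order
moments cannot distinguish a cell from its 180° rotation; no flip
correction is applied, which keeps extraction deterministic.

Initial coordinate guesses come from the binary alone: a least-squares
quadratic through the per-column foreground center of mass gives
$a_0, a_1, a_2$; half the median per-column foreground height gives $r$;
and the foreground extrema pulled inward by $r$ give $x_l, x_r$, since
the hemispherical poles extend one radius beyond the midline domain.

## The three objectives

All three objectives are non-negative sums of squares, zero exactly in
their exact-fit case, minimized by Nelder–Mead from the current
parameters with per-parameter scales (1 px for $a_0, x_l, x_r$; 0.01 for
$a_1$; $10^{-4}\,\mathrm{px}^{-1}$ for $a_2$; 0.5 px for $r$), relative
convergence $10^{-6}$, plus one restart from the incumbent — the binary
objective is integer-valued and piecewise constant, and a restart
reliably escapes degenerate simplices. Invalid geometries
($x_r - x_l < 1$, $r \le 0$) are rejected with a large finite penalty
rather than an error so the simplex can recover. The driver never
returns a point worse than its start.

* **binary** — the model mask $r_c \le r$ versus the measured binary;
  $\chi^2$ is the count of disagreeing pixels. All six parameters are
  free, including $r$: the radius trades boundary pixels directly and
  the joint fit is what the iterative refinement of the mask comparison
  suggests.
* **image** — any image channel with an angularly isotropic signal. The
  angularly averaged radial profile (histogram binning, 0.5 px bins,
  empty bins inheriting their nearest neighbour's value) is interpolated
  back onto every pixel, giving the isotropic image the current
  coordinate system predicts; $\chi^2$ is the squared difference over
  pixels with $r_c \le r + 5$ px. Excluding far background keeps the
  profile and the $\chi^2$ from being dominated by empty field — without
  a cutoff an unbounded frame contributes unbounded background variance.
  Histogram binning (rather than kernel smoothing) is the deliberate
  speed-over-accuracy trade of the published behaviour; it is also why a
  smooth radial function is only a *near*-fixed point of the simulation
  (within intra-bin variation). Only the five shape parameters are
  optimized; the radius is then set by the half-maximum point of the
  radial intensity profile — the $r_c$ where the profile first crosses
  halfway between its peak and its far-field baseline outward of the
  peak, with monotone profiles peaking at $r_c = 0$. The half-max step
  uses finer 0.25 px bins: the crossing is interpolated linearly between
  bin centers, and at the steep membrane edge 0.5 px histogram bins bias
  the crossing by about 0.12 px, while 0.25 px bins roughly halve that.
* **localizations** — membrane-marker SMLM data;
  $\chi^2 = \sum_i (r_{c,i} - r)^2$. All six parameters are free; at the
  optimum $r$ converges to the mean radial distance of the scatter.

## Analysis outputs

Axial distributions bin pixel intensities (means) or localizations
(counts) along one cellular coordinate; binning conserves mass exactly.
The ensemble radial distribution computes each cell's profile on a
normalized grid ($r_c / r$, so the membrane sits at 1), normalizes each
curve by its own maximum, and reports the per-bin mean and standard
deviation across cells — the spread then reflects only profile shape.

Alignment maps every pixel center or localization of every cell to
cellular coordinates, rescales $l_c$ by $L_{model}/L_{cell}$ and $r_c$
by $r_{model}/r_{cell}$ (uniformly, poles included — the simplest
consistent choice), transforms back into the model-cell frame, and
renders the weighted point cloud as a sum of 2-D Gaussians (default
$\sigma = 0.5$ model px, truncated at $4\sigma$). Each stamp is
normalized to its own discrete sum, so rendering is linear in the input
and conserves total mass up to frame clipping; with the default
auto-sized frame, exactly. Image pixels farther than $r + 2$ px from the
midline are excluded — far background carries no shape information and
would land outside any model cell.

The perimeter pipeline targets periodic membrane fine structure. Each
localization is assigned an arc position along the closed isodistance
outline at distance $r$, clockwise from the top membrane start
($l_c = 0, \varphi = 0, r_c = r$): top segment, right pole, bottom
segment (traversed backward), left pole. Offset-curve segment lengths
are integrated numerically on a fine grid (the offset curve of a
quadratic has no convenient closed form); for a straight cell the
perimeter reduces to $2L + 2\pi r$ exactly. Positions are binned at
10 nm — well below the tens-of-nanometres structures of interest — then
an unbiased autocorrelation over lags up to half the perimeter is
detrended by subtracting a centered 150 nm moving average. The window
default is roughly three times the expected period: wide enough to pass
the low-frequency envelope, narrow enough not to absorb the oscillation;
it is configurable and results are insensitive to factor-of-two changes.
The dominant wavelength is read off a 4× zero-padded Fourier spectrum,
excluding the zero-frequency term.

## The synthetic generator

The generator defines the study conditions under which everything above
is validated; its defaults are fixed once and are not tuning knobs.

* Geometry: radius $\sim N(5, 0.5)$ px, midline chord length
  $x_r - x_l \sim N(25, 5)$ px truncated above 10 px, curvature
  $a_2 \sim N(0, 0.004)$ px$^{-1}$, at 80 nm/px — E. coli-like
  dimensions (0.8 µm diameter, 2 µm body) at a typical EMCCD pixel
  size. The published benchmark drew its geometry from measured cells
  whose distributions were not released, so these are the package's own
  choices, fully configurable. "Length" is the chord $x_r - x_l$, not
  the arc length: both are configurable and the chord needs no root
  solve against the sampled curvature.
* Binary: exact, pixel $=1$ iff the pixel center has $r_c \le r$.
* Brightfield: noiseless model = photons × a normalized radial intensity
  function with background 1 and fixed peak contrast 0.5; per-pixel
  Poisson shot noise; additive Gaussian read noise, sd 20 photons.
  Photon levels 500 / 1000 / 10000 reproduce the published
  signal-to-noise conditions. The default radial function is a logistic
  edge of width 1.5 px centered at $r$ — its half-maximum point *is*
  the membrane radius, so the half-max radius convention is
  self-consistent by construction. (A Gaussian membrane ring centered at
  $r$ is available as an option, but note that the outward half-max
  crossing of a ring of width $w$ sits $w\sqrt{2\ln 2} \approx 1.8$ px
  outside the ring center, i.e. the ring shape and the half-max radius
  convention disagree about where "the" radius is.)
* Localizations: homogeneous along the closed outline at the target mean
  radius (uniform in outline arc length, inverted through the
  offset-curve parametrization), with Gaussian radial scatter
  $\sigma = 0.25$ px (20 nm). The inner membrane sits at $0.9\,r$ —
  roughly 40 nm inside an 80 nm/px membrane radius, consistent with a
  membrane marker seen inside the brightfield-measured cell edge — and a
  second element 100 nm further out. An optional cosine intensity
  modulation along the perimeter (rejection-sampled) provides ground
  truth for the periodicity pipeline.
* Fields: cells are drawn with replacement, randomly rotated and placed
  in 512×512 px fields (40 µm at 80 nm/px), $\mathrm{round}(N(10,3))$
  cells per field, with at least 5 px between binaries, enforced by
  exact point-set distances (each candidate is rendered by pulling field
  pixels back through the placement transform and evaluating the exact
  geometry, so no interpolation artifacts). Placements that fail after
  the retry budget are skipped and logged, matching the "fewer cells"
  behaviour of a crowded field.

## The benchmark and its scoring

`run_benchmark()` exercises the whole chain per cell: sample geometry →
render truth elements → degrade the binary (pixels within 1 px of the
outline re-assigned at random with probability 0.5, emulating imperfect
segmentation) → initial guess from the degraded binary → optimize with
each requested method → score. Segmentation by neural network is out of
scope, so degraded truth binaries stand in for a segmenter's output;
this isolates the coordinate-system machinery being validated. Matching
of measured to truth cells in composed fields is by nearest centroid
with a 5 px gate (we control truth identity, so the published
intensity-encoding cluster matching is unnecessary), with
under-recovered cells flagged and foreign localizations removable by
truth membership.

Scoring uses the relative $\chi^2$: the localization objective at the
fitted parameters divided by its value at the ground truth, so 1 is a
perfect fit. One subtlety matters: the localizations sit at the inner
membrane ($0.9\,r$), so the parameters a *perfect* localization fit
recovers are the truth parameters with $r$ replaced by the true
inner-membrane radius — that is the denominator's coordinate system,
and the reference for radius-recovery errors. Using the cell radius
instead would put the denominator at
$\approx (0.1 r)^2 + \sigma^2$ per localization and drive every ratio
far below 1, which cannot be what a "value of 1 indicates a perfectly
fitted coordinate system" normalization means. With $n = 200$
localizations and six free parameters, the fitted $\chi^2$ sits slightly
below the truth $\chi^2$ on average (the optimizer absorbs
$\sim k/n$ of the variance), so medians just under 1 are expected
behaviour, not bias.

Radial-coordinate errors are reported for all membrane localizations as
$(r_c^{fit} - r_c^{true})/r^{true}_{inner}$, with the absolute mean
deviation, root-mean-square deviation and median absolute deviation per
cell.

Problem sizes: the packaged acceptance checks run 100 cells per
condition for the headline medians (localization-based fits recover the
membrane radius to well under 1%; brightfield-only fits assign
localization radial coordinates to well under 5% at 10000 photons), 50
cells per photon level for the method ordering (localizations ≤ image ≤
binary in median relative $\chi^2$ at 500, 1000 and 10000 photons), and
20 seeds for the 56 nm periodicity recovery. These sizes give stable
medians while keeping a full run to a few minutes on one core.

## What the synthetic benchmark does and does not show

The generator emulates geometry, shot and read noise, localization
scatter and crowding — the features the coordinate machinery interacts
with. It does not emulate segmentation-network failure modes (binaries
are degraded truth, not U-Net output), fluorophore photophysics,
frame-by-frame SMLM acquisition, drift, or non-quadratic cell shapes
(bent or branched cells violate the midline model by construction).
Passing benchmarks therefore validate the transform, objectives and
pipeline plumbing — not the upstream segmentation, and not the model's
adequacy for strongly deformed cells.

## Known limitations

* The midline is quadratic; higher-order or S-shaped cells are out of
  scope, as are 3-D coordinates and temporal structure (kymographs,
  lineages).
* Nelder–Mead is local. Poor initial guesses (badly degraded binaries)
  can leave a fit in a secondary minimum; the benchmark reports these as
  the high-$\chi^2$ tail rather than hiding them. Bounded or global
  optimization is deliberately not included.
* The binary objective's integer landscape limits sub-pixel precision;
  it is the coarsest of the three methods, which is exactly its observed
  ordering in the benchmark.
* Persistence uses R serialization (single-file, lossless, compact);
  it is not a cross-language archive format.
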