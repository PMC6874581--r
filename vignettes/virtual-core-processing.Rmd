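---
title: "Virtual-core processing of underway flow cytometry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-core processing of underway flow cytometry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocore)
```

## The measurement problem

Sheathless underway flow cytometers sample a ship's flow-through seawater
continuously. Without a sheath fluid, particles cross the laser anywhere in
the open sample stream, and only those inside a small, optically
well-defined region — the *virtual core* — are measured accurately. Two
position-sensitive detectors (D1, D2) locate each particle laterally:
particles that scatter equally on both detectors are aligned on the stream
axis, and particles whose forward scatter dominates the position-detector
signals are in focus. The intersection of those two conditions defines the
*optimally-positioned particles* (OPP), and every downstream quantity —
abundance, size, carbon — is computed on the OPP subset.

This package implements the complete processing chain from raw per-particle
event tables to curated per-population records, together with a seeded
cruise simulator that provides ground truth for end-to-end validation.

## Virtual-core filtration

In log10 bead-normalized coordinates the relationship between forward
scatter and each position detector is modeled as two line segments meeting
exactly at the coordinates of the 1-micron calibration beads — one segment
for particles scattering less than the beads, one for particles scattering
more. `fit_filtration_params()` places the anchor at the median coordinates
of the densest bead scatter mode. Calibration runs often include several
bead sizes; anchoring on the modal cluster rather than the whole-cloud
median keeps the anchor on the 1-micron cluster even when the extra sizes
are asymmetrically distributed in scatter (Mie response curves are not
monotone for high-index beads, so two bead sizes can share a scatter
level).

Per detector, segment and confidence quantile (2.5, 50, 97.5%), the slope
is fit by quantile regression constrained through the anchor: the exact
minimizer of the pinball loss for a one-parameter line is a weighted
quantile of the per-bead slopes with weights proportional to the scatter
offset, and loss ties are broken toward the smaller slope. By
construction the q% boundary leaves a fraction q/100 of beads at or below
it on each segment, and the three boundaries nest, so
OPP(2.5) ⊆ OPP(50) ⊆ OPP(97.5) on any input.

The "equal scatter on both detectors" alignment condition is
operationalized as a tolerance on |log10(d1/d2)|, self-calibrated as the
97.5th percentile of the bead log-ratio distribution; it is dimensionless
and insensitive to channel gains.

## Classification

OPP are partitioned in a fixed sequence: polygon gates for calibration
beads, *Synechococcus* and small *Crocosphaera* (each has a distinctive
pigment/scatter signature; first containing polygon wins, in that order);
then a density-based step for *Prochlorococcus*; then scatter and red
fluorescence thresholds for picoeukaryotes; residual particles are labeled
`unknown`, so the labels always partition the table.

The *Prochlorococcus* step emulates a sequential bivariate gating strategy
driven by cell density: a 2-D kernel density estimate on (log10 fsc,
log10 red), the dominant low-scatter mode at the density maximum (ties
toward lower scatter), and membership as the connected region above
`min_density` (default 0.001) of the peak density. The highest-density
contour holding `mass_fraction` (default 0.9) of the KDE mass is reported
as the mode core for diagnostics; it is deliberately not the membership
cutoff, because a 0.9-mass region by definition excludes ~10% of a
clean cluster while the low-density connected region captures essentially
all of it without bridging to separated modes. The step is deterministic:
no random initialization is involved.

## Mie sizing

Forward scatter is converted to equivalent spherical diameter (ESD) with a
forward Mie model for homogeneous spheres. The Mie coefficient series is
truncated at `N = ceiling(x + 4x^(1/3) + 2)`; the size parameter uses the
medium index, `x = pi D n_medium / lambda`, with relative index
`m = n_particle / n_medium` (seawater 1.34). The detector is an annular
cone bounded by two half-angles; the unpolarized phase intensity is
integrated over the annulus by Gauss–Legendre quadrature (48 nodes;
refining 10-fold changes responses by < 0.5%) and divided by the same
integral for a 1-micron sphere of the bead index (1.60), so a 1-micron
bead has response exactly 1 and all responses are bead-normalized.

The default geometry (half-angles 2° and 15°) represents a forward-scatter
detector with a central obscuration: genuinely forward collection keeps
the response monotone in diameter at all three cell refractive indices
(1.35, 1.38, 1.41), whereas wide annuli beginning at 10–15° lose the
forward lobe and develop plateaus for the lowest-contrast index. The two
half-angles are free parameters fit to a bead calibration table by
`calibrate_geometry()` (Nelder–Mead on squared log10 residuals from
several starts, with the fit R² reported; if no start improves on the
current geometry it is kept, with a warning).

Because raw Mie curves oscillate, `build_lookup()` replaces each response
curve by its least-squares monotone envelope (`isoreg`), making inversion
single-valued; within flat stretches ties break toward the smaller
diameter. `scatter_to_esd()` interpolates linearly in (log10 scatter,
log10 diameter), clamping values outside the table to the endpoint
diameters with a flag and returning `NA` (flagged) for non-positive
scatter. For fixed scatter, a higher assumed refractive index yields a
smaller ESD, so reporting all three indices brackets the size of real
cells whose index is unknown.

Cellular carbon comes from the biovolume power law
`fgC = 0.261 * V^0.860` with `V = (pi/6) ESD^3` in cubic micron —
sub-linear, so carbon per unit volume declines with size.

## Quantification and its error model

The analyzed sample volume is flow rate × duration; the virtual-core
volume is that volume times the OPP-to-total ratio; abundance is the
population count divided by the core volume. The reported abundance
standard error carries only the flow-rate calibration uncertainty (the
relative SE of the flow rate, delta method — default 5% when
uncalibrated); Poisson counting error is computed but kept in a separate
`abundance_se_count` column, never merged, so users can choose either
error model downstream.

## Quality control

Files fail instrument QC when stream pressure deviates by strictly more
than 5% from the cruise mean, or when the event rate strictly exceeds
18,000 particles per second (coincidence regime). Flags are tri-state —
pass, fail, or not-evaluable when inputs are missing — and flagged files
are retained with flags set, never dropped. Derived quantities
(abundance, median ESD and median carbon at the mid index) are screened
per cruise and population with the classical single-pass Chauvenet
criterion: a point is an outlier when `N * P(|Z| >= z) < 0.5` under the
normal law, i.e. outside the band holding probability `1 - 1/(2N)`. The
rule is applied once, without re-estimating moments after removal, and is
invariant under affine transforms of the series.

## The cruise simulator

`simulate_cruise()` emits event files, ship metadata, a bead calibration
table, a matched gating specification and per-particle truth,
deterministically from a seed. Its measurement model mirrors the
assumptions above:

* **Arrivals** are Poisson per population with rate concentration × flow.
* **Sizes** are lognormal per population; forward scatter comes from the
  package's own Mie forward model at the population's refractive index.
* **Virtual core**: each particle draws a uniform position in the stream
  cross-section; the position detectors see
  `d = fsc * A * exp((r/w)^2) * exp(±b·u)` — a radially symmetric gain
  with opposing lateral sensitivity, the simplest model in which centered
  particles give equal, low position-detector signals and the OPP
  predicates recover exactly the central region of the stream.
* **Noise** is multiplicative lognormal with a common-mode term (0.04
  dex) shared by forward scatter and both position detectors plus smaller
  detector-specific terms (0.02 dex). The common-mode structure reflects
  that all three signals derive from the same laser interrogation of the
  same particle — per-particle illumination and stream variability scale
  them together. This matters statistically: independent scatter noise
  would act as errors-in-variables on the anchored regressions and bias
  the boundary slopes, a bias the real shared-illumination physics does
  not produce.
* **Beads**: the 1-micron normalization bead is co-run with the standard
  calibration ladder (0.3–5.7 micron, 40% of bead concentration), giving
  the anchored regressions leverage across the scatter range, as a
  single-size bead cloud cannot constrain a slope.
* **Fluorescence** is lognormal per population in bead-normalized units;
  default centroids sit at least one decade apart in their gating planes
  (abundant dim *Prochlorococcus*, phycoerythrin-bright *Synechococcus*
  and *Crocosphaera*, red-bright picoeukaryotes). A `"hard"` preset
  overlaps *Prochlorococcus* with the noise floor to stress the density
  clusterer.
* **Defaults**: 3-minute files, 0.1 mL/min sample flow (≈ 70,000
  particles per file at the default concentrations of 200 / 20 / 10 / 2
  cells/µL for *Prochlorococcus* / *Synechococcus* / picoeukaryotes /
  *Crocosphaera* and 1 bead/µL), 5% flow-rate calibration SE.

What the simulator does **not** emulate: optical saturation and detector
nonlinearity, multi-particle coincidence, debris and noise-floor events,
pigment variability with light history (diel fluorescence shifts),
non-spherical or structured cells (vacuoles, frustules), and drift of
gains within a cruise. Passing the recovery tests therefore shows the
pipeline machinery is consistent under its own measurement model, not
that real-ocean classifications are this clean; on real data the
populations overlap more and acceptance corrections are imperfect.

## Numerical choices and edge cases

* Quantiles in summaries use the linear-interpolation (type-7)
  convention, stated here for bit-reproducibility.
* Rows with any non-positive channel are excluded before log transforms;
  empty populations are omitted from summaries; missing metadata
  propagates as `NA`, never as zero.
* The pressure QC comparison applies a 1e-9 relative guard so a deviation
  of exactly the tolerance is "not more than" the tolerance even after
  floating-point arithmetic.
* Filtration and gating identification numbers are deterministic 32-bit
  hashes of the parameter values at 12 significant digits — stable across
  CSV/YAML round-trips, distinct for any meaningful parameter change.
* Diameter grids are 2,000 log-spaced points on [0.2, 6] micron;
  simulations in the test suite use coarser grids (300–600 points) and
  shorter files (10–30 s), which leaves interpolation error far below the
  tolerances tested. The end-to-end recovery check uses a 20-file cruise
  at the full default conditions.
* Re-running any pipeline or simulation with the same configuration and
  seed reproduces byte-identical curated output; the run log is the only
  output not covered by that guarantee.

## Known limitations

The channel-to-filter mapping is recorded as configuration
(`pipeline_defaults()$filter_map`) rather than hard-coded: published
descriptions of such instruments disagree on which bandpass feeds the
"red" versus "orange" label, so the package names channels by pigment
role — red as the chlorophyll proxy, orange as the phycoerythrin proxy —
and leaves the filter wiring as metadata. ESD is only as good as the
homogeneous-sphere assumption; for large or structured cells the
refractive-index bracket should be treated as a sensitivity range, not a
confidence interval. The abundance SE excludes counting error by design
(it is reported separately), so sparse populations in short files are
best compared using both columns in quadrature.
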