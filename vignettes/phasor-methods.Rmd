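---
title: "Phasor FLIM analysis of free and bound NADH: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor FLIM analysis of free and bound NADH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimphasor)
```

## The phasor model

A TCSPC pixel records photon counts `I_k` in `N` time bins spanning one
excitation period `T = 1/f` of the pulsed laser. The phasor transform maps
the decay to the normalized Fourier coefficients at harmonic `n` of the
repetition rate,

$$g = \frac{\sum_k I_k \cos(n\omega t_k)}{\sum_k I_k}, \qquad
  s = \frac{\sum_k I_k \sin(n\omega t_k)}{\sum_k I_k},
  \qquad \omega = 2\pi f ,$$

with `t_k` the bin-centre times. No decay model is fitted; the coordinates
themselves are the analysis. Three classical facts carry the whole
pipeline:

1. **Universal semicircle.** A mono-exponential decay with lifetime
   $\tau$ maps to $g = 1/(1+(\omega\tau)^2)$,
   $s = \omega\tau/(1+(\omega\tau)^2)$ — on the semicircle of radius 1/2
   centred at (0.5, 0), with $\tau = 0$ at (1, 0) and $\tau \to \infty$
   at (0, 0). Multi-exponential decays map strictly inside.
2. **Vector algebra.** A mixture with intensity fractions $f_n$ of
   species with phasors $(g_n, s_n)$ sits at
   $\left(\sum f_n g_n, \sum f_n s_n\right)$. Two species span a segment,
   three a triangle (barycentric coordinates recover the fractions), N a
   convex polygon.
3. **Lifetime read-back.** $\tau_\phi = s/(g\omega)$ and
   $\tau_m = \sqrt{1/(g^2+s^2) - 1}\,/\,\omega$ agree on the semicircle
   and split apart inside it — the signature of a multi-exponential decay.

Free NADH has a short lifetime, protein-bound NADH a long (and itself
multi-exponential) one, so every pixel of an NADH image lands on the
segment between the two reference phasors. The orthogonal projection onto
that segment, parameterized 1 at the free end and 0 at the bound end, is
the *free-NADH fractional intensity*; the segment is the *metabolic
trajectory* from a glycolytic phenotype (free-rich) to an
oxidative-phosphorylation phenotype (bound-rich).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| repetition rate `f` | 80 | MHz | standard Ti:Sapphire two-photon source; fixes `T = 12.5` ns and `omega` |
| time bins `N` | 256 | – | typical TCSPC electronics depth; discretization residual < 1e-3 on (g, s) |
| harmonic | 1 | – | the default analysis plane; higher harmonics supported throughout |
| reference lifetime | 4.04 | ns | fluorescein, the classical mono-exponential calibration dye |
| free-NADH endpoint | 0.4 | ns | literature-typical effective free-NADH lifetime; configurable, not a measured constant |
| bound-NADH endpoint | 3.2 | ns | literature-typical effective bound-NADH lifetime; configurable |
| `min_counts` | 30 | photons | background cut below which a pixel's phasor is meaningless and becomes `NA` |
| smoothing | off | – | optional 3×3 median on g and s; off by default so quantitative results are filter-free |

The free and bound endpoint lifetimes deserve emphasis: they are
*configuration*. The NADH-phasor literature cites effective values near
0.4 ns (free) and 3.2–3.4 ns (bound), but they vary with the enzyme pool;
every function that uses a cursor accepts explicit lifetimes or explicit
`(g, s)` endpoints, and no test in the package treats the defaults as
biological truth.

## Undefined pixels

A pixel with zero (or sub-threshold) total counts has no phasor. The
package represents this with an explicit `NA` marker that every stage
propagates — the median filter never interpolates across it, fraction maps
render it black, ROI averages exclude it, and the phasor-field file format
stores an explicit validity plane. Nothing ever silently becomes (0, 0).

## Calibration

The instrument response (timing offset, pulse broadening, detector and
electronics dispersion) multiplies every measured phasor by the same
complex factor $m\,e^{i\varphi}$ at a given harmonic. Measuring a
reference fluorophore of known lifetime determines the factor;
`estimate_calibration()` returns the corrective rotation
(`phase_shift = phi_expected − phi_measured`) and modulation scale
(`m_expected / m_measured`), and `apply_calibration()` multiplies it back
out. Sign convention: with the `g + i s` convention (s ≥ 0), a *delayed*
decay gains phase, so a pure IRF delay $\Delta t$ produces
`phase_shift = −omega * dt`, and a centred Gaussian IRF of width
$\sigma$ produces no phase change and a modulation boost
$\exp((\omega\sigma)^2/2) > 1$. Estimate-then-apply on the same reference
is exact to machine precision by construction.

## Cell phasors and statistics

The per-cell statistic is the intensity-weighted mean of the per-pixel
phasors over a segmented ROI. Weighting by pixel intensity is not a free
choice: it is the unique averaging rule that makes the ROI mean
algebraically identical to the phasor of the pooled (summed) ROI decay, so
the cell phasor is exactly "the phasor of the cell's photons" and its shot
noise scales with the cell's total photon count rather than the worst
pixel's. The unweighted pixel mean is available behind
`weighted = FALSE` for sensitivity checks. ROIs come in as label images
(hand-drawn or generator-emitted); the package deliberately implements no
automatic cell segmentation, mirroring manual segmentation practice.

Groups of cell phasors are compared with a Welch (unequal-variance)
two-sided t-test on the g coordinate — the axis along which free/bound
shifts express themselves. Welch is the default because equality of group
variances is exactly what the heterogeneity analysis questions; the pooled
test is available (`var_equal = TRUE`), as is testing the free fraction,
which is monotonically related to g under a fixed cursor. Group
heterogeneity is summarized as `delta_g`, the sample standard deviation
(n − 1) of cell g values. Only explicitly requested pairwise comparisons
are computed, so no multiple-testing correction is applied. Frame-to-frame
stability pools consecutive 10-frame blocks, computes a cell phasor per
block, and reports both `delta_g` across blocks and a linear g-trend with
a 95% CI as a drift detector (with exactly two blocks the trend is
reported as undetermined).

## The synthetic generator: what it emulates, what it does not

`simulate_decay()` builds the expected counts of a periodically wrapped
multi-exponential decay, circularly convolved with an instrument response
(time shift + Gaussian broadening, applied through its exact Fourier
factor on a 16× oversampled grid so a pure shift obeys the shift theorem
exactly at every harmonic), scales to a photon budget and draws Poisson
counts. `simulate_cell_image()` paints compartments (nucleus free-rich and
dim, mitochondria bound-rich and bright, cytoplasm intermediate) and
`simulate_population()` places non-overlapping circular cells whose
per-cell free fractions are drawn from a truncated normal around a
condition preset. Every output is a pure function of (specification,
seed).

The condition presets encode the qualitative topology of the NADH
metabolic trajectory — progenitors above neurons (E12 0.70 > E16 0.60 >
neuron 0.40 in mean free fraction, between-cell sd 0.05), respiration
block (KCN) and high glucose above control, oxidative stress (H2O2) and
glycolysis inhibition (DCA) below — with separations chosen to reproduce
the figure-level ordering and significance behaviour of real populations.
They are deliberately *not* measurements: no public numeric cell-phasor
table exists for these populations, so the presets are stand-ins whose
directions, not values, are the constrained content. The ordering
constraints are asserted at preset construction so a misconfigured preset
fails immediately. Default photon budget is 500 photons/pixel (realistic
TCSPC imaging); parameter-recovery oracles run at 1e4 photons/pixel and in
a noise-free mode that returns expected counts.

What the generator does **not** model: scanning artifacts, detector
afterpulsing, spectral channels and emission spectra (the excitation
wavelength is metadata only), autofluorescence background other than a
flat Poisson floor, or absolute photon budgets of any particular
microscope. Passing tests therefore demonstrate that the *pipeline*
recovers what the *model* generates; they say nothing about biology beyond
the model's assumptions.

## Numerical choices

* **Time base.** Uniform mid-bin sampling, `t_k = (k + 0.5) T / N`,
  256 bins by default; both configurable. No sinc binning correction is
  applied: mid-bin sampling cancels the first-order aliasing terms, and
  the residual inflation of the modulation is about
  $(\omega\,\Delta t)^2/24$ relative — below 1e-3 on (g, s) at 256 bins.
  A consequence worth knowing: the *discrete* phasor of a
  mono-exponential sits up to ~8e-5 *outside* the ideal semicircle at
  256 bins (and components faster than a bin width degenerate toward a
  delta at the first bin centre, which is off the circle by
  construction). Geometry tests therefore use a 1e-4 band at 256 bins
  and a 1e-6 band on an 8192-bin grid.
* **Cursor consistency.** Because mixture linearity holds *exactly*
  under the discrete transform, building the cursor endpoints from
  mono-exponential decays binned on the same grid as the data
  (`species_cursor(n_bins = ...)`) makes noise-free fraction recovery
  exact to machine precision. Closed-form endpoints remain the default
  for hand-built cursors; the two differ by the ~1e-5 discretization
  offset, negligible at any realistic photon budget.
* **Off-segment pixels.** Shot noise pushes phasors off the cursor
  segment. The two-species fraction projects orthogonally and clamps to
  [0, 1] so maps are renderable everywhere; the three-species barycentric
  output is *not* clamped — outside-triangle points are flagged — because
  triangle fractions are quantitative. With two coincident triangle
  vertices the decomposition degenerates to the line rule, splitting the
  shared fraction equally.
* **Containment tolerance.** Polygon/semicircle membership uses 1e-9
  boundary tolerance; "on the semicircle" checks use 1e-6.
* **Degenerate inputs.** Zero-modulation references, collinear triangle
  vertices, empty ROIs, overflowing 16-bit counts and sidecar/page
  mismatches all raise named errors rather than propagating garbage.

## Problem sizes used by the test-suite

Simulation-backed tests run at deliberately desk-friendly sizes chosen to
keep the statistical margins wide: populations of 10–20 cells at 1e4
photons/pixel on 256×256 (or smaller) frames for the significance and
recovery checks, 160×160 frames with 64 bins for the three-seed trajectory
ordering, and 70-frame 64×64 stacks at 500 photons/pixel for the
stability protocol. The measured margins (recovery MAE ~2e-4 against a
0.02 bound; p ~ 1e-22 against a 1e-4 bound) make these sizes comfortable.

## Known limitations

* The analysis is two-endpoint by design; it quantifies position *along*
  the free–bound segment and does not unmix which enzymes bind the bound
  pool (a three-or-more-species question the triangle/polygon tools can
  pose, but for which the package ships no NADH-specific references).
* No `.sdt`/hardware ingestion: input is the documented TIFF + sidecar
  format.
* No automatic segmentation; ROI quality is the user's responsibility.
* PNG label files are 8-bit (≤ 255 ROIs); use TIFF for more.
* The CLI covers the scripted pipeline, not interactive cursor dragging;
  cursors and phasor-plot regions are specified in configuration.
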