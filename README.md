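# flimphasor

Fit-free phasor analysis of NADH fluorescence lifetime images (FLIM), in R.

## The problem

NADH is an intrinsic metabolic biomarker: its fluorescence lifetime is short
when the coenzyme is free in solution and long when it is protein-bound, so
the free/bound balance reads out the glycolysis vs oxidative-phosphorylation
balance of a living cell without any label. Time-correlated single photon
counting (TCSPC) microscopy records a full photon-arrival histogram in every
pixel; the phasor approach analyses those decays without fitting
multi-exponential models, which makes it fast, robust at low photon counts,
and graphical.

`flimphasor` implements that pipeline end to end for people doing label-free
metabolic imaging (and for anyone who wants a tested, scriptable phasor
stack): per-pixel phasor transform, reference calibration, free/bound-NADH
fraction maps, per-cell "cell phasors" from label-image segmentations, and
population statistics. Because raw microscope data are rarely shareable, the
package also ships a synthetic TCSPC image generator (cell phantoms,
condition presets, Poisson photon noise, instrument-response shift and
broadening) so every stage is verifiable on data with known ground truth.

## The model

For a decay `I(t)` over one excitation period `T = 1/f` (default 80 MHz,
`T = 12.5` ns), the phasor at harmonic `n` is

    g = ∫ I(t) cos(nωt) dt / ∫ I(t) dt,   s = ∫ I(t) sin(nωt) dt / ∫ I(t) dt,

with `ω = 2πf`. A mono-exponential decay with lifetime τ maps to

    g = 1 / (1 + (ωτ)²),   s = ωτ / (1 + (ωτ)²),

a point on the *universal semicircle* from (0, 0) (τ → ∞) to (1, 0)
(τ = 0). Phasors add vectorially: a mixture with intensity fractions `f_k`
sits at `Σ f_k (g_k, s_k)`, so two species span a segment, three a
triangle, N a polygon. Projecting a pixel's phasor onto the segment joining
the free-NADH and bound-NADH reference phasors yields its free-NADH
fractional intensity; along this segment runs the metabolic trajectory from
glycolytic (free-rich) to oxidative (bound-rich) phenotypes. The instrument
response is calibrated away by measuring a reference fluorophore of known
lifetime (fluorescein, 4.04 ns) and rotating/rescaling all phasors
accordingly. Cell phasors are intensity-weighted ROI averages — identical to
the phasor of the pooled ROI decay — and groups of cells are compared with
Welch t-tests on the g coordinate.

## Worked example

```r
library(flimphasor)

# a progenitor-like and a neuron-like population, 20 cells each,
# 1e4 photons/pixel, with ground-truth ROIs
run <- function(cond, seed) {
  pop   <- simulate_population(condition_preset(cond), n_cells = 20,
                               photons = 1e4, seed = seed)
  field <- image_phasor_field(pop$image)          # per-pixel (g, s)
  cell_phasors(field, pop$rois,
               cursor = species_cursor(n_bins = 256))
}
records <- dplyr::bind_rows(run("E12", 101), run("neuron", 102))

summarize_groups(records)
#> # A tibble: 2 × 6
#>   group  n_cells mean_g mean_s delta_g mean_free_fraction
#>   <chr>    <int>  <dbl>  <dbl>   <dbl>              <dbl>
#> 1 E12         20  0.763  0.268  0.0498              0.710
#> 2 neuron      20  0.567  0.341  0.0434              0.423

compare_groups(records)
#> <phasor_group_test> g_mean: E12 (n=20) vs neuron (n=20)
#>   t = 13.26, df = 37.3, p = 1.098e-15 (Welch)

trajectory_order(summarize_groups(dplyr::bind_rows(
  records, run("E16", 103))))
#> <trajectory_order> strictly decreasing: E12 > E16 > neuron -> 0.7097, 0.6003, 0.4228
```

The mean free fractions recover the generator presets (0.70, 0.60, 0.40),
the progenitor population sits at higher g (toward free NADH), and the two
populations separate far below the p < 0.0001 bound. `autoplot(field)`,
`autoplot(fraction_map(field, cursor))` and `plot_cell_phasors(records)`
draw the phasor density, the free/bound map and the cell-phasor scatter.

A thin command-line wrapper (`inst/scripts/flim-phasor`) exposes the same
stages as subcommands (`simulate | phasor | calibrate | map | segment |
compare | stability`) composing through TIFF/CSV/JSON files; see
`?flim_cli`.

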