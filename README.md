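# sticcs

Spatiotemporal image cross-correlation spectroscopy (STICCS) and EB3
comet tracking for quantifying microtubule dynamics in two-channel
fluorescence time-lapse movies.

## The problem

Growing microtubule plus ends can be labelled with end-binding proteins
(EB3), which appear as moving "comets" in live-cell movies, while the
polymer itself is labelled with tubulin-GFP. Two complementary analyses
extract dynamics from such movies:

* **Particle tracking** (LoG detection + LAP linking, TrackMate-style)
  follows individual comets and yields per-cell growth metrics:
  assembly rate, growth length, growth duration, number of growth
  events.
* **STICCS** computes space–time correlation functions of intensity
  fluctuations in overlapping image subregions (16×16 px ROIs shifted by
  4 px; 30-frame TOIs shifted by 15 frames). For a subregion ("voxel"),
  the normalised correlation

  r_ab(ξ, η, τ) = ⟨δI_a(x, y, t) · δI_b(x+ξ, y+η, t+τ)⟩ / (⟨I_a⟩⟨I_b⟩)

  has a peak whose translation with temporal lag τ gives a local
  velocity vector — without tracking individual particles, so slow and
  dense motion remains measurable. The GFP autocorrelation maps
  microtubule movement, the EB3 autocorrelation maps assembly, and the
  GFP×EB3 **cross**-correlation detects co-transport of polymer and tip:
  *explorative* growth into unoccupied territory moves both signals
  together and produces a cross peak, whereas assembly along an existing
  bright fiber leaves the cross channel silent (*fiber-guided* growth).

The package implements the full chain — photobleaching correction,
background subtraction, temporal Fourier immobile filtering, voxel
correlation analysis, peak-translation velocity fitting, neighbourhood
similarity filtering, explorative/guided classification, comet tracking,
per-cell summaries and group statistics — plus a synthetic two-channel
movie generator with complete ground truth used to validate every stage.

## Worked example

```r
library(sticcs)

# simulate one cell: radial fiber network, 50 growth events at
# 20 um/min, 30% explorative, camera noise and bleaching
p   <- sim_params(explorative_fraction = 0.3, seed = 1)
sim <- simulate_cell(p)

res <- analyze_cell(sim$gfp, sim$eb3, sim$mask, cell_id = "demo")
res$summary[, c("assembly_speed_um_min", "cross_fraction_pct",
                "track_assembly_rate_um_min", "track_n_events")]
```

A full multi-condition run with group statistics:

```r
res <- run_pipeline(demo_config(seed = 7))
res$summaries[, c("cell_id", "assembly_speed_um_min",
                  "cross_fraction_pct", "track_assembly_rate_um_min")]
#>               cell_id assembly_speed_um_min cross_fraction_pct track_assembly_rate_um_min
#> 1      guided_fast_01              21.32339           26.35432                   19.74182
#> 2      guided_fast_02              20.63718           41.13821                   18.36622
#> 3      guided_fast_03              21.99934           39.37500                   19.86516
#> 4 explorative_slow_01              15.62198           60.06006                   12.49909
#> 5 explorative_slow_02              15.88513           46.07251                   12.84916
#> 6 explorative_slow_03              15.68337           60.09245                   12.57160
res$groups$assembly_speed_um_min
#> group_result for 'assembly_speed_um_min' (t test, P = 0.00371)
#>   guided_fast: 21.3 +/- 0.393 (n = 3)
#>   explorative_slow: 15.7 +/- 0.0795 (n = 3)
```

The two simulated conditions differ in growth speed (20 vs 12 µm/min)
and explorative fraction (0.3 vs 0.6): the pipeline recovers the faster
assembly in the first condition and the higher proportion of
cross-correlated (explorative) growth events in the second, with the
comet tracker agreeing on the speed ordering.

Everything is driven by plain configuration lists (or JSON/YAML files;
see `inst/extdata/demo_config.json`), and a thin command-line wrapper is
available at `inst/scripts/sticcs_pipeline.R`.

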