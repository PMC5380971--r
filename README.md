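# lipodrop

Quantitative analysis of lipid droplets (LDs) in multi-channel
fluorescence microscopy: how many droplets a cell holds, how their
projected areas distribute, which droplets sit in boundary-contact
clusters, whether clustered pairs are static or dynamic in live
recordings, and whether marker proteins (e.g. non-muscle myosin IIa or
formin-family actin nucleators) form patches at droplet surfaces,
droplet–droplet contacts and dissociation sites.

The package is aimed at cell biologists quantifying neutral-lipid
storage phenotypes (RNAi / drug perturbations, patient cells) from
standard confocal, Airyscan or label-free CARS recordings.

## What it computes

**Still-image morphometry** (`run_morphometry`) runs a three-tier
hierarchy on a (nuclei, cytoplasm, LD) field:

1. nuclei by windowed Otsu thresholding with watershed declumping and a
   diameter gate (default 100–250 px);
2. cell bodies by seeded intensity propagation from the nuclei
   (CellProfiler-style geodesic cost, `EBImage::propagate`);
3. LDs by an undecimated à-trous B3-spline wavelet spot detector with
   separate small/large scale maps, per-region half-maximum refinement,
   and a fragment-merge correction for large droplets split by the
   detector.

Droplets are clustered by the boundary-gap rule — two LDs are clustered
when the minimum distance between their pixel centres is ≤ 2 px, i.e.
0.266 µm at the default 0.133 µm/px calibration — and summarised per
cell: size-class histogram ([0,0.5), [0.5,1), [1,1.5), [1.5,2), ≥2 µm²),
clusters per 100 LDs by cardinality (2, 3, 4, 5, ≥6), and mean ±
heterogeneity (sample s.d.) of clustered-LD areas.

**Time-lapse dynamics** (`run_dynamics`) detects droplets per frame,
tracks them by exact gated minimum-cost matching, derives per-frame pair
association states (gap ≤ threshold), classifies pairs as *static*
(associated in every observed frame of a 5-min window) or *dynamic*,
detects persistent dissociation events, and scores marker co-occurrence
at the event site (3σ above the frame background) with "before"/"during"
onset timing.

**Foci counting** (`detect_foci`, `assign_foci`) finds marker patches in
z-stacks (per-section maxima above a preset minimum intensity, merged
across sections) and counts them at LDs with diameter ≥ 1 µm and at
LD–LD contact sites (a patch associated with two neighbouring LDs).

**Synthetic data** (`generate_field`, `generate_timelapse`) renders
fields and movies with complete planted ground truth — cells, nuclei,
right-skewed LD areas (~90 % below 0.5 µm²), clusters at exactly the
2-px criterion, diffraction-limited foci, Poisson–Gaussian noise, and
two-state Markov association kinetics — so every stage above can be
validated against known truth.

## Worked example

```r
library(lipodrop)

# a synthetic field: 2 cells, ~100 LDs each, peak SNR 10
sp  <- field_spec(seed = 7)
fg  <- generate_field(sp)
cfg <- pipeline_config(output_dir = "ld_out", seed = 7)
res <- run_morphometry(cfg, fg$image)
#> morphometry: segmenting nuclei
#> morphometry: 2 nuclei
#> morphometry: 2 cells
#> morphometry: 187 droplets
#> morphometry: 14 clusters

res$per_cell[, c("cell_id", "n_lds", "mean_area_um2", "n_clusters",
                 "clustered_mean_area_um2", "rate_2")]
#>   cell_id n_lds mean_area_um2 n_clusters clustered_mean_area_um2   rate_2
#> 1       1    93     0.2537325          7               0.3217187 5.376344
#> 2       2    94     0.2645823          7               0.3953492 3.191489
```

Cell 1 holds 93 detected droplets of mean projected area 0.25 µm²; 7
clusters were found, clustered droplets average 0.32 µm², and there are
5.4 two-droplet clusters per 100 LDs. `ld_out/` now contains
`droplets.csv`, `clusters.csv`, `per_cell.csv`, the three label-map
TIFFs and the resolved `config.yaml` that reproduces the run.

For a movie:

```r
tl  <- generate_timelapse(sp, k_dissoc = log(2) / 150, k_assoc = 0,
                          n_pairs = 40, seed = 7)
dyn <- run_dynamics(pipeline_config(output_dir = "ld_dyn",
                                    detection_method = "threshold",
                                    seed = 7),
                    tl$ld_frames, tl$marker_frames)
dyn$summary
#>             n_pairs n_pairs_full_window     static_fraction
#>          42.0000000          40.0000000           0.2500000
#>            n_events   fraction_positive     fraction_before
#>          30.0000000           0.7666667           0.6956522
#>     fraction_during
#>           0.3043478
```

With a dissociation half-life of 150 s over a 300-s window, a quarter
of pairs are expected to remain static (e^(−ln2·2) = 0.25); the
measured fraction over the 40 fully observed pairs is exactly 0.25.
All 30 planted dissociation events were detected; 23 of them (77 %)
were marker-positive in the ground truth and the scored fraction is
0.767, with a before/during onset split of 16/7.

A thin command-line wrapper with `simulate` / `analyze` / `dynamics`
subcommands is installed at `inst/cli/lipodrop.R`.

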