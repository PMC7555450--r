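# tilkill

Quantification of immune-mediated killing of ex vivo tumor fragments from
multi-channel confocal z-stack time series.

## The problem

Checkpoint-inhibitor response can be read out ex vivo: tumor fragments
(150–300 µm) stained with CellTracker Green are perfused with
tumor-infiltrating lymphocytes (TILs, CellTracker Red) pretreated with an
isotype control, anti-PD-1 or anti-CTLA4, under continuous annexin V-APC,
and imaged as three-channel confocal z-stacks (10 µm slices) every 3–4 h for
several days. A tumor voxel that is green **and** APC-positive is *dying*
(early apoptosis with the membrane still intact); APC-only tissue is *dead*
and may have many causes unrelated to treatment (loading damage, perimeter
flow damage, initially dead cells), so it is excluded from the response
statistic by the co-localization requirement.

`tilkill` implements that readout for analysts running such assays:

- **voxel classification** — per-channel low-intensity thresholds (strict
  inequality), per-z-slice minimum-area filtering of connected regions
  (union-find labeling, 4/8-connectivity in 2D, 6/26 in 3D), and the
  co-localization classes `live`, `dead`, `dying`, `til`, `dying_til`,
  `til_on_live`;
- **the normalized dying-tumor fraction** per fragment and timepoint,
  f(t) = V_dying(t) / V_tumor(t), with per-condition mean ± SE trajectories
  and fold increases over the isotype control (both the relative-increase
  and the ratio conventions are always reported);
- **group statistics** — a tie-corrected Kruskal–Wallis test written from
  first principles (midranks; C = 1 − Σ(t³−t)/(N³−N); optional exact
  permutation p for small designs), applied per timepoint; plus in vivo
  tumor-growth summaries (per-day means/SE under censoring and percent
  volume reduction versus vehicle);
- **a synthetic fragment simulator** — perturbed spheroids with a perimeter
  damage ring, a condition-dependent inward kill front, Poisson TIL
  arrivals with contact killing, live→dying→dead dye transitions, green
  photobleaching, and background + signal-proportional noise — with
  per-voxel ground truth, so the whole pipeline is testable without real
  data;
- **an orchestrator** (`run_pipeline()`, plus the thin `exec/tilkill`
  command-line wrapper) that chains simulate → classify → quantify →
  compare from one YAML/list config into deterministic CSV outputs with a
  run manifest.

## Worked example

Simulate a three-condition experiment (3 fragments per condition, default
200 µm fragments, five timepoints over 96 h), quantify it, and compare
conditions:

```r
library(tilkill)

cfg <- list(
  experiment = list(fragments_per_condition = 3, tumor_model = "MC38"),
  simulation = list(time_points = c(0, 24, 48, 72, 96)),
  thresholds = list(live_green = 480, til_red = 1100, dead_apc = 1100,
                    min_area = 100),   # um^2
  quantify   = list(plot = FALSE))

run_pipeline(cfg, mode = "full", out_dir = "demo", seed = 42)

read.csv("demo/condition_summary.csv") |> subset(time_h == 24)
#>   condition time_h n mean_fraction se_fraction
#>  anti_CTLA4     24 3        0.3407    0.002056
#>    anti_PD1     24 3        0.2217    0.000856
#>     isotype     24 3        0.0674    0.001469
```

After one day, 34% of anti-CTLA4-exposed tumor tissue is dying versus 22%
for anti-PD-1 and 6.7% for the isotype control (SE over the three fragments).
The fold-increase table reports both conventions against the control
(anti-CTLA4 at 24 h: relative increase 4.06, ratio 5.06), and
`kruskal_wallis.csv` holds the per-timepoint rank test — with n = 3/group
the three fully separated conditions give the maximal statistic H = 7.2
(p = 0.027, chi-square approximation):

```r
read.csv("demo/kruskal_wallis.csv")
#>  day k n_total     H      p p_holm
#>    0 3       9 0.267 0.8752  0.875
#>   24 3       9 7.200 0.0273  0.137
#>   ...
```

Because the run was simulated, `recovery.csv` compares every recovered
fraction against the simulator's ground truth; here the mean absolute error
is 0.013. The fold-increase arithmetic on reported group means works
directly too:

```r
fold_increase(0.13, 0.08)$relative_increase   # 13% over 8% -> 0.625
fold_increase(0.25, 0.08)$ratio               # 25% over 8% -> 3.125
```

## Layout of a real experiment

Real data enter as one multi-page TIFF per fragment per timepoint (pages
channel-major, channel names and voxel sizes in a JSON sidecar; lateral
voxel size has no default and must be supplied) plus a YAML layout mapping
fragments to conditions and stack paths; see `?read_stack`, `?load_layout`
and the vignette `vignettes/quantifying-fragment-killing.Rmd` for the data
model, the denominator and fold-convention choices, and what the simulator
does and does not emulate.
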