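# farmscapes

Farm-level ecosystem-service indicators for agricultural landscapes.

`farmscapes` screens a landscape of farms for ecosystem-service potential.
For every farm it computes nine spatial indicators from parcel geometry,
land cover, roads, crop sequences, population, visitor points and
protected-area layers; standardises them across the farm population; groups
farms by production type, livestock density and size; and compares each
group against an **area-weighted local reference** — the mean of the
surrounding reference farms within 20 km, weighted by their agricultural
area — using Welch *t*-tests and a Welch-consistent Cohen's *d*. A Spearman
redundancy screen then selects the indicators used in gridded regional
summaries.

Because register and map data of this kind cannot be shipped, the package
includes a deterministic synthetic-landscape generator that produces a
complete data bundle (farms, parcels, seven-year crop sequences, land-cover
mosaic, roads, population raster, visitor points, protection layers,
habitat points). All examples, tests and power analyses run on these
synthetic landscapes; the analysis code itself is agnostic about where the
bundle came from.

## The nine indicators

| Code | What it measures |
|---|---|
| `LanVar` | shared land-cover borders in the farm's study area (m/ha) |
| `CrpDst` | mean distance from interior cropland to other land cover |
| `Gra` | semi-natural grassland relative to agricultural area |
| `SSHab` | small-scale habitat points per cropland hectare |
| `CrpSeq` | seven-year crop-sequence quality score |
| `RodVar` | land-cover patches adjacent to roads per hectare |
| `Acc` | accessibility (roads nearby + population within 10 km) |
| `Visit` | photo and species-observation users per km² |
| `NatRes` | protected-area coverage of the study area |

## Worked example

```r
library(farmscapes)
cfg <- list(seed = 7, sim = list(n_farms = 120, world = 16000))
state <- run_pipeline(cfg, out = "readme_run")
nrow(state$farms)
#> [1] 101
head(state$raw[, c("farm_id", "lanvar", "crpdst", "gra", "sshab", "crpseq")], 5)
#>   farm_id lanvar crpdst gra   sshab crpseq
#> 1   F0001  45.26 116.10   0 0.08032 0.7262
#> 2   F0002 133.05  38.29   0 0.20000 0.6537
#> 3   F0003  43.02 107.63   0 0.19704 0.7454
#> 4   F0004  60.13  69.86   0 0.12500 0.5985
#> 5   F0005  76.97  81.05   0 0.00000 0.6315
```

120 farms are simulated on a 16 × 16 km world; 101 pass the selection
filters (the rest are grass-only holdings, farms without parcels, or farms
with insufficient crop-sequence coverage — see `readme_run/farms_excluded.csv`).

Group-versus-reference results for the detailed type scheme:

```r
rows <- state$comparisons[["type:detailed"]]$rows
head(rows[!is.na(rows$p),
          c("cluster", "indicator", "n_focal", "mean_D", "p", "d", "category")], 8)
#>        cluster indicator n_focal mean_D        p       d   category
#> 10 small_scale    LanVar      27  1.789 8.92e-09  1.9026      large
#> 11 small_scale    CrpDst      27 -0.599 2.09e-01 -0.3487      small
#> 12 small_scale       Gra      27  0.521 1.53e-02  0.7033   moderate
#> 13 small_scale     SSHab      27  1.241 2.48e-06  1.5733      large
#> 14 small_scale    CrpSeq      27  0.674 1.88e-03  0.9004      large
#> 15 small_scale    RodVar      27  0.290 7.49e-01  0.0880 negligible
#> 16 small_scale       Acc      27  0.247 8.77e-01  0.0425 negligible
#> 17 small_scale     Visit      27 -0.182 9.32e-01 -0.0234 negligible
state$retained
#> [1] "LanVar" "Gra"    "CrpSeq" "SSHab"  "Acc"    "Visit"  "NatRes" "CrpDst"
```

Small-scale farms in this landscape sit well above their local references
on landscape variation, small habitats and sequence quality. In this run
the redundancy screen drops only `RodVar` (strongly rank-correlated with
`LanVar` here); the remaining indicators feed the 15 km grid summaries in
`readme_run/grid_summary.csv`.

All artefacts (bundle, per-stage CSVs, `manifest.yaml` with checksums,
`pipeline.log`) land in the output directory, and a rerun with the same
configuration is byte-identical.

## Command line

The same pipeline is available as a CLI:

```sh
inst/cli/farmscapes all      --config cfg.yaml --out run1
inst/cli/farmscapes simulate --config cfg.yaml --out run2
inst/cli/farmscapes indicators --config cfg.yaml --out run2   # resumes from run2/
inst/cli/farmscapes validate --config cfg.yaml                # schema + deviations
```

Subcommands: `simulate`, `indicators`, `cluster`, `compare`, `screen`,
`map`, `all`, `validate`; flags `--config`, `--out`, `--seed`,
`--log-level`. Logs go to stderr and `<out>/pipeline.log`. Exit codes:
0 success, 1 user error, 2 internal error.

## Testing

```r
testthat::test_dir("tests/testthat", package = "farmscapes",
                   load_package = "installed")
```

Each quantitative claim is tested against an independently coded oracle:
geometry against brute-force polygon routines, each indicator against a
per-farm recomputation sharing no code with the engine, the test statistics
against textbook formulas, the 1-D k-means against exhaustive search, plus
null-calibration and planted-effect simulation experiments
(`tests/testthat/test-acceptance.R`; the simulation blocks dominate the
suite's run time). See the vignette for the validation design and a known
small-cluster calibration caveat.

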