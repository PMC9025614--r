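# tailmorph

Quantitative analysis for the **mouse tail test**, an in vivo
morphometric model of psoriasis. The scale epidermis of the mouse tail
is naturally parakeratotic (it lacks a granular layer, like psoriatic
skin); a topically applied anti-psoriatic substance induces
orthokeratosis, extending the granular layer along each scale. The
package is for pharmacology groups running this assay — or reanalyzing
its published summaries — who want the measurement and statistics layer
as tested, reproducible code instead of spreadsheet arithmetic.

For each scale (the epidermal unit between two adjacent hair follicles)
two primary lengths are measured in µm: *A*, the horizontal length of
the continuous granular layer, and *B*, the horizontal scale length
between the two follicles. From these:

- **orthokeratosis degree** of a scale: `100 · A / B` (percent);
- **percentual drug activity** of a treatment with group mean degree
  `Oks` against the vehicle-control mean `Okc`:
  `(Oks − Okc) / (100 − Okc) × 100`;
- **mean epidermal thickness**: the average of five vertical readings
  per scale from the dermo-epidermal junction to the lower border of
  the stratum corneum (stratum corneum excluded).

Group contrasts use the Kruskal–Wallis test; pairwise comparisons are
the two-sample special case with **exact permutation p-values on
per-animal means** (n = 6 per group), assembled into S/N significance
matrices at p ≤ 0.05.

The package covers the full pipeline:

- `default_study_specs()` — the reference seven-arm design (two
  negative controls, tretinoin 0.05% positive control, diclofenac and
  celecoxib at 1%/2%), 6 animals × 10 scales × 5 readings per group;
- `generate_measurements()` / `generate_study()` — synthetic per-scale
  tables from a two-level (animal/scale) truncated-normal model, fully
  reproducible via hashed per-animal/per-scale RNG substreams;
- `generate_label_image()` / `measure_image()` — schematic labeled
  pseudo-histology images with ground-truth sidecars, and the
  measurement algorithm (follicle detection, longest granular run,
  thickness sampling) that extracts A, B and thickness from them;
- `summarize_groups()`, `drug_activity()`, `rank_groups()` — scoring
  and report tables; `drug_activity_bootstrap()` for animal-level
  uncertainty;
- `kruskal_wallis()`, `pairwise_comparisons()` — the statistical layer;
- `run_config()` / `run_pipeline()` — one-call orchestration writing
  CSVs, Markdown tables, bar charts and a reproducibility manifest.
  A thin CLI wrapper lives at `inst/cli/tailmorph.R`
  (`generate|measure|score|stats|run` subcommands).

## Worked example

```r
library(tailmorph)

tab <- generate_study(default_study_specs(), seed = 42)   # 420 scales
s <- summarize_groups(tab, control_group = "white soft paraffin",
                      activity_exclude = "untreated mice")
writeLines(format_summary_table(s))
```

```
| Group | Orthokeratosis degree (%) | Mean epidermal thickness (µm) | Percentual drug activity (%) |
|---|---|---|---|
| untreated mice | 17.98 ± 1.54 | 25.04 ± 2.39 |  |
| white soft paraffin | 18.91 ± 3.01 | 29.81 ± 2.20 | 0.00 |
| tretinoin 0.05% | 45.75 ± 4.87 | 33.84 ± 2.57 | 33.10 |
| diclofenac 1% | 42.96 ± 13.55 | 28.70 ± 2.53 | 29.66 |
| diclofenac 2% | 38.89 ± 7.69 | 27.82 ± 3.17 | 24.64 |
| celecoxib 1% | 41.93 ± 6.94 | 27.41 ± 2.59 | 28.40 |
| celecoxib 2% | 55.00 ± 12.08 | 31.98 ± 6.14 | 44.51 |
```

Each row is one simulated arm: mean ± SD of the 60 per-scale degrees,
of the 300 pooled thickness readings, and the group's drug activity
against the vehicle (blank for the untreated baseline, 0 for the
vehicle itself). Celecoxib 2% induces the most orthokeratosis:

```r
rank_groups(s, "ok_mean")
#> "celecoxib 2%" > "tretinoin 0.05%" > "diclofenac 1%" > "celecoxib 1%"
#> > "diclofenac 2%" > "white soft paraffin" > "untreated mice"

pairwise_comparisons(tab, "orthokeratosis", unit = "animal")
```

```
                    untreated mice white soft paraffin tretinoin 0.05% ...
untreated mice                     N (0.31)            S (0.00216)
white soft paraffin N (0.31)                           S (0.00216)
tretinoin 0.05%     S (0.00216)    S (0.00216)
...
S = statistically significant; N = non-significant; p <= 0.05
```

Every treated arm separates from both negative controls while the two
controls do not separate from each other; 0.00216 = 2/C(12,6) is the
floor of the exact permutation test at 6 animals per group.

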