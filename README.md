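# linkerdock

Carbohydrates bind the intrinsically disordered inter-domain linkers of
GntR-family bacterial transcription factors weakly but persistently:
individual contacts look like nonspecific surface attachment, yet over
repeated docking rounds the same linker region fills with sugar molecules.
`linkerdock` is an R package for studying exactly this regime. It implements,
end to end and fully testable offline:

- an **empirical pairwise scoring function** on the AutoDock-Vina functional
  form: for each receptor–ligand heavy-atom pair at surface distance
  *s = d − r_i − r_j*,

  ```
  c_inter = Σ [ w₁·exp(−(s/0.5)²) + w₂·exp(−((s−3)/2)²) + w_rep·s²·1(s<0)
              + w_hyd·ramp(s; 0.5, 1.5) + w_hb·ramp(s; −0.7, 0) ]
  ΔG = c_inter / (1 + w_rot · n_rot)      [kcal/mol]
  ```

  with hydrophobic and H-bond terms gated by per-atom interaction classes
  and the rotatable-bond count `n_rot` as an entropic penalty;
- **stochastic flexible-ligand blind docking** (iterated Monte Carlo over
  rigid-body + torsion moves, Metropolis acceptance, Nelder–Mead polishing)
  over a whole-surface box;
- the **sequential multi-ligand protocol**: ten rounds in which each round's
  best pose is frozen into the receptor before the next fresh ligand copy
  is docked, plus the retained-subset rerun used to validate cluster
  stability;
- **geometric interaction profiling**: protein–ligand and ligand–ligand
  hydrogen bonds (heavy-atom donor–acceptor distance ≤ 3.6 Å) and ligand
  clusters (connected components of the contact graph);
- **region-aware statistics**: poses are classified as pocket / linker /
  bridging / nonspecific from residue-range annotations; nonspecific ΔG
  values are pooled into a background mean ± SD, and a binding energy is
  flagged significant when ΔG ≤ mean − 3·SD; occupancy summaries
  ("x.x ± y.y molecules per model"), exact Mann–Whitney U and Shapiro–Wilk
  tests;
- **global sequence alignment** (Needleman–Wunsch/Gotoh with affine gaps,
  BLOSUM62) for effector-domain homology comparisons;
- **synthetic generators** for every input: MD-like conformer ensembles of
  a two-domain protein joined by a flexible serine linker, pyranose-like
  ligands with rotatable hydroxymethyl arms, ground-truth H-bond fixtures
  and ΔG tables with planted significant binders.

Everything is tidyverse-native: analysis functions take and return tibbles,
fitted objects have `tidy()`/`glance()` methods, and results plot with
`autoplot()` / `plot_dg_heatmap()`.

## Worked example

Dock a sugar-like ligand sequentially against three synthetic conformers
and separate linker binding from the nonspecific background:

```r
library(linkerdock)

tp  <- make_toy_protein(toy_protein_spec(n_snapshots = 3, seed = 7))
lig <- make_toy_ligand("pyranose_like")
cfg <- protocol_config(n_rounds = 10,
                       docking = docking_config(n_runs = 2, n_steps = 50,
                                                seed = 7))
runs <- lapply(tp$ensemble, run_sequential, ligand = lig, config = cfg)

recs <- label_rounds(runs, tp$regions)
bg   <- compute_background(recs)
bg
#> <dg_background> pyranose_like: -2.41 +/- 0.26 kcal/mol (n = 13)

recs$significant <- flag_significant(recs$delta_g, bg)
head(dplyr::select(recs, -regions_touched), 5)
#> # A tibble: 5 × 7
#>   model_id time_label_ns ligand_species round delta_g category    significant
#>   <chr>            <dbl> <chr>          <int>   <dbl> <chr>       <lgl>
#> 1 toy_01              10 pyranose_like      1   -2.02 pocket      FALSE
#> 2 toy_01              10 pyranose_like      2   -2.44 nonspecific FALSE
#> 3 toy_01              10 pyranose_like      3   -2.28 linker      FALSE
#> 4 toy_01              10 pyranose_like      4   -2.42 linker      FALSE
#> 5 toy_01              10 pyranose_like      5   -2.52 pocket      FALSE

occupancy_summary(recs, "linker")
#> # A tibble: 1 × 4
#>   region mean_count sd_count n_models
#>   <chr>       <dbl>    <dbl>    <int>
#> 1 linker       3.67     1.53        3

find_clusters(runs[[3]]$final_complex)
#> # A tibble: 2 × 3
#>   cluster  size members
#>     <int> <int> <list>
#> 1       1     3 <chr [3]>
#> 2       2     3 <chr [3]>
```

Reading: across the three snapshots, 13 of the 30 placed ligands attached
nonspecifically, giving a background of −2.41 ± 0.26 kcal/mol; on average
3.7 ± 1.5 ligand copies per conformer sat on the linker (bridging copies
included), and in the third snapshot the ten copies condensed into two
contact clusters of three. Two of the 30 rounds beat the 3-SD significance
cutoff of −3.18 kcal/mol (the strongest pose reached −3.45); the rest are
the weak, surface-attached kind of binding expected on a featureless
miniature protein.
`run_pipeline(run_manifest(...))` wraps the same steps for whole ensembles
and writes heat-map TSVs (`ΔG|category|*` cells, rounds × time labels) plus
JSON summaries.

Homology comparisons use the same package:

```r
needleman_wunsch("HEAGAWGHEE", "PAWHEAE")
#> <alignment_result> score = 4, identity = 30.0%
#> HEAGAWGHEE
#> ---PAWHEAE
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end demonstration from scratch: it generates
the 3-snapshot toy ensemble under `--seed`, runs the 10-round sequential
protocol against the pyranose-like ligand, labels every round, pools the
nonspecific background and writes the report JSON to `--out`.

## Package layout

| Path | Contents |
|---|---|
| `R/structures.R` | PDB/SDF/MOL2 IO, interaction classes, Kabsch RMSD, regions |
| `R/synthetic.R` | toy ensembles, ligands, H-bond fixtures, ΔG tables |
| `R/scoring.R` | empirical scoring function |
| `R/docking.R` | Monte-Carlo pose search and local optimization |
| `R/sequential.R` | sequential protocol and retained-subset rerun |
| `R/profiling.R` | H-bond and cluster detection |
| `R/sitestats.R` | region labels, background stats, tests, heat maps |
| `R/seqhomology.R` | affine-gap global alignment |
| `R/workbench.R` | manifest-driven pipeline orchestration |

The methods vignette (`vignettes/linker-binding-analysis.Rmd`) documents the
model, parameter choices and limitations.
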