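# znsight

Template-based prediction of zinc (and, by coordination similarity, other
transition-metal) ion binding sites in protein structures, for structural
bioinformaticians screening experimental structures or predicted models
(AlphaFold/ESMFold-class) at scale.

Zinc binding is local stereochemistry: three or more side chains — His,
Cys, Asp, Glu, and occasionally Asn, Ser, Thr, Tyr — place their
coordinating atoms around the ion, usually tetrahedrally at 1.9–2.3 Å.
znsight searches a query structure for residue clusters whose composition
and Cα/Cβ pair distances match a curated library of experimentally
observed coordination templates (via an inverted index over binned pair
distances), places the ion by Levenberg–Marquardt minimisation of

```
Σ_i (d_i − d_ideal,i)²ideal = 2.15 Å (2.32 Å for Cys S)
```

scores each placement as

```
s = b1·dRMSD + b2·TRMSD + b3·HisAnglesScore + c      (lower is better)
```

with weights dispatched on (His present?, 3 vs ≥4 residues), and converts
s into a calibrated probability with Platt scaling,
`p = 1/(1 + exp(−(A·s + B)))`, A = −0.532, B = 7.306 (fitted through the
published anchor pairs (s = 3.36, p = 0.996) and (s = 15.32, p = 0.30)).
dRMSD measures deviation from ideal coordination distances, TRMSD the
superposition RMSD onto the matched template, and the His angle score the
misorientation of each histidine imidazole relative to the placed ion —
optionally minimised by sampling χ2 rotamers in 15° steps, which rescues
misoriented histidines in predicted models. Every prediction names the
template it is based on, so results are directly interpretable.

## Worked example

Build a small template library from synthetic ideal sites, perturb a
tetrahedral His₂-Glu-Cys site with 0.2 Å coordinate noise (emulating
predicted-model error), and run the pipeline:

```r
library(znsight)

fix <- make_fixture_library(list(c("HIS","HIS","GLU","CYS"),
                                 c("HIS","HIS","GLU")), seed = 42)
idx <- build_inverted_index(fix$library)

st <- perturb_site(make_ideal_site(c("HIS","HIS","GLU","CYS"),
                                   zinc = c(10, 4, -2), structure_id = "demo"),
                   0.2, seed = 99)
res <- run_pipeline(st, idx, pipeline_config())
predictions_table(res$predictions)
#>   structure_id site_rank  zinc_x   zinc_y    zinc_z
#> 1         demo         1 9.72747 4.175562 -1.997438
#>                              residues   chosen_atoms          template_id
#> 1 A:HIS:10;A:HIS:20;A:GLU:30;A:CYS:40 NE2;NE2;OE1;SG T001_CYS-GLU-HIS-HIS
#>       drmsd     trmsd his_angles_score       s         p
#> 1 0.1352052 0.2489394         36.44025 13.8398 0.4851098
```

The predicted ion lands 0.33 Å from the construction position (10, 4, −2).
`drmsd` (Å) and `trmsd` (Å) are small — distances and template geometry
survive the noise — while the His angle score (degrees) is inflated
because i.i.d. noise bends the rings themselves; the calibrated
probability p = 0.49 reflects that. On the unperturbed site the same call
returns the ion within 10⁻⁴ Å with s ≈ 0 and p ≈ 0.999.

Overlapping predictions are compressed best-first within 2.6 Å, the
distance below which two real zinc ions essentially never co-occur.
`match_predictions()`, `pr_curve()` and `mad_stats()` implement the
standard 2 Å / 5 Å benchmark protocol against ground-truth ion positions.

## Command line

```sh
Rscript -e 'znsight::znsight_main()' fixtures --out fix --seed 3
Rscript -e 'znsight::znsight_main()' curate   --in fix --out lib.json --seed 3
Rscript -e 'znsight::znsight_main()' predict  --library lib.json --in fix --out out [--no-rotamers] [--min-p 0.15]
Rscript -e 'znsight::znsight_main()' evaluate --pred out/predictions.csv --truth fix/truth.csv --radius 2 --out report.json
```

`predict` writes `predictions.csv`, one PyMOL `.pml` command script per
structure (ion spheres coloured red→yellow→green by p), and a JSON run
manifest. Identical inputs and seed give byte-identical CSV output.

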