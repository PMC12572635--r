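---
title: "znsight: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{znsight: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znsight)
```

## The problem and the model

Zinc is, after iron, the most abundant transition metal in proteins, with
structural, catalytic and regulatory roles. Its binding is overwhelmingly
local stereochemistry: three or more side chains — most often His, Cys, Asp
and Glu, occasionally Asn, Ser, Thr and Tyr — present their coordinating
atoms (His ND1/NE2, Cys SG, Asp OD1/OD2, Glu OE1/OE2, Asn OD1, Ser OG,
Thr OG1, Tyr OH) around the ion, typically in a tetrahedral arrangement
with bond lengths of 1.9–2.3 Å. znsight exploits this locality: it detects
clusters of residues whose composition and geometry match an
experimentally observed coordination template, places the ion, and reports
a calibrated probability that the site is real. Because every prediction is
anchored to a specific template, the output is directly interpretable — a
property the convolutional and gradient-boosting alternatives in this space
lack.

The pipeline, per query structure:

1. **Candidate pairs.** All residues of the eight coordinating types are
   collected; unordered pairs whose *binding points* (the single listed
   atom, or the mean of the two listed atoms for His/Asp/Glu) lie strictly
   closer than 7 Å are kept. A cell-grid neighbour search keeps this linear
   in the number of binding residues at bounded density.
2. **Inverted-index lookup.** Each template residue pair is posted under
   keys (sorted type pair, Cα–Cα or Cβ–Cβ distance bin). A query pair is a
   hit for a template pair slot when the types match and *both* distances
   fall within the bin tolerance. Candidate sites are completed from
   pairwise hits by backtracking, with a combinatorial cap per template.
3. **Ion placement.** Initial estimate: centroid of binding points for
   4+ residues; for 3-residue sites, two mirrored starts offset ±1.5 Å
   along the plane normal. The listed atom of each residue nearest the
   estimate becomes the coordinating atom, and the ion position is refined
   by Levenberg–Marquardt minimisation of
   $\sum_i (d_i - d_i^{\mathrm{ideal}})^2$, with ideal distances 2.15 Å
   (2.32 Å for Cys S).
4. **Histidine orientation.** For each coordinating His, two angles measure
   imidazole orientation relative to the placed ion: α, the elevation of
   the coordination bond out of the ring plane, and β, the in-plane
   deviation of the bond from the extension of the midpoint-to-nitrogen
   axis (midpoint of CD2/CE1 for NE2, CE1/CG for ND1). The His angle score
   is RMS(α) + RMS(β). For 3-residue sites with His, this score picks the
   mirror side; His-free 3-residue sites take a deterministic side "A".
5. **Rotamer sampling** (default on): the ring is rotated about the CB–CG
   (χ2) axis in joint ±15° proposals per His (≤ 3^h new states per round,
   h ≤ 4), re-selecting the nitrogen and re-refining the ion for each new
   configuration, keeping the best imidazole score, stopping at ±180°
   cumulative rotation, on no new configuration, or on no improvement.
   A visited-set guarantees no configuration is evaluated twice.
6. **Score and probability.** The composite score is
   $s = b_1\,\mathrm{dRMSD} + b_2\,\mathrm{TRMSD} + b_3\,\mathrm{HisAngles} + c$,
   with four parameter sets dispatched on (has His, 3 vs ≥4 residues) and
   $b_3 = 0$ without His; TRMSD is the minimum RMSD over same-type
   permutations after Kabsch superposition onto the template's coordinating
   atoms. The probability is the two-parameter logistic
   $p = 1/(1+e^{-(As+B)})$.
7. **Compression.** Overlapping predictions are suppressed best-first
   within a 2.6 Å radius (almost all binuclear zinc pairs are further
   apart), then the reporting threshold is applied.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| pair cutoff | 7.0 (strict `<`) | Å | upper bound on binding-point separation within one site |
| ideal distances | 2.15 / 2.32 (Cys S) | Å | centre of observed coordination-bond ranges |
| index bin width / tolerance | 1.0 / ±1 bin | Å / bins | tolerance must exceed typical Cα displacement between homologous sites |
| coordination cutoff (curation) | 2.8 | Å | brackets the 1.9–2.3 Å bond range with margin for coordinate error |
| 3-residue start offset | 1.5 | Å | ≈ apex height of typical coordination; the optimiser is insensitive within 0.5–3 |
| rotamer step / span | 15 / 180 | degrees | coarse enough to bound the state count, fine enough to land within one step of ideal |
| compression radius | 2.6 | Å | >99% of binuclear ion pairs are further apart |
| score weights, constants | four cases | — | taken as given (published optimisation); an AUC-PR objective can be plugged into any external optimiser |
| ideal α, β | 0, 0 | degrees | the angle scores square raw angles, implying zero ideals; configurable |
| calibration (A, B) | (−0.5322, 7.3055) | — | exact interpolation through the published anchor pairs (3.36, 0.996), (15.32, 0.30); refitting supported via `fit_platt()` |
| reporting threshold | p ≥ 0.15 | — | permissive default; p ≥ 0.39 ≈ max-F1 regime, p ≤ 0.20 for recall priority |

## Template curation

Templates are extracted from zinc-bound structures under three filters:
(1) at least three coordinating residues — fewer is predominantly a
crystallisation artifact; (2) the residue combination must occur in at
least three binding sites across at least three distinct structures;
(3) ion occupancy strictly above 0.5. One representative per accepted
combination is drawn uniformly at random under a recorded seed. B-factors
are deliberately not used as a filter: catalytic sites are often mobile.
Explicit user templates (`add_user_template()`) bypass the multiplicity
filters — only the three-residue minimum applies — so users can cover
combinations the multiplicity rule excludes.

## What the synthetic generator does and does not establish

`make_ideal_site()` builds sites whose *selected* coordinating atom sits
exactly at its ideal distance from a known ion position, in tetrahedral,
trigonal-apex or partial-octahedral geometry, with full side-chain
scaffolds and planar imidazoles pointing at the ion (α = β = 0). The
placement optimum, all three score features and hence s and p are therefore
analytically known, which is what the end-to-end identity tests exploit.
`perturb_site()` adds i.i.d. Gaussian noise per atom, emulating the
coordinate error of predicted models (mean site RMSD ≈ 0.6 Å for the
AlphaFold2 test systems that motivated the rotamer step).

Two caveats bound what a green test establishes. First, i.i.d. noise
distorts the imidazole ring *internally*; real rings are rigid bodies, so
real model error translates and rotates them instead. Under i.i.d. noise
the His angle score consequently carries irreducible error that χ2 sampling
cannot remove, deflating p. The robustness test therefore measures location
accuracy on the unthresholded pipeline (reporting threshold 0); the decoy
rejection test keeps its stated p ≥ 0.5 threshold. Second, synthetic decoys
and fillers do not reproduce the compositional background of real
proteins — precision measured on fixtures says nothing about precision on
proteomes; the published benchmark protocol (`match_predictions()`,
`pr_curve()`, `mad_stats()`) exists for users who supply real ground truth.

## Numerical choices

* **Levenberg–Marquardt:** analytic Jacobian $(x - p_i)/d_i$, damping
  ×10/÷10, convergence on step norm < 1e-8 or relative objective decrease
  < 1e-16, 200 iterations. Non-convergence returns the best point with
  `converged = FALSE` and a warning (intermediate rotamer proposals muffle
  it; only the selected configuration warns). Validated against a dense
  0.01 Å grid oracle and the closed-form trigonal apex height
  $h = \sqrt{2.15^2 - r^2}$.
* **Superposition:** Kabsch via SVD with reflection guard; correspondence
  by enumerating permutations within same-type groups (sites are ≤ 8
  residues, so this is small).
* **Ties:** atom selection ties break lexicographically (ND1 < NE2); equal
  mirror scores take side A; compression ties break on (chain, seq_id) of
  the first residue, then template id, making the retained set
  order-independent.
* **Degenerate inputs:** collinear 3-residue binding points raise a
  degenerate-geometry error and the site is skipped with a warning;
  log-loss probabilities clip at 1e-15; single-value MAD reports sd 0.
* **Altloc:** highest occupancy wins, ties to label 'A'; missing occupancy
  reads as 1.0 (required by the occupancy filter).

## Design choices where the design was open

* The curation coordination cutoff is unstated in the source method; 2.8 Å
  is used (see table) and is configurable.
* Whether Cα and Cβ distances gate a pair jointly or separately is
  unstated; both must match here (the stricter reading), configurable in
  principle via the index builder.
* Rotamer proposals are joint across His (3^h states per round), matching
  the stated complexity bound, rather than one-His-at-a-time.
* The ion is re-refined after every accepted rotamer move — the
  conservative reading of "selecting the optimal configuration at each
  step".
* Candidate sites matched by several templates are all scored; overlap is
  resolved by compression afterwards.
* A plain-text PyMOL command script replaces binary session output so the
  visualisation path is reviewable and testable.

## Known limitations

No χ1 or backbone sampling; no rotamer-library statistics (deliberately —
libraries mix apo and holo conformers). Nonstandard residues (e.g. MSE)
are excluded, not mapped to parents. Multi-chain sites are supported, but
the oligomeric assembly must be provided as input — monomers of
interface-binding proteins will be missed. No network fetcher: inputs are
files. The shipped fixture library is synthetic; real use requires curating
a library from experimental zinc-bound structures (`znsight curate`).
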