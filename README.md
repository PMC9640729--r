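# bindresp

Binding-site geometry features and multiclass drug-response classification
for receptor–inhibitor complexes.

Response of EGFR-mutated lung tumours to first-generation tyrosine kinase
inhibitors (gefitinib/erlotinib) is graded under RECIST into four classes —
complete, partial, stable, progressive (coded 0–3).  bindresp implements a
structure-informed pipeline for predicting that class: it reads
molecular-dynamics snapshots of a patient-specific receptor–drug complex
(multi-model PDB), derives geometric descriptors of the binding interface,
joins them with MM-GBSA energy components and encoded clinical covariates,
and trains four-class classifiers under a nested cross-validation protocol
with y-scrambling and feature-group ablation.  It is aimed at
computational structural biologists who already have MD trajectories and
per-patient tables and want the feature engineering and evaluation
machinery end to end.

## The descriptors

Atoms are weighted points *a = (p, w)* (default *w* = van der Waals
radius, Å).  Surface atoms are the boundary vertices of the weighted alpha
complex at parameter α (default 0, the space-filling surface).  Each
surface atom gets a solid angle Ω — the steradians covered by its incident
alpha-complex tetrahedra, per tetrahedron the sum of the three dihedral
angles at the atom minus π — and a convexity score

    Ω′ = cos(Ω) / 4,   convex if Ω′ > 0, concave if Ω′ < 0.

With surfaces *A* (complex), *B* (isolated target), *C* (isolated drug),
the interacting atoms are *I = (B ∪ C) − A*, split into target side
*I_t = I ∩ B* and drug side *I_d = I ∩ C*.  Per trajectory the package
computes:

* **matching rate** — matched (convex–concave) pairs across *I_t × I_d*
  within a contact cutoff, totalled over frames and divided by the frame
  count;
* **convex atoms** — convex complex-surface atoms near the interface;
* **connectivity** — receptor atoms within 40 Å of any drug atom,
  averaged over frames (plus an every-frame persistent variant);
* **binding-site positioning** — mean distance between binding-site CA
  atoms and the drug-center atoms (14 CA × 2 centers over 200 frames give
  a 200 × 28 matrix);
* **hydrogen bonds** — donor–acceptor pairs across the interface
  (≤ 3.0 Å, D–H···A ≥ 135° when hydrogens are present), trajectory total.

Features are z-scored with training-only statistics, composites
(x_g1, x_g2, x_p, x_e1) are means of z-scored constituents, and the
classifier grid — {10, 100, 500} estimators × {2, 4, 6, 10, 12} max
features × depth 3 — is searched in 3 inner folds inside 10 stratified
outer folds.

Because clinical cohorts of this kind are private, the package ships
generators that emulate one: lattice toy complexes with
combinatorially provable surface/interface/convexity ground truth,
jittered trajectories, and labeled cohorts with the 19/118/30/34 class
imbalance and tunable class separation.  See the methods vignette
(`vignettes/binding-geometry-methods.Rmd`) for the model, conventions and
limitations.

## Worked example

```r
library(bindresp)

# a toy receptor with a pocket, a ligand filling it, and 5 MD-like frames
tc   <- make_toy_complex(seed = 1)
traj <- jitter_trajectory(tc$frame, n_frames = 5, sigma = 0.05, seed = 2)
extract_geometric_features(traj)[, 1:5]
#>  matching_rate convex_atoms connectivity euclidean_distance hydrogen_bonds
#>             46         51.6          198               6.18            180

sets <- interface_sets(tc$frame, alpha = 0)
lengths(sets[c("I", "I_t", "I_d")])
#>   I I_t I_d
#>  24  15   9
```

46 matched convex–concave pairs per frame across the interface; 24 atoms
buried on complexation (15 target-side, 9 drug-side); all 198 receptor
atoms sit within 40 Å of the small ligand, and 180 polar interface
contacts accumulate over the 5 frames.  On a synthetic cohort the full
protocol:

```r
co  <- make_cohort(seed = 7)                  # 201 patients, 19/118/30/34
fit <- nested_cv_train(co[1:140, ], cv_protocol(seed = 7), "random_forest")
fit$report
#> nested CV ( 10 outer / 3 inner ), random_forest
#> mean accuracy: 0.9933 sd: 0.0211

evaluate(fit$model, co[141:201, ])
#> 4-class evaluation on 61 rows
#> accuracy: 0.9836  balanced accuracy (macro recall): 0.9688
#> macro precision/recall/F1: 0.9943 0.9688 0.9805
#>      pred
#> truth 0  1 2 3
#>     0 2  0 0 0
#>     1 0 43 0 0
#>     2 0  1 7 0
#>     3 0  0 0 8
```

The held-out accuracy is high because this cohort is generated
well-separated; `make_cohort(effect_size = "none")` collapses to the
majority baseline, and `y_scramble()` verifies the same for permuted
labels.

A thin CLI over the same functions lives at `inst/cli/bindresp.R`
(subcommands `surface`, `extract`, `assemble`, `simulate`, `train`).

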