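---
title: "Binding-site geometry and drug-response classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site geometry and drug-response classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindresp)
```

## The problem

Response of EGFR-mutated lung tumours to first-generation tyrosine kinase
inhibitors (gefitinib/erlotinib) varies widely between patients, and the
response class under RECIST (complete, partial, stable, progressive; coded
0--3) is the clinical quantity one would like to predict before treatment.
bindresp implements a structure-informed feature pipeline for this task: it
takes molecular-dynamics snapshots of a patient-specific receptor--drug
complex, derives geometric descriptors of the binding interface, combines
them with MM-GBSA energy components and encoded clinical covariates, and
trains four-class classifiers under a nested cross-validation protocol.
Everything downstream of the MD engine is in scope; running the simulations
themselves (force fields, thermostats) and computing the MM-GBSA energies
are not — their outputs are inputs here.

## Weighted alpha-shape surfaces and solid-angle convexity

Each atom is a weighted point $a = (p, w)$: $p$ its coordinates in
angstroms, $w$ a contact radius (by default the element's van der Waals
radius; atomic mass is available as an alternative scheme, recorded in
output metadata).  Two atoms are *orthogonal* when their spheres are
tangent, $|p_1 p_2| = w_1 + w_2$, and *sub-orthogonal* when the spheres
overlap, $|p_1 p_2| < w_1 + w_2$ — the only reading of the
tangency/overlap pair under which "orthogonal" means touching, which is
how `orthogonality()` implements it.

Surface atoms are vertices of the boundary of the weighted alpha complex,
built on point weights $w^2$.  A tetrahedron belongs to the regular
(weighted Delaunay) triangulation when its orthosphere is empty — every
other weighted point has positive power distance to it — and to the alpha
complex when additionally its orthoradius squared is at most $\alpha$.
The default $\alpha = 0$ is the boundary dual to the space-filling model,
the standard molecular-surface choice; it is exposed as a parameter
everywhere.  An atom is *interior* when every facet of its incident
tetrahedra is shared by two tetrahedra of the complex; otherwise it is on
the surface.  Atoms incident to no tetrahedron at all are exposed and are
reported as surface — the interiority criterion is vacuous for them, but
a bare atom is certainly not buried.

The convexity of a surface atom is scored through its solid angle
$\Omega$, the steradian measure covered by its incident alpha-complex
tetrahedra: per tetrahedron, the sum of the three dihedral angles along
the edges meeting at the atom minus $\pi$, summed over incident
tetrahedra.  The score is

$$\Omega' = \cos(\Omega) / 4,$$

convex when positive, concave when negative.  The constant $1/4$ is kept
although only the sign matters, and the raw $\Omega$ is always reported
alongside so alternative scores can be derived.  Two conventions are
fixed deliberately: a score of exactly zero (within $10^{-12}$) is
classified concave and flagged `boundary_score`; and atoms with
$\Omega > 2\pi$ — nearly enclosed, which the cosine nevertheless scores
positive over $(3\pi/2, 5\pi/2)$ — are flagged `high_omega` rather than
reinterpreted, since the score is implemented exactly as defined.  Note
the consequence: a locally flat surface atom ($\Omega = 2\pi$) scores
$+0.25$ (convex), a step edge ($\Omega = \pi$) scores $-0.25$ (concave),
and a pit base with walls on two sides ($\Omega \approx 2.9\pi$) scores
negative.  Whether solid angles should be accumulated over all incident
alpha-complex tetrahedra or only over surface-facet fans is genuinely
open; we use all incident tetrahedra and record that in the report
metadata.

### Numerical choices

Degenerate configurations (cospherical quintuples, ubiquitous in lattice
test fixtures) are resolved by a deterministic symbolic perturbation: the
predicates are evaluated on coordinates jittered by about $10^{-7}$ of
the bounding-box scale, with the jitter keyed on the atom serial, while
all reported angles are computed on the unperturbed coordinates.  Results
are therefore deterministic across runs and rigid-motion invariant to
machine precision.  Geometric predicates use a relative degeneracy
threshold of $10^{-13}$ on the orthocenter solve; fewer than four atoms
or a coplanar set raise a degenerate-geometry error from
`alpha_surface()`, while the interface machinery treats such
sub-structures (a two-atom ligand, a planar fragment) as trivially
all-exposed, which is the geometrically correct reading.

## Interface sets, matching rate, and the other descriptors

For each frame, `interface_sets()` runs the surface extraction three
times: $A$ on the full complex, $B$ on the isolated receptor, $C$ on the
isolated drug.  Atoms that are surface in an isolated structure but
buried in the complex are the interacting atoms

$$I = (B \cup C) - A, \qquad I_t = I \cap B, \qquad I_d = I \cap C.$$

A target-side/drug-side pair is *matched* when one atom is convex and
the other concave — the product of their $\Omega'$ scores (taken in each
atom's isolated structure) is strictly negative; zero scores never
match.  The matching rate is the total matched-pair count over the
trajectory divided by the number of frames $N$ — by definition a
per-frame matched count, not a fraction.  The
matched fraction over considered pairs is emitted as a supplementary
column.  Which pairs enter
the sum is not fully pinned down by the definition; we enumerate all
$I_t \times I_d$ pairs within a contact cutoff (default 5 angstroms,
`Inf` giving the unrestricted variant) to keep the statistic local.

The remaining descriptors per trajectory:

* **Convex interface atoms** — complex-surface atoms labeled convex
  within the interface neighbourhood ($I$ plus atoms within the contact
  cutoff of the ligand), averaged over frames.
* **Connectivity** — receptor atoms within 40 (angstroms, inclusive) of
  any drug atom per frame ($D_k$), averaged into $E_k$; the count of
  atoms connected in *every* frame is reported separately as the
  persistent variant, so both the per-frame and the all-frames reading
  of persistence are available.  The threshold is interpreted in
  coordinate units (angstroms); it is configurable and recorded in
  provenance columns.
* **Binding-site positioning** — Euclidean distances between binding-site
  CA atoms (default: residues with any atom within 5 angstroms of the
  ligand in frame 0, overridable by an explicit list) and the drug-center
  atoms (default: the two ligand atoms nearest the ligand centroid,
  configurable, or the centroid itself).  With 14 CA atoms and 2 centers
  a 200-frame run yields a 200 x 28 matrix whose grand mean is
  $D_{avg}$.
* **Hydrogen bonds** — geometric criterion mirroring the common MD
  post-processing defaults: heavy-atom donor--acceptor distance at most
  3.0 angstroms and, when the donor hydrogen is resolvable, D--H...A
  angle at least 135 degrees; structures without hydrogens fall back to
  the distance criterion, flagged in the output.  Donors/acceptors are N
  and O (S optional), counted across the receptor/drug interface by
  default.  The trajectory total is the primary feature (the emulated
  cohort range, roughly 775--1650 per 200-frame run, is a trajectory
  aggregate); the per-frame mean is reported alongside.

All distance comparisons are inclusive at the threshold.

## Feature assembly

Age in years is encoded 0--4 over the brackets up to 40, 41--50, 51--60,
61--70, and 71+, with boundary ages in the lower bracket.  Sex and
smoking are pre-encoded 0--2; code 2 for sex is accepted and documented
as "unrecorded" rather than guessed at.  Response is strictly the
prediction target — listing it among the clinical attributes would leak
the label — and survival time is post-treatment information carried only
as metadata.

Binding free energy combines the thermodynamic-cycle terms
$\Delta G = \Delta G_{bind,vac} + \Delta G_{solv,complex} -
(\Delta G_{solv,lig} + \Delta G_{solv,rec})$; the four MM-GBSA
components (VDW, EEL, ESURF, EPB) are carried as individual features.

Normalization is the z-score $z = (x - \mu)/\sigma$ with population
$\sigma$, fitted on training rows only and applied to test rows with the
training statistics; constant features map to 0 and are flagged.  The
z-score does not bound values to a fixed interval; a min-max variant is
offered, and values are never silently clipped.  Composite features
aggregate z-scored constituents by their mean — a scale-free,
order-independent operator chosen because the aggregation operator
itself is unspecified — giving `x_g1` (matching rate, connectivity,
hydrogen bonds), `x_g2` (convex atoms, positioning distance), `x_p`
(DCI codes) and `x_e1` (energy components), with raw constituents
retained so models can use either.

## Classification protocol

`nested_cv_train()` runs stratified outer folds (default 10) for
generalization estimation and an inner grid search (default 3 folds)
selecting by mean inner accuracy over the grid of ensemble sizes
$\{10, 100, 500\}$ times maximum features $\{2, 4, 6, 10, 12\}$ at tree
depth 3 — 15 candidates, enumerated estimators-major with ties broken by
enumeration order so runs are exactly reproducible.  Features are
z-scored inside every split with training-part statistics.  Gradient
boosting (xgboost) and random forest (ranger) are first-class and share
the grid above; k-nearest-neighbours and an RBF SVM are available with
small conventional grids (neighbours; cost), and a single-hidden-layer
softmax network (nnet) stands as an optional neural baseline — a deep
multi-layer variant would need a DL framework and is deliberately out of
scope.  Class imbalance is handled
by stratification only — no resampling or class weights.  A class absent
from some stratified fold raises a protocol error suggesting fewer
folds.

Evaluation reports the 4 x 4 confusion matrix, per-class one-vs-rest
precision, recall and F1, and — because "accuracy" and "balanced
accuracy" are easily conflated in imbalanced four-class settings — both
are emitted under unambiguous names (`accuracy` = trace over total,
`balanced_accuracy` = macro recall).  Zero-denominator
metrics are reported as 0 with a flag.  Multiclass averaging is macro,
with per-class values always present.  `y_scramble()` permutes labels
with iteration-indexed seeds and reruns the full protocol, and
`ablation()` reruns it restricted to feature-group unions.  Train/test
overlap on patient identifiers is a hard error.  Train/test split sizes
are parameterized rather than fixed, since no single split is canonical
for cohorts of this size.

## What the synthetic generators emulate

Real cohorts for this task are private, so the package ships generators
in their place; the generators define the conditions under which all
tests run.

`make_toy_complex()` builds a cubic-lattice receptor block (spacing 2.2
angstroms, equal weights 2.0) with a square pocket in its top face and a
ligand filling the pocket sites bottom-up.  The weight exceeds the
worst-case lattice-cell circumradius ($2.2\sqrt{3}/2 \approx 1.9$), so
at $\alpha = 0$ every occupied cell is fully tetrahedralized and an atom
is interior exactly when its six face-neighbour sites are occupied —
surface, interface and burial labels are therefore decidable
combinatorially, with no geometry run.  Convexity markers are limited to
atoms whose solid angle is forced: interior face atoms ($\Omega = 2\pi$,
convex) and pocket-floor footprint corners ($\Omega = 2.892\pi$,
concave).  The test suite validates this ground truth against an
exhaustive brute-force enumeration before using it (two-stage trust).
`jitter_trajectory()` emulates 10-ps-sampled snapshots as seeded Gaussian
coordinate noise around a rigid frame, with optional drift; it does not
attempt realistic conformational dynamics.

`make_cohort()` draws features uniformly within the emulated cohort
ranges (energies in kcal/mol, e.g. VDW in [-60, -45]; geometric
descriptors e.g. positioning distance in [30, 39]) with the class
imbalance 19/118/30/34, then shifts the geometric columns per class:
adjacent class means are separated by three within-class standard
deviations at `effect_size = "well-separated"`, one at `"weak"`, zero at
`"none"` (labels independent of features).  The signal is placed on the
geometric block deliberately — those are the descriptors designed to
carry structural information — and shifts act on raw features so the
no-leakage property of the normalizer is exercised.
Discrete features are rounded; shifted values may exceed the nominal
range and are never clipped.  Passing tests on these cohorts shows the
protocol machinery is correct — fold hygiene, seeding, metric identities,
collapse under label scrambling — not that any particular accuracy is
attainable on real patients, whose feature correlations, label noise and
mutation structure the generator does not model.

## Problem sizes and limitations

The test suite and the acceptance script run, by choice, at desk scale:
oracle-equivalence on 220 random fixtures of 8--30 atoms (the exhaustive
enumeration is $O(n^4)$ in atom count), 50 triangulated balls of about
25 vertices for solid-angle closure, and the full classification
protocol — 10 x 3 nested CV over the 15-point grid plus 50 scrambling
iterations — on the 201-row synthetic cohort with the random-forest
family, whose fits are fastest among the tree ensembles at these sizes.
The alpha-complex construction enumerates candidate tetrahedra with
locality pruning; it is comfortable to a few thousand atoms but is not a
CGAL replacement for whole-protein surfaces with waters.  Hydrogen-bond
detection is geometric only (no water-mediated bridges), there is no
trajectory alignment or RMSD quality control, and mmCIF/binary
trajectory formats are out of scope.
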