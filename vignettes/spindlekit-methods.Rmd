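---
title: "spindlekit: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spindlekit: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spindlekit implements two quantification pipelines that often occur
together in centrosome biology: calling interactors from tandem-affinity
purification mass spectrometry (AP-MS) pulldowns of a tagged bait, and
measuring the 3D geometric relationship between centrosomes and mitotic
spindle poles in multichannel confocal stacks. This vignette explains the
underlying procedures, the tunable parameters, and the choices made where
the design was genuinely open.

## 1. AP-MS hit calling

### The evidence model

The unit of evidence is the **unique peptide count** $u_{p,r}$ of protein
$p$ in pulldown run $r$, together with a Mascot identification score
$s_{p,r}$. An experiment set consists of $R$ bait replicates (default
$R = 3$) and a collection of control pulldowns: an untagged wild-type
line (which shares sticky, bead- and tag-unrelated background) and other
TAP-tagged bait lines (which additionally share tag-specific binders).
Spectral search and FDR control happen upstream and are out of scope;
spindlekit starts from per-run protein evidence tables.

Duplicated accessions within a run are collapsed to a non-redundant list
by taking the per-field **maximum** over duplicates. Summing was rejected
because duplicate rows usually represent the same underlying peptide
evidence reported under several protein groups, and summing would count
shared peptides twice; the maximum is the most generous single-row
reading. The collapse sorts by accession, making it idempotent and
independent of input row order.

### The filtering cascade

Writing $n_p = \#\{r : u_{p,r} \ge 1\}$ (presence count) and
$m_p = \#\{r : u_{p,r} \ge \theta_\text{pep}\}$ (strong-replicate count),
the tier of a protein detected in at least one bait replicate is a pure
function of $(u_p, \text{control hit}, \theta)$:

1. **excluded_control** — the protein was seen with at least
   $\theta_\text{ctrl}$ unique peptides (default 1: a single peptide
   suffices) in *any single replicate of any control line*. Exclusion is
   unconditional on bait evidence: a protein with dozens of bait peptides
   is still removed if one control peptide exists. Control counts are
   never summed across runs.
2. **below_threshold** — $n_p < \theta_\text{pres}$ (default 2) or
   $m_p < \theta_\text{rep}$ (default 2 replicates at
   $\theta_\text{pep} = 4$ peptides).
3. **filtered2** — $n_p \ge \theta_\text{pres}$ and
   $m_p \ge \theta_\text{rep}$.
4. **filtered3** — additionally $n_p \ge \theta_\text{all}$ (default
   $R = 3$: present in every replicate).

All comparisons are inclusive ("at least", "four or more"). The tiers are
nested (filtered3 $\subseteq$ filtered2 $\subseteq$ candidates), monotone
in every threshold, and invariant to row and file order; the test suite
asserts all three properties, plus exact agreement with an independently
coded transcription of the filtering rules over the exhaustive space
$u_p \in \{0..5\}^3 \times \{\text{control}, \text{no control}\}$.

The final localization shortlist is driven by a user-supplied annotation
table plus an excluded-category list (for example nucleus, spliceosome,
membrane) rather than a live gene-ontology query: live queries tie the
result to a database snapshot and are not reproducible. Proteins whose
annotation lists only excluded categories are removed; proteins carrying
any other category, and unannotated proteins (kept as `"unknown"`), are
retained — detected proteins are never silently dropped.

### Network construction

The network is bait-centric: one node per retained prey plus the bait,
one bait–prey edge per prey weighted by the prey's best Mascot score
across replicates ($S_p = \max_r s_{p,r}$, the attribute a viewer would
map to line darkness). By default only filtered3 preys become nodes;
`include_filtered2 = TRUE` adds two-replicate preys with dashed edges, the
convention used for borderline interactors. Previously reported prey–prey
interactions are added as unweighted `prior_known` edges only when both
partners are present. The graph is simple (no self-loops or duplicate
edges); GraphML is the canonical, attribute-preserving interchange format,
with a flat edge TSV as the alternative.

## 2. 3D mitotic geometry

### Image model and segmentation

Images are multichannel z-stacks with anisotropic voxels, default
$0.1 \times 0.1 \times 0.3\ \mu m$ (0.3 µm z-steps). Segmentation is
plain intensity thresholding: objects are 26-connected components of
$\{v : I(v) \ge \tau\}$ with at least `min_voxels` voxels (default 5).
The same thresholds are applied to every cell of an experiment regardless
of genotype. Centroids are intensity-unweighted means of voxel centres
(voxel $(i,j,k)$ sits at $((i-\tfrac12)dx, (j-\tfrac12)dy,
(k-\tfrac12)dz)$), converted to µm; volume is voxel count times voxel
volume. 26-connectivity and unweighted centroids were chosen because the
upstream commercial tools this replaces do not document their choices;
both are the most common defaults in 3D component analysis.

### Spindle axis, back edges, angle, distance

* **Axis**: the line connecting the two spindle-pole centroids
  (alpha-tubulin channel at the high threshold `tau_pole`). A cell is
  *accepted* for angle measurements only when the pole z-separation is at
  most `dz_max` = 1.8 µm (six z-steps); the comparison is inclusive, the
  ordinary reading of "within". Rejected cells are reported as excluded.
* **Back edges**: the whole-spindle object (alpha-tubulin at the lower
  threshold `tau_spindle`) is projected onto the axis; the two extreme
  voxel centres are the pole back edges ("longest axis points").
* **Angle** $\alpha$: computed in the xy maximum-projection plane
  (z discarded), because the measurement it reproduces was defined on
  maximum projections. The vertex is the *nearer pole centroid*, and
  $\alpha$ is the angle between the outward axis direction (away from the
  other pole) and the pole-to-centrosome vector, binned at 15° and 30°.
  Whether the original manual measurement used the pole or the spindle
  midpoint as vertex is not documented; the pole centroid is the
  reproducible choice consistent with per-pole reporting, and it is a
  single documented convention rather than a config maze. A centrosome
  coincident with the vertex gets $\alpha = 0$, flagged.
* **Distance** $d$: the 3D Euclidean distance from the centrosome
  centroid (gamma-tubulin channel) to the *nearer* back edge; the
  centrosome is assigned to that pole. Reported centrosome columns are
  ordered by assigned pole (poles ordered by centroid position), so the
  pairing is stable and does not depend on segmentation label order.

Both quantities are invariant under rigid transforms of coordinate-level
input (distances under all 3D isometries, angles under isometries of the
projection plane), asserted to $10^{-9}$ µm/degrees in the tests.

### Intensity and phenotype

Centrosomal marker intensity ("mean fluorescence in marker-positive
volumes") is the mean of the measurement channel over each gamma-tubulin
object's voxels; the per-cell summary averages the two largest objects
(ties break toward the lower label; more than two objects is treated as
debris with a warning, a single object is flagged).

Phenotype classification, in precedence order:
**multipolar** (> 2 pole objects) → **disorganized** (< 2 poles, or axis
rejected/degenerate: unfocussed, monopolar or collapsed spindles) →
**detached** (any centrosome with $d > d_\text{det}$; one or both may be
detached) → **normal**. The detachment threshold $d_\text{det}$ defaults
to 1.0 µm. This is an explicit analysis choice, not a literature value:
"detached" is a qualitative category, and 1.0 µm sits well above the
back-edge offset of an attached centrosome (~0.6 µm here) while staying
below typical displaced positions. It should be recalibrated for other
cell types or optics.

## 3. Exact small-sample tests

Group comparisons use two bespoke exact tests, each validated against an
independent enumeration oracle (and, where applicable, base R):

* **Fisher's exact test** (2×2, two-sided) enumerates the hypergeometric
  distribution over the observed margins and sums the probabilities of
  all tables no more probable than the observed one (the probability-mass
  definition, the convention in standard software; doubling the one-sided
  tail is the documented alternative and is *not* used). A relative
  tolerance of $10^{-7}$ guards the $\le$ comparison against floating
  point. Zero-margin tables return $p = 1$, flagged. No approximation is
  used at any size.
* **Wilcoxon rank-sum** (two-sided). With no ties and the smaller group
  at most 8, the exact null distribution is enumerated
  ($p = P(|W - \mu| \ge |w - \mu|)$, valid because the tie-free null is
  symmetric). Otherwise a normal approximation is used with tie-corrected
  variance, continuity correction, and an Edgeworth fourth-cumulant term
  using the exact tie-free excess kurtosis
  $\gamma_2 = -\tfrac{6}{5}\,(n_x^2 + n_y^2 + n_x n_y + N)\,/\,
  (n_x n_y (N+1))$; the kurtosis term assumes no ties and is applied as
  an approximation when ties are present. The correction keeps the
  approximation within about $10^{-3}$ of full enumeration already at 8
  observations per group (the tests assert 0.01).

Counts are compared with Fisher, continuous measures with Wilcoxon. One
published figure legend applies "Fisher's test" to continuous intensity
dot plots; that is treated as an inconsistency, and `phenotype_stats()`
deliberately routes continuous measures to Wilcoxon. P-values are
reported per comparison without multiplicity adjustment, matching the
reporting convention of the workflows this package reproduces.

The null-rejection-rate check for the Wilcoxon test uses 10,000 draws of
two equal groups of $n = 50$: at that size the attainable size of the
(discrete) test is close to the nominal 0.05, so the $[0.04, 0.06]$ band
is meaningful; at very small $n$ discreteness alone forces the size far
below nominal, which would test the sample size rather than the code.
The Fisher null check is one-sided ($\le 0.06$) because the test is
conservative by construction.

## 4. The synthetic-data generators

### AP-MS sets

`simulate_apms()` emulates the *structure* of a TAP screen: three planted
classes (true interactors in bait runs only; background in bait and every
control line; tag-specific binders in every TAP-tagged run but not
untagged WT), Poisson unique-peptide counts
($\lambda_\text{true} = 6$, $\lambda_\text{bg} = 3$), per-replicate
Bernoulli dropout $q$ for true interactors, and Mascot scores from
$s = 30u + N(0, 10)$ floored at zero — the simplest generative model
matching per-replicate count data. In the runs that define a class's
presence, counts are zero-truncated so class membership guarantees
detection there, making the exclusion invariants exact by construction.
`fixed_count_mode` replaces Poisson draws with their means so threshold
behaviour is deterministic: at count 6 and dropout $q$, a true interactor
reaches the top tier exactly when no replicate drops out, giving the
closed form $(1-q)^R$ implemented in `filtered3_recovery_prob()`
(at $q = 0.2$, $R = 3$: 0.512). What the generator does *not* model:
protein-level score correlations, shared-peptide ambiguity, abundance
dependence of dropout, or FDR at the identification layer — passing
recovery tests therefore validates the filtering arithmetic, not
identification quality on real data.

### Voxelized cells

`simulate_cells()` renders each cell into three channels: alpha-tubulin
(a Gaussian-profile spindle body of radial σ 0.35 µm and amplitude 80
connecting two pole blobs of σ 0.3 µm and amplitude 255), gamma-tubulin
(two centrosome blobs, σ 0.3 µm, amplitude 200), and a measurement
channel co-located with the centrosomes whose amplitude is scaled by the
genotype factor $\rho$. Background (default 2) and Gaussian read noise
(default σ 10, i.e. signal-to-noise 20 at the default amplitudes) are
added last; Poisson shot noise is optional. Gaussian blobs, not a point
spread function: the generator exists to exercise segmentation and
geometry with exact ground truth, and optical realism is a non-goal.

Geometry: poles sit `spindle_length` = 8 µm apart; the axis has a random
in-plane azimuth (±15°) and a pole z-separation uniform on [0, 1.2] µm,
inside the 1.8 µm acceptance window. The **back edge is defined
geometrically** at $r_\text{be}$ = 0.6 µm beyond each pole centroid, and
`sim_geometry_params()` derives the alpha-tubulin threshold whose
rendered iso-surface crosses the axis exactly there — so the truth table
(pre-noise coordinates) is exact and independent of voxelization.
Detached centrosomes are displaced by a truncated lognormal offset
(median 2 µm, log-sd 0.25, cap 3.2 µm) at an angle uniform on [0°, 90°]
from the outward axis, in the xy plane; attached centrosomes get
isotropic 0.05 µm jitter. The truth *category* applies the phenotype rule
to the exact coordinates, so a planted displacement that happens to land
below $d_\text{det}$ is truthfully "normal" and estimator checks compare
like with like. An explicit `planted` table (angle, offset) overrides the
random model for recovery experiments; in the validation runs planted
angles keep 2.5° clear of the 15°/30° bin boundaries so the bin check is
unambiguous under the ±2° recovery tolerance. The default grid
(176 × 112 × 24 voxels = 17.6 × 11.2 × 7.2 µm) contains the spindle plus
the maximal planted displacement with a 4σ rendering margin; generation
fails loudly, naming the cell, if a planted object falls outside.

A single seed fully determines each simulation (geometry is drawn first,
then per-cell rendering noise in cell order), so rendering everything and
streaming cell-by-cell (`simulate_quantify_cells()`, which avoids holding
~9 MB per cell in memory) consume the random stream identically and are
bit-reproducible.

### Problem sizes used in validation

The shipped validation runs use sizes chosen to give tight checks at
interactive runtimes: the exhaustive filter space (432 cases), 1,000
random evidence sets for the monotonicity properties, all 2×2 tables
with margins ≤ 30 (~164k tables) for Fisher, 500 samples plus 10,000
null draws for Wilcoxon, 200 seeded simulations for dropout recovery,
100 noiseless cells for angle/distance recovery, and 200 cells per
genotype for the end-to-end experiment (detachment fractions 0.05 vs
0.30, $\rho = 0.5$).

## 5. Numerical conventions and degenerate inputs

* Distances in µm after anisotropic scaling; angles in degrees in
  $[0, 180]$; volumes in µm³.
* Ties: object-size ties break toward the lower segmentation label;
  equal-distance pole assignment takes pole 1; threshold comparisons are
  all inclusive.
* Degenerate inputs are defined, not fatal, wherever a downstream
  pipeline must continue: empty evidence tables, cells with no marker
  objects, zero-margin contingency tables ($p = 1$, flagged), identical
  samples ($p = 1$, flagged), centrosome-on-vertex angles (0°, flagged).
  Coincident pole centroids *are* an error (no axis exists).
* TIFF storage is 32-bit float, scaled to a 12-bit dynamic range
  ([0, 4095]); intensities are arbitrary units throughout.

## 6. Known limitations

* The angle is a projection-plane quantity; strongly tilted spindles
  (within the 1.8 µm window but not flat) foreshorten angles slightly,
  exactly as in the projection-based workflow it reproduces.
* The localization shortlist is only as good as the supplied annotation
  table; no identifier mapping across databases is attempted
  (accessions are opaque strings).
* No probabilistic interaction scoring (CompPASS/SAINT-style) is fitted —
  the reproduced procedure is deterministic thresholding; the tier table
  deliberately carries the evidence needed if such scoring is added
  downstream.
* The cell generator does not model multipolar or collapsed spindles;
  those phenotype branches are validated on constructed inputs, not on
  rendered cells.
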