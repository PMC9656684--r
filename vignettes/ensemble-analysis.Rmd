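---
title: "Reference-free analysis of disordered peptide ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free analysis of disordered peptide ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrfel)
```

## The problem

Intrinsically disordered regions (IDRs) such as the ~80-residue kinase-insert
domain (KID) of the receptor tyrosine kinase KIT do not fold into a single
native structure: a molecular-dynamics simulation of such a peptide produces
a broad conformational ensemble in which transient helices continuously
form and dissolve.  Conventional structure comparison (RMSD against a
reference) is then close to meaningless, because no conformation deserves to
be the reference.  `idrfel` implements a reference-free alternative: each
frame of an ensemble is summarised by *intrinsic* geometric descriptors —
quantities computed from the frame alone, invariant under rigid motion —
and the resulting feature space is clustered and converted into a Gibbs
free-energy landscape.

The pipeline is, in order:

1. **Trajectory handling** (`read_multimodel_pdb`, `concatenate`,
   `subsample`, `superpose`): multi-model PDB ensembles with one entity
   label per input (e.g. a cleaved, a domain-fused and a glycine-cyclised
   construct of the same peptide) are merged into one concatenated dataset
   while each frame keeps its entity label.
2. **Descriptors** (`radius_of_gyration`, `sasa`, `backbone_dihedrals`,
   `pseudo_torsion`, `triangle_area`, `tetrahedron_volume`,
   `pairwise_ca_distances`, `assign_helices`, `ramachandran_region`) and
   **contacts** (`find_hbonds`, `find_vdw_contacts`, `contact_occurrence`).
3. **Featurisation** (`extract_features`): a fixed catalog of 31 intrinsic
   descriptors per frame — radius of gyration, hydrophobic-contact and
   hydrogen-bond counts, the solvent-accessible surface areas and backbone
   dihedrals of the four tyrosine sites, the six tyrosine–tyrosine Cα
   distances and their tetrahedron volume, the distances, pseudo-torsions
   and triangle area of the maximally fluctuating residues, and the
   distance and pseudo-torsion of the minimally fluctuating pair.
4. **Pre-processing** (`minmax_scale`, `prune_correlated`, `pca_reduce`):
   min–max scaling to [0, 1] per entity and per feature, removal of one
   member of every feature pair with |Pearson r| ≥ 0.8, PCA retention of
   the smallest number of leading components reaching 80% cumulative
   variance.
5. **Clustering** (`sweep_dbscan`, `sweep_kmeans`, `sweep_ward`,
   `score_partition`, `select_best`, `contingency_agreement`,
   `cluster_composition`, `representative_conformation`).
6. **Free-energy landscape** (`knn_density`, `free_energy_landscape`,
   `fel_wells`, `td_coordinates`): ΔG(R₁, R₂) = −k_B·T·ln(P/P_max) over two
   reaction coordinates with P estimated by a k-nearest-neighbour scheme.

`run_pipeline()` chains all stages and writes CSV/JSON artifacts.

## The synthetic ensemble generator

The original MD trajectories for KID are not publicly deposited, so the
package carries a generator of labelled surrogate ensembles
(`default_three_basin_spec`, `sample_ensemble`, `build_chain`) that every
pipeline stage is tested against.  A frame is drawn by choosing a
conformational *basin* (a mixture component in backbone dihedral space),
perturbing its per-residue mean (φ, ψ) with independent wrapped-Gaussian
noise of the basin's σ, and rebuilding all-backbone coordinates by
internal-coordinate (NeRF) chain extension with standard bond geometry
(N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å, ω = 180°).  Residues carry N, H,
Cα, C, O plus a two-carbon side-chain proxy (Cβ, Cγ) for non-glycine
residues and a hydroxyl-like terminal oxygen for tyrosine — the minimal
chemistry needed by the SASA, hydrogen-bond and hydrophobic-contact
descriptors.  Frames with a non-bonded heavy-atom pair closer than 1.5 Å
are resampled.

The default specification is an 84-residue KID proxy (the F689–D768 span
plus a C-terminal Gly-Gly-Gly-Gly spacer, tyrosines at 703/721/730/747)
with three basins:

| basin    | (φ, ψ) means | σ  | weight |
|----------|--------------|----|--------|
| helix    | (−64, −41)   | 8° | 0.50   |
| extended | (−120, 130)  | 10°| 0.30   |
| pp_like  | (−75, 150)   | 10°| 0.20   |

These emulate a transiently helical sub-ensemble against two
extended/polyproline-like sub-ensembles of realistic angular spread.  What
the generator does **not** emulate: correlated backbone fluctuations
(noise is independent per residue, so long-range geometry diffuses more
than in a physical chain), side-chain rotamer chemistry, solvent, and the
actual cyclisation of the spacer (it is sequence content only).  Passing
tests on these surrogates therefore demonstrate the correctness of the
*computations*, not the biology of any real KID ensemble.

## Numerical and design choices

* **Superposition** is Kabsch SVD with a determinant-sign correction;
  collinear selections are refused.
* **SASA** is Shrake–Rupley with a deterministic golden-section spiral of
  960 points per atom and Bondi radii (probe 1.4 Å); quadrature error is
  about 1% of the closed-form single-sphere area, and hydrogens are
  excluded as both surfaces and occluders.
* **Helix assignment** uses the Kabsch–Sander electrostatic hydrogen-bond
  energy (bond at E < −0.5 kcal/mol) with runs of i→i+4 turns labelled H
  and i→i+3 turns labelled G; sheets/bridges are not assigned — the
  Ramachandran classifier covers extended states instead.  Missing amide
  hydrogens are rebuilt on the N–H bisector geometry (1.01 Å); proline
  never donates.
* **Contact boundaries are inclusive**: D–A ≤ 3.6 Å, D–H···A angle ≥ 120°,
  side-chain C–C ≤ 3.6 Å, occurrence ≥ 40%.  Van der Waals contacts
  require a sequence separation of at least 2 residues and intra-residue
  hydrogen bonds are excluded; both choices are configurable in
  `contact_criteria()`.
* **Angular features** enter scaling as raw degrees in (−180, 180] with no
  circular embedding; a basin straddling ±180° would be split by the
  scaler.  This mirrors the straightforward treatment the feature catalog
  is defined with and is a known limitation.
* **Pruning tie-break**: of each correlated pair the higher catalog index
  is dropped, scanning pairs in catalog order — so the distance between
  maximally fluctuating residues survives and their triangle area is
  removed when the two correlate.
* **K-means** folds its 1000-iteration budget into 10 restarts × 100
  Lloyd iterations under a fixed, recorded seed; DBSCAN's minimum sample
  size is ⌈0.05·n⌉ and its ε grid is 0.10–1.00 in steps of 0.05; the Ward
  tree is built once and cut at k = 2…15.
* **Cross-clustering agreement** is the mass of the maximum-weight
  one-to-one matching between the two cluster sets on their contingency
  table (computed exactly by dynamic programming over column subsets),
  divided by the number of co-clustered frames.
* **The k-NN density** uses k = ⌈√n⌉ by default (bias/variance
  compromise; always recorded in the output).  ΔG is anchored so the most
  probable *occupied* bin is exactly 0; the surface is evaluated at every
  bin centre of a 100×100 grid over the 5%-padded bounding box, with
  unoccupied bins flagged rather than zeroed.  T = 310 K and
  k_B = 1.98720425×10⁻³ kcal/mol/K give k_B·T = 0.61603 kcal/mol.
* **Well detection** uses sublevel-set persistence: basins are flooded in
  order of increasing ΔG and a well's depth is the saddle at which it
  merges into a deeper basin (its topographic prominence).  A literal
  "lowest neighbouring saddle" rule collapses a deep regional well to the
  depth of its nearest noise-induced sibling minimum whenever the
  estimated surface is rough, so persistence is the robust formulation; on
  a noise-free surface the two coincide.  The surviving global minimum is
  scored by the saddle of the deepest basin that merged into it, falling
  back to the total relief, so a featureless surface reports no wells.

## What the desk-scale study shows — and honestly does not

On the default three-basin ensemble (600 frames), the pipeline behaves as
follows; every number here is recomputed by the test suite.

* The 31-feature table is extracted, scaled, pruned (about 20 of the 31
  features are removed at |r| ≥ 0.8 — with three basins almost every
  global descriptor is a monotone function of basin identity, so the
  catalog is heavily redundant on this data) and reduced to 3 principal
  components at the 80% target, PC1 alone carrying ~64% of the variance
  and separating all three basins by ≥ 4 within-basin standard deviations.
* **K-means at k = 3 reaches an adjusted Rand index of ~0.86 against the
  ground truth, short of the 0.9 the package aims for.**  The cause is
  instructive: the third retained component is almost pure within-basin
  noise from the long-range pseudo-torsion features (independent
  per-residue dihedral noise makes a 25-residue-span torsion nearly
  uniform), and on data with such unequal within-cluster variances the
  variance-minimising K-means objective genuinely prefers splitting the
  noisier extended basin over respecting the PC1 gaps — the
  misclustered solution has *lower* within-cluster sum of squares than
  the true partition.  K-means on the first two components, or Ward at
  k = 3, recovers the basins at ARI ≈ 0.97.  The retention rule (smallest
  k reaching 80%) is kept as specified; the shortfall is reported, not
  patched.
* **The PC1/PC2 free-energy landscape shows 3 wells at a depth cutoff of
  ~0.5 kcal/mol but only 2 at 1 kcal/mol**: with k_BT = 0.616 kcal/mol,
  the pp-like basin (20% weight) peaks only ~1.5 k_BT above the saddle
  connecting it to the extended basin, so its prominence sits at
  ~0.5–0.6 kcal/mol.  This is a property of the stated basin weights and
  spreads, not of the estimator.
* A kNN density estimate on bounded support is biased low near the
  support boundary (a corner bin sees roughly a quarter-plane of data,
  inflating ΔG there by about k_BT·ln 4 ≈ 0.85 kcal/mol); landscapes of
  structureless data therefore show spurious relief slightly above
  1 kcal/mol at their corners.  Well depths, which are measured at
  interior saddles, are essentially unaffected.

Problem sizes used throughout the tests (50–1000 frames, 25–100×100 FEL
grids, 10⁵-point Monte-Carlo SASA references) were chosen so the whole
suite exercises every stage end to end at interactive speed.
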