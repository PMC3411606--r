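---
title: "Methods: helicity, conformational states and membrane immersion of an interfacial helix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helicity, conformational states and membrane immersion of an interfacial helix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helix8)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, and the design decisions taken where several
defensible choices existed. The running system is helix 8 (H8) of a class C
GPCR: an amphipathic helix lying parallel to the membrane plane at the
cytoplasmic interface, whose folded state depends on the surrounding
bilayer. All coordinates are in Å and the z axis is the bilayer normal by
convention; the package never auto-detects units.

## Helicity as a backbone hydrogen-bond fraction

An α-helix of $n$ residues is stabilized by $n-4$ canonical
$i \rightarrow i{+}4$ backbone hydrogen bonds (carbonyl O of residue $i$ to
amide N of residue $i+4$). The helicity of a conformation is the percentage
of those *reference* bonds that are intact:

$$\%\,\text{folded} \;=\; 100 \times \frac{\#\{\,i : d(\mathrm{O}_i, \mathrm{N}_{i+4}) \le d_{\max}\,\}}{n-4}.$$

Decisions behind this metric:

* **Criterion.** The default is hydrogen-free: heavy-atom O···N distance
  $d_{\max} = 3.5$ Å, the conventional heavy-atom hydrogen-bond cutoff.
  Synthetic topologies carry no hydrogens, and a distance criterion is
  sufficient to classify the well-separated intact (2.9 Å) and broken
  (≥ 5 Å) states the generator produces. When amide hydrogens are present,
  `hbond_criterion(require_hydrogen = TRUE)` additionally demands an
  N–H···O angle ≥ 120°.
* **Frozen reference set.** The bond list is fixed from the starting
  structure (`helix_definition()`), so the metric is a fraction of a known
  denominator rather than a count of whatever bonds exist per frame. For
  the default 11-residue segment (residues 817–827, `ILFQPQKNVVS`) the
  denominator is 7 and the metric lives on the lattice $k/7$:
  100, 85.71, 71.43, 57.14, 42.86, 28.57, 14.29, 0.
* **Rounding.** Percentages are reported half-up to 2 decimals, matching
  the precision at which such fractions are conventionally quoted.

Two published assignments of the hydrophobic (membrane-buried) face of this
helix circulate: residues {821, 822, 824, 825, 826, 828, 829} and
{821, 823, 824, 825, 826, 829, 830}. The first is the default; both are
selectable via `helix_definition(hydrophobic_face = "main" | "alt")`.

## Feature space: RMSD and radius of gyration

Per frame the package records two scalars (`compute_features()`):

* **RMSD from the starting structure** after optimal rigid superposition of
  the helix backbone (N, CA, C, O of the helix residues) on the same atoms
  of the reference frame. Superposition is the Kabsch algorithm: SVD of the
  cross-covariance matrix with the determinant correction, so the rotation
  is always proper (no reflections). The superposition target is the
  helix's own backbone — the metric measures internal deformation, not
  displacement relative to the rest of a protein; an external reference
  frame can be supplied where anchoring to a larger structure is wanted.
  Degenerate subsets (< 3 atoms, collinear) are rejected.
* **Radius of gyration** $G_r = \sqrt{\sum_i w_i |r_i - \bar r|^2 / \sum_i w_i}$
  over the helix heavy atoms, mass-weighted by default (a plain-geometric
  option exists; for a backbone-only topology the two differ little).

Both observables are invariant under global rigid motion, which the test
suite checks by property (random rotations/translations) and against
independent oracles (Horn's quaternion method for RMSD, a direct sum for
$G_r$).

## Conformational states from a 2D kernel density

The per-frame (RMSD, $G_r$) pairs are summarized by a Gaussian-product
kernel density estimate on a regular grid (`kde2d_features()`; the grid
computation is delegated to `MASS::kde2d` with the bandwidth
re-parameterized so that the reported bandwidth is the kernel standard
deviation). Defaults and rationale:

* **Bandwidth:** Scott's rule per dimension, $h_j = \hat\sigma_j n^{-1/6}$.
  The original analyses of this kind used external tools with unstated
  bandwidths, so a standard data-driven rule is the only reproducible
  choice; it is configurable (`"silverman"` uses the robust
  $\min(\hat\sigma, \mathrm{IQR}/1.349)$; in two dimensions the Scott and
  Silverman prefactors coincide) and fixed numeric bandwidths are accepted.
  Zero variance in a dimension is an error that suggests a fixed bandwidth.
* **Grid:** 128 × 128, spanning the data range plus 3 bandwidths per side.
  At that resolution the sub-cell bias of a mode location is below the grid
  spacing, and margins keep essentially all kernel mass inside the grid
  (the density integrates to the in-grid kernel mass; a Simpson-rule test
  verifies this to 10⁻⁶).
* **Modes = states** (`find_modes()`): strict local maxima over the
  8-neighborhood, kept if their density is ≥ 5% of the global maximum
  (`min_rel_density`). The threshold is deliberately low because genuinely
  shallow states must survive; it filters only outright ripples.
* **Prominence merging** (`min_saddle_drop = 0.05`): a local maximum that
  is not separated from a denser mode's basin by a density dip of at least
  5% of its own height is merged into that mode. This guards against
  undersmoothing artifacts: a kernel estimate of a perfectly unimodal cloud
  at Scott bandwidth shows twin summits with a near-flat ridge between them
  in a few percent of random samples, and a state boundary should require a
  real valley. Saddles are measured between steepest-ascent basins on the
  grid. With the merging in place, mode counting recovers 1, 2 and 6
  components on well-separated seeded mixtures in ≥ 95 of 100 seeds (the
  test suite runs exactly that experiment).
* **Assignment** (`assign_frames()`): each frame maps to its nearest grid
  cell and climbs by steepest ascent to a summit; ties among equally dense
  uphill neighbors break toward the lowest cell index, so assignment is
  fully deterministic. Frames outside the grid are clamped to the nearest
  cell and counted, never dropped. State probabilities are assigned-frame
  fractions and sum to 1 exactly.
* **Average structures** (`state_average_structure()`): member frames are
  superposed on the first member via the helix backbone and averaged
  coordinate-wise; the helicity of the average is reported. Averaging (not
  medoid selection) matches the usual presentation of cluster-average
  structures; `method = "medoid"` gives the member closest to the average
  instead. A degenerate case worth knowing: coordinate averaging of frames
  from *different* basins that were merged into one state can shrink bond
  distances; with the generator's well-separated schedules this does not
  occur.

## Electron density profiles, thickness, immersion offset

`electron_density_profile()` implements the slab method: per frame, each
selected atom contributes its electron count to the 1 Å-thick slab
containing its z coordinate; slab sums are divided by slab volume (box
cross-section × slab width); the profile is the per-slab mean over frames
with the across-frame sd. Electron-count conservation (slab sums × volume =
total electrons of the selection) holds exactly per frame and is tested.

* **Electron count:** $e = Z - q$ by default — a positive partial charge
  depletes the electron cloud, which is the physically standard convention
  for approximate electron density. Because the phrasing "summing the
  atomic number and the partial charges" in density tools is ambiguous, the
  literal $Z + q$ is available behind `electron_mode = "add"`; for
  symmetric species the peak positions, and hence every distance reported
  here, are insensitive to the choice.
* **Normalization volume:** the full box cross-section (local-area
  normalizations are out of scope). Supply `area` explicitly for
  trajectories without a box.
* **Peaks:** per half-profile (split at the grid midpoint), the maximum
  slab refined by 3-point parabolic interpolation. Printed peak-to-peak
  distances carry 0.01 Å precision — much finer than the slab — and the
  interpolation delivers it: halving the slab width moves interpolated
  peaks by < 0.1 Å on the bilayer presets, and on deterministic
  quadratic-spread systems (`deterministic_peak_system()`) recovery is
  exact because binned counts of a quadratic profile are an exact parabola
  in the slab center. Monotone or single-sided profiles are errors.
* **Thickness** (`peak_to_peak()`): distance between the leaflet peaks,
  e.g. D_PO4–PO4 for a phosphate selection; the sd is computed from
  per-frame peak positions.
* **Immersion offset** (`helix_offset()`): on one leaflet, the distance of
  the helix Cα peak from the bilayer center minus that of the phosphate
  peak. Negative = helix buried toward the bilayer center; positive =
  displaced toward solvent. This maps the qualitative "left/right of the
  phosphate peak" description of profile plots onto a leaflet-independent
  sign convention. Both profiles must share a slab grid (pass a common
  `z_range`); the helix profile must be unimodal on the chosen side and
  have most of its mass there, otherwise an error points at the other
  leaflet. The bilayer is assumed centered at the grid midpoint.
* **Phosphate selection:** which atoms constitute "the PO4 group" is a
  user choice (`select_atoms()` expression). The synthetic bilayers carry
  one phosphate-marker atom per lipid (`res_name=PO4`); for an all-atom
  membrane, `name=P,O11,O12,O13,O14`-style selections express the full
  group. Peak positions shift by well under the leaflet width between the
  two readings.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions for every quantitative check:

* **Helix conformers** (`build_ideal_helix()`, `perturb_unfold()`): backbone
  heavy atoms on an ideal helical lattice (rise 1.5 Å, twist 100°, Cα
  radius 2.3 Å, N/C/O at cylindrical offsets fitted once to standard
  covalent geometry, giving all O···N contacts at 2.90 Å). Unfolding
  translates the terminal residues axially by 2.5 Å per residue beyond a
  pivot, breaking exactly `n_break` reference bonds from either terminus —
  terminal fraying is how such helices are seen to destabilize.
  `generate_helix_trajectory()` adds per-frame Gaussian jitter (default
  0.05 Å, far below the ~1.5 Å gap between intact and broken O···N
  distances and the cutoff, so bond states never flip) and a random rigid
  motion to exercise superposition. Not emulated: side chains, hydrogens,
  gradual unwinding, force-field energetics.
* **Bilayers** (`generate_bilayer()`): independent point atoms per marker
  species, z ~ Normal(±leaflet mean, leaflet sd), x–y uniform. The presets
  place phosphate planes at ±21.9 Å (`chol_rich`) and ±20.68 Å
  (`chol_depleted`) and carbonyl planes at ±17.5 / ±15.0 Å — the reference
  geometry of a polyunsaturated-PC membrane with and without 25%
  cholesterol, so the recovered thicknesses are nominally 43.8 / 41.36 Å
  (phosphate) and 35.0 / 30.0 Å (carbonyl). Leaflet widths (2–2.5 Å) are
  plausible thermal spreads, not fitted values. Not emulated: packed lipid
  conformers, undulations, protein-induced deformation.
* **Feature mixtures** (`generate_feature_cloud()`): bivariate Gaussian
  mixtures over (RMSD, $G_r$). The 2-state and 6-state presets mirror the
  state structure of cholesterol-rich vs -depleted membranes (two states;
  three high + one medium + two low). Component *locations* are synthetic:
  plausible values for an 11-residue helix whose folded form has
  $G_r \approx 5$ Å, separated by ≥ 2.2 Å against component sds of
  0.25–0.3 Å. No published per-state coordinates exist to match, so
  passing mode-recovery tests demonstrates correct density estimation and
  mode detection on well-separated states — not that real landscapes are
  this well separated.

Consequently, green tests validate the *metrics and machinery* on systems
with known ground truth. They do not show that a real receptor's helix
behaves this way; on real trajectories the states are broader, bond
distances hover near the cutoff, and helicity values off the exact lattice
occur.

## Pipeline, determinism, problem sizes

`run_pipeline()` composes the stages from one `run_config()` and writes
every intermediate (TSV/JSON/multi-model PDB) plus `summary.json` with a
provenance block (seed, config hash, package version). All generators are
pure functions of (spec, seed) — reruns are bit-identical, and the pipeline
test asserts byte-identical summaries. A failed stage writes a `FAILED`
marker naming the stage and keeps completed outputs. In preset runs the
feature-space state analysis runs on the mixture preset (the stand-in for
pooled multi-run features) while per-state helicities come from the
synthetic helix trajectory; the depleted-preset schedule includes four
helicity levels (100/71.43/42.86/28.57%), of which the two most-extended
merge under the data-driven bandwidth — a real property of kernel density
estimates at that separation, visible in the run summary.

Default problem sizes were chosen so the whole suite runs comfortably on a
single CPU: bilayer checks use 5,000 atoms per species per leaflet × 20
frames; mixture presets draw 4,000 (2-state) and 6,000 (6-state) samples;
the mode-recovery experiment runs 100 seeds per class; oracle equivalence
uses 1,000 random superposition instances. At these sizes every reported
distance is determined to well within the tolerances quoted above.

## Known limitations

* No DSSP-style secondary-structure assignment or per-residue energetics;
  helicity is the hydrogen-bond fraction only.
* No free-energy conversion of state probabilities, no kinetics or
  transition-path analysis — states are density modes, nothing more.
* The PDB reader handles ATOM/HETATM/MODEL/CRYST1 records only (no
  insertion codes, altLocs or binary trajectory formats); topologies with
  partial charges travel in a sidecar CSV/TSV because the PDB format cannot
  carry them.
* Electron density profiles use point atoms per slab (no Gaussian smearing
  or X-ray form factors) and full-box volume normalization.
* The bilayer must be centered at the profile-grid midpoint for leaflet
  splitting and the offset sign convention to be meaningful.
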