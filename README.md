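# helix8

Conformational-state and membrane-immersion analysis for amphipathic
interfacial helices, built around GPCR helix 8 (H8) — the short amphipathic
helix that follows TM7 and lies at the cytoplasmic membrane interface. The
package quantifies how a membrane environment (for example its cholesterol
content, which thickens the bilayer) stabilizes or disrupts such a helix,
and ships a synthetic-data generator so every stage of the analysis can be
exercised and validated without molecular-dynamics trajectories.

## What it computes

**Helicity as a hydrogen-bond fraction.** A helical segment of *n* residues
has *n − 4* canonical i → i+4 backbone hydrogen bonds. Per frame, the
percent folded is

    % folded = 100 × |{ i : d(O_i, N_{i+4}) ≤ 3.5 Å }| / (n − 4)

using a hydrogen-free heavy-atom criterion on the reference bond set frozen
from the starting structure. For the default 11-residue segment (residues
817–827, `ILFQPQKNVVS`) the metric lives on the lattice k/7: 100, 85.71,
71.43, …, 0.

**Conformational states from a 2D density.** Per frame the package records
the RMSD from the starting structure after optimal (Kabsch) superposition of
the helix backbone, and the radius of gyration G_r of the helix heavy atoms.
A Gaussian-product kernel density estimate over (RMSD, G_r) is computed on a
grid (Scott's rule per dimension by default), its modes are the states, and
frames are assigned to states by steepest ascent on the density grid. Each
state gets a probability (frame fraction) and an average structure with its
helicity.

**Bilayer thickness and helix immersion from electron density profiles.**
Atoms contribute Z − q electrons (atomic number minus partial charge) to
1 Å-thick slabs along the membrane normal; slab sums are normalized by slab
volume. Bilayer thickness is the distance between the two leaflet peaks of
the phosphate profile (D_PO4–PO4), with peaks refined to sub-slab precision
by 3-point parabolic interpolation. The helix immersion offset is the signed
distance of the helix Cα density peak from the phosphate peak: negative =
buried toward the bilayer center, positive = displaced toward solvent.

**Synthetic generators.** Ideal α-helices with an exactly controlled number
of broken i → i+4 bonds, bilayer leaflets as Gaussian point clouds with
preset geometries (`chol_rich`: phosphate planes ±21.9 Å; `chol_depleted`:
±20.68 Å), deterministic peak systems for exact-recovery checks, and
feature-space Gaussian mixtures with 2-state and 6-state presets.

## Worked example

```r
library(helix8)

# helicity of an ideal 11-residue helix, then with 2 of 7 bonds broken
helix <- build_ideal_helix(helix_spec())
hd <- helix_definition(helix)
helicity_percent(helix, hd)
#> <helicity> 100.00% folded (7/7 reference H-bonds intact)
helicity_percent(perturb_unfold(helix, n_break = 2), hd)
#> <helicity> 71.43% folded (5/7 reference H-bonds intact)

# thickness of the cholesterol-rich synthetic bilayer
bil <- generate_bilayer(bilayer_preset("chol_rich"), n_frames = 20)
peak_to_peak(electron_density_profile(bil, "res_name=PO4"))
#> <thickness> 43.70 A (peaks -21.86 / 21.84 A, sd 0.19 A over 20 frames)

# six conformational states in the cholesterol-depleted feature mixture
cloud <- generate_feature_cloud(mixture_preset("chol_depleted"))
model <- identify_states(cloud)
tidy(model)
#> # A tibble: 6 × 6
#>   state  rmsd    rg density n_frames probability
#>   <int> <dbl> <dbl>   <dbl>    <int>       <dbl>
#> 1     1 0.787  4.92  0.188      1454      0.242
#> 2     2 2.99   5.32  0.166      1293      0.216
#> 3     3 5.20   5.78  0.140      1088      0.181
#> 4     4 3.40   7.60  0.126       986      0.164
#> 5     5 6.59   7.90  0.0803      638      0.106
#> 6     6 1.20   7.29  0.0686      541      0.0902
```

The helicity readings mean 7/7 and 5/7 of the reference backbone hydrogen
bonds are intact; the thickness is the phosphate peak-to-peak distance of
the preset membrane (nominal 43.8 Å); the state table lists density modes
sorted by height with their frame occupancies (three major, one medium, two
minor states).

`run_pipeline(run_config(preset = "chol_rich", output_dir = "out"))` runs
every stage end to end and writes TSV/JSON/PDB outputs plus a `summary.json`
with a provenance block; `autoplot()` methods exist for density profiles,
KDE grids and state models.

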