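# ligmap

Reusable, tested R implementations of the computational analyses behind
a protein–ligand binding study of the plasma lipocalin **alpha-1-acid
glycoprotein variant 2 (AGP2)** and the antitumour kinase inhibitor
**UCN-01** (7-hydroxystaurosporine).  AGP2 binds many drug-like
molecules in its β-barrel and can dominate a compound's
pharmacokinetics; UCN-01 is its tightest known ligand (K_d ≈ 3.5 nM).
The package is aimed at structural-biology and biomolecular-NMR
practitioners who need these analyses as scriptable, verifiable steps
rather than one-off manual procedures:

* **Reverse minimal chemical-shift mapping** — assign an unassigned
  free-state ¹H–¹⁵N HSQC peak list by greedy nearest-neighbour matching
  onto an assigned ligand-bound list, under per-dimension gates
  (0.1 / 0.68 ppm), a weighted combined-shift distance
  d = √(Δδ_H² + (w·Δδ_N)²) with w = range_H/range_N = 0.147, and a 5%
  relative-height floor; residues whose bound peak captures nothing are
  classed `bound-only` (candidate large-shift / exchange-broadened).
* **¹⁵N relaxation** — per-residue mono-exponential T₁/T₂ fits
  (I(t) = I₀·e^(−t/T), Levenberg–Marquardt) on the published delay
  grids, hetNOE ratios with propagated errors, and a mobility profile
  flagging fast-motion residues (T₁/T₂ *and* NOE below fractions of the
  trimmed-mean core) and contiguous low-T₂ patches.
* **Structure comparison** — PDB/mmCIF reading, residue-range backbone
  superposition by the Kabsch SVD algorithm with RMSD, and geometric
  detection of hydrogen bonds, salt bridges, cation-π (stacked vs
  T-shaped by ring-normal angle), CH-π, bridging waters and pocket
  contacts.
* **Sequence bookkeeping** — expression-construct cleavage to mature
  numbering (tag, "GP" scar at positions −1/0, stop-codon truncation),
  N-glycosylation sequon scans (N-X-[S/T], X ≠ P), residue position and
  Hamming-difference utilities.
* **Thermodynamics** — ΔΔG = RT·ln(K_d ratio), affinity fold changes,
  melting-temperature shifts.
* **Synthetic data** — seeded generators producing ground-truth-bearing
  inputs for every stage, so the whole pipeline runs and is validated
  offline.

## Worked example

```r
library(ligmap)

# construct bookkeeping: His6-tag cleavage, truncation, feature scans
rep <- sequence_report(agp2_truncated_construct())
rep$mature_length          # 183
rep$truncation$removed     # 11
rep$sequons$position       # 15 38 54 75 85
rep$cysteines              # 5 72 147 165

# reverse minimal-shift mapping on a synthetic titration
w <- compute_weight(4.504, 30.616)   # weight = 0.147
sim <- simulate_peaklists(simulation_spec(seed = 1), weight = w$weight)
mp <- reverse_assign(sim$free, sim$bound, w, gate_spec())
mp
#> csp_mapping (global greedy): 111 pairs, 59 bound-only, 7 free-only
score_mapping(mp, sim$truth)$recovery_percent   # 100

# thermodynamics of losing the C7 hydroxyl (staurosporine vs UCN-01)
delta_delta_g(88, 3.5, temperature_k = 298)     # 7.99 kJ/mol
fold_change(88, 3.5)                            # 25.1
delta_tm(61.9, 75.6)                            # 13.7
```

The mapping output reads: 111 free peaks matched one-to-one to bound
peaks within the gates, 59 assigned bound peaks found no free partner
(their residues are perturbed beyond the gates or their free peaks were
lost), and every matchable ground-truth pair was recovered.  The ΔΔG of
~8 kJ/mol is the binding-energy cost of removing UCN-01's C7 hydroxyl —
the group that hydrogen-bonds to Glu64 in the AGP2 pocket — and the
13.7 °C Tm shift quantifies the thermal stabilization of AGP2 by bound
UCN-01.

The numbered drivers under `analysis/` run the five stages end to end
(`01_sequence_report.R` … `05_thermodynamics.R`), printing what each
finds and writing tables under `results/`; `run_pipeline()` does the
same from a single [`pipeline_config()`] whose untouched defaults are
the published analysis parameters.

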