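---
title: "Methods: chemical-shift mapping, relaxation fitting and interaction geometry in ligmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-shift mapping, relaxation fitting and interaction geometry in ligmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligmap)
```

ligmap packages the computational analyses of a lipocalin–ligand binding
study — alpha-1-acid glycoprotein variant 2 (AGP2) bound to the kinase
inhibitor UCN-01 (7-hydroxystaurosporine) — as reusable, tested
functions.  This vignette explains each method, its assumptions, the
parameters that matter, and the design choices made where the published
description left the procedure open.

## Reverse minimal chemical-shift mapping

The free (apo) AGP2 HSQC spectrum is too poor to assign directly, so the
mapping runs in reverse: each peak of the *unassigned free* spectrum is
matched to a peak of the *assigned ligand-bound* spectrum, and a
residue's apparent perturbation is the distance to the free peak its
bound peak captured — a lower bound on the true shift, hence "minimal".

The combined shift between a bound peak $b$ and free peak $f$ is the
weighted Euclidean distance

$$ d(b, f) = \sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2 }, \qquad
   w = \frac{\mathrm{range}_H}{\mathrm{range}_N} $$

with the $^{15}$N axis scaled into $^1$H ppm by the ratio of the
assigned-shift ranges of the two dimensions.  For the bound AGP2
assignments the ranges are 4.504 ppm ($^1$H) and 30.616 ppm ($^{15}$N),
giving $w = 0.147$.  The published account cites the minimal-shift
method without printing the distance formula; the weighted Euclidean
form is the standard of that method and is what the stated units
("$^1$H ppm per $^{15}$N ppm") imply, so it is adopted here.

Candidate pairs must pass two **per-dimension gates** — $|\Delta\delta_H|
\le 0.1$ ppm and $|\Delta\delta_N| \le 0.68$ ppm — applied as a
rectangular box *before* distance ranking, because the acceptance
thresholds are stated per dimension rather than as a combined radius.
Peaks are only counted if **strictly taller than 5%** of the tallest
peak of their own spectrum (each spectrum keeps its own reference
maximum; in the study both references are the His172 resonance).

Matching is **globally greedy**: all gated cross-list pairs are ranked
by $d$ ascending and accepted in order, each acceptance consuming its
bound and free peak.  The published two-phase description ("closest
peaks assigned first, then more distant free peaks to the closest
remaining peak") is read as this distance-ordered global greedy; a
free-peak-sequential variant is available via `method = "sequential"`
in `reverse_assign()` since the original wording admits either reading.
On well-separated peak lists the two coincide.  Ties in distance break
lexicographically on (bound id, free id) so results are deterministic.

Bound peaks that capture no gated free peak are reported categorically
as `bound-only` — the candidate large-shift or exchange-broadened
residues that the study colours as "missing" on the structure — rather
than being assigned an imputed shift value, because a vanished peak
carries no distance information.  Whether the 5% floor preceded or
followed matching in the original analysis is not stated; here
filtering is exposed as an explicit separate step (and a
`apply_height_floor` convenience flag), with the pipeline applying it
before matching.

## Relaxation fitting and mobility profiling

Longitudinal ($T_1$) and transverse ($T_2$) $^{15}$N relaxation decays
are fitted per residue with the two-parameter mono-exponential

$$ I(t) = I_0\, e^{-t/T}, $$

the standard model for amide $^{15}$N peak-height decays; no offset term
is used because none is described and modern gradient-selected
sequences decay to zero.  Delays are taken in ms (the published grids:
13 $T_1$ delays from 10 to 2500 ms, 10 $T_2$ delays from 10 to 320 ms)
and converted to seconds internally.  Fitting uses
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with
deterministic initial guesses ($I_0 = \max I$; $T$ = the delay where
$I$ is nearest $I_0/e$).  Parameter uncertainties come from the
residual-scaled covariance of the solution, with residual-resampling
Monte-Carlo errors behind the `mc_errors` argument.  A fit that fails
or lands outside the physically sensible window (1 ms, 100 s) is
returned as a flagged failure so one bad residue cannot abort a
whole-protein table.

The heteronuclear NOE is the ratio $I_{sat}/I_{ref}$ of the saturated
and reference interleaved spectra, with first-order error propagation.

`mobility_profile()` encodes the qualitative solution finding as a
reproducible rule: a residue is flagged *fast-motion* when both its
$T_1/T_2$ ratio and its NOE fall below 0.75 of the trimmed-mean
(trim = 0.2) core values — reduced ratio *and* reduced NOE being the
signature of sub-nanosecond internal motion — and a contiguous run of
at least 4 residues with $T_2$ below 0.75 of the core is reported as a
low-$T_2$ patch, the signature of microsecond–millisecond exchange.
The fractions and patch length are configuration defaults chosen to
separate a 50% terminal depression from 1–3% experimental noise by a
wide margin; the study states only the qualitative finding, so no
printed values constrain them.

## Superposition and RMSD

`superpose()` pairs atoms by (chain, author residue number, insertion
code, atom name) over a residue interval and computes the least-squares
optimal rotation by the Kabsch SVD construction, with the determinant
sign correction so that reflections are never returned.  The default
atom set is the backbone heavy atoms N, CA, C, O — the published RMSDs
say only "backbone residues (11–167)", and a CA-only fit is one flag
away; the ±0.05 Å acceptance band around the printed values absorbs
this ambiguity.  Tests cross-check the implementation against Horn's
quaternion method and bio3d's fitter to 10⁻⁹, and against the
closed-form expectation RMSD $\approx \sqrt{3}\sigma$ for a copy with
isotropic per-coordinate noise $\sigma$.

## Interaction geometry

All detectors are heavy-atom distance/angle criteria, because crystal
structures at the study's resolution carry no hydrogens; when hydrogens
are present the hydrogen-bond detector additionally requires a
D–H···A angle ≥ 120°.  Defaults:

| interaction | criterion | default |
|---|---|---|
| hydrogen bond | donor–acceptor distance | ≤ 3.5 Å |
| salt bridge | cationic N to anionic O, min per residue pair | ≤ 4.0 Å |
| cation-π | cation-group centroid to ring centroid | ≤ 6.0 Å |
| CH-π | carbon to ring centroid, elevation ≥ 30° | ≤ 4.5 Å |
| water bridge | water O to ≥ 2 polar atoms | ≤ 3.5 Å |
| pocket contact | any ligand–protein heavy-atom pair | ≤ 4.5 Å |

Cation-π geometry is classified by the angle θ between the ring normal
and the centroid-to-cation vector: θ ≤ 30° is *stacked*, θ ≥ 60° is
*T-shaped*, between is *intermediate*.  The 30°/60° boundaries follow
common literature convention; the study makes only the qualitative
stacked/T-shaped distinction (Arg90 T-shaped over UCN-01, stacking over
chlorpromazine).  Ring centroids and unit normals come from a
least-squares plane (SVD); rings deviating more than 0.35 Å from
planarity are skipped with a warning rather than silently mis-measured.

Ligand chemistry (ring atom sets, donors/acceptors, charged groups,
named reference atoms such as the C7 hydroxyl and the bridging ether
oxygen) is declared in a plain-text table keyed by het code rather than
perceived from connectivity — this avoids a cheminformatics dependency
and the ambiguity of chemical-component dictionaries.  The shipped UCN
entry uses generic staurosporine-like atom names and is labelled as
such in the file; deposited files with different nomenclature are
handled by per-entry overrides.  Author residue numbering is always
authoritative; altloc resolution keeps the highest-occupancy conformer,
ties preferring "A".

## Thermodynamics

Affinity differences are expressed as
$\Delta\Delta G = R T \ln(K_d^{(a)}/K_d^{(b)})$ in kJ/mol with
$R = 8.314$ J mol⁻¹ K⁻¹.  The temperature defaults to 298 K — the
solution experiments' temperature — since the published 6–8 kJ/mol
estimate does not state one; at 298 K the 88 nM vs 3.5 nM pair gives
`r round(delta_delta_g(88, 3.5), 2)` kJ/mol, inside the stated band.
The fold change 88/3.5 ≈ 25 is compared against the published
"approximately 20-fold" as a lower bound, since the study's rounding
basis (midpoints vs bounds of the 1–3.5 nM range) is not stated.

## Synthetic data: what it emulates, and what it does not

The seeded generators reproduce the *statistical structure* each
analysis assumes, with known ground truth:

* **Peak lists** — bound-state shifts over realistic amide ranges
  ($^1$H 6.5–11, $^{15}$N 105–135 ppm) with a minimum weighted
  separation of 0.2 ppm (about an order of magnitude above the core
  perturbation scale, and about the densest packing the amide region
  admits at ~170 peaks); ~7% "pocket" residues with large shifts pushed
  beyond the gates; 30% free-peak dropout emulating the extensive
  free-state peak loss; log-normal heights.
* **Relaxation** — core $T_1$ 0.95 s, $T_2$ 0.07 s, NOE 0.82 (typical
  of a rigid ~20 kDa protein at 700 MHz), five-residue termini with
  ratio and NOE at 50% of core, 2% Gaussian intensity noise, sampled on
  the published delay grids.
* **Structures** — an idealized helical backbone trace (N, CA, C, O),
  a copy with isotropic Gaussian coordinate noise and a uniformly
  random proper rigid transform.

They deliberately do **not** emulate spectral lineshapes or peak
overlap, exchange broadening, relaxation interference, real
force-field geometry, or crystallographic artefacts.  Passing tests
therefore demonstrate that the *algorithms* recover known truth under
the study's sampling designs and noise levels — not that any particular
real spectrum would be assigned perfectly.

## Problem sizes and numerical choices

The shipped analyses and checks run at desk scale: 60–170 residue peak
lists, 200-replicate estimator-recovery simulations, 500-atom
superpositions, matcher-oracle equivalence up to 50×50 peak instances.
These sizes make every stochastic property estimable with comfortable
margins while keeping a full run to minutes on one core.  All
randomness flows from a single integer seed per generator call;
repeated runs are bit-identical, and the generators restore the
caller's RNG state.

Known limitations: no titration-series $K_d$ fitting from shift
trajectories; no model-free or dispersion analysis of the relaxation
data; no alignment in sequence comparison (inputs must be pre-aligned
and equal length, as the gapless AGP1/AGP2 alignment is); the
interaction detectors measure geometry, not energetics.  The mature
sequence numbering trusts the explicit tag interval (17 residues) over
the prose count of the cleaved segment, because only the former is
consistent with every downstream residue reference (Cys5/72/147/165,
sequons 15/38/54/75/85, Arg149, Glu173).
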