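---
title: "Detecting mutation-induced solvent exposure of a hydrophobic core"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mutation-induced solvent exposure of a hydrophobic core}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsolv)
```

## The question and the model

A destabilizing point mutation need not unfold a protein to be pathogenic:
it can loosen a buried hydrophobic cluster just enough for water to reach
residues that are normally dry, creating the exposed hydrophobic surface
that chaperones such as BIP recognize. `mutsolv` operationalizes that
picture as a comparative trajectory analysis between a wild-type and a
mutant solvated ensemble:

* **Structural drift.** Per replicate, RMSD against the replicate's own
  initial structure after optimal rigid superposition. We use the Kabsch
  algorithm (SVD of the weighted cross-covariance with reflection
  correction), which yields the exact minimum over proper rigid
  transforms. A fluctuating mutant shows a rising, noisier series.
* **Local solvent accessibility.** Per-residue Shrake–Rupley SASA for
  every residue in the mutation-site neighborhood, as distributions over
  post-equilibration frames pooled across replicates. Shifted, widened
  SASA distributions are the first sign of surface deformation.
* **Where the water goes.** A radial distribution function g(r) of water
  oxygens around each neighborhood residue, and the cumulative difference
  `ΣΔg = Σ_r [g(r)_WT − g(r)_mut]` as a one-number-per-residue ranking
  statistic. Residues with large |ΣΔg| are where the mutation changed
  hydration most; the sign says in which direction (negative = wetter
  mutant under the WT-minus-mutant convention). We rank by magnitude but
  always report the signed value.
* **Core geometry.** The hydrophobic members of the top-ranked set define
  the core; its per-frame mass-weighted radius of gyration, summarized as
  a distribution and median per system, measures core compactness. A
  positive mutant-minus-WT median shift quantifies core opening.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| neighborhood cutoff | 8.0 | Å | minimum heavy-atom distance, closed interval; taken on the shared reference structure so both systems get the same residue set |
| equilibration fraction | 0.4 | — | first `floor(0.4 n)` frames of each replicate discarded, mirroring a 0.4 µs burn-in of 1 µs runs |
| SASA probe radius | 1.4 | Å | water-sized probe |
| SASA lattice points | 960 | — | doubling changes the analytic-sphere value < 0.5% |
| vdW radii | Bondi | Å | standard element radii; hydrogens carried but never occlude |
| RDF range / bin | 10.0 / 0.1 | Å | r_max at the typical nonbonded-cutoff scale and within minimum-image validity (r_max ≤ L/2 enforced) |
| RDF site | heavy-atom center of geometry | — | a point site admits exact shell-volume normalization and a brute-force oracle; minimum-atom-distance RDFs have no clean normalization and are deliberately not implemented |
| ranking direction | abs(ΣΔg) descending | — | ties broken by residue number |
| hydrophobic set | ALA VAL LEU ILE MET PHE TRP CYS TYR | — | the standard-style set under which the motivating ten-residue neighborhood yields exactly seven hydrophobic members |
| contact cutoff | 4.5 | Å | heavy-atom contact for the qualitative "packed core" check; reported, never gates a statistic |
| Rg weighting | mass | — | uniform available via flag |

Open conventions the source protocol left unstated were fixed once, as
flags with defaults: heavy-atom (not Cα) RMSD selection, heavy-atom (not
Cα or center-of-mass) neighborhood distances, replicate-level (not
time-block) RDF standard deviations, pooled-across-replicates (with
per-replicate tables also emitted) distribution summaries, and
accumulation of ΣΔg over the full [0, r_max] range (sub-range flag
provided).

## The synthetic world

`build_mini_protein()` + `generate_ensemble()` state a deliberately small
world in which every planted effect is analytically known:

* a mutation-site residue at the origin surrounded by ten labeled
  residues on a 3.2 Å shell (all within 8 Å of the site; the seven
  hydrophobic ones mutually within 4.5 Å contact — a packed core with the
  site buried at its center), plus nine distant filler residues that any
  correct neighborhood selection must exclude;
* ideal-gas water: oxygens resampled uniformly every frame at the TIP3P
  bulk oxygen density 0.0334 Å⁻³ in a 30 Å cubic box (≥ 2 Å from any
  protein heavy atom), with **no** water–water structure — so g(r) is
  exactly flat away from the protein and normalization tests have exact
  expectations;
* thermal motion as isotropic Gaussian jitter (σ = 0.3 Å) on every
  protein atom;
* mutant mode plants (a) a rigid scaling of the core about its centroid
  so the pre-jitter core Rg rises by exactly +0.8 Å — the toy-scale
  analogue of the full-scale 8.847 → 9.675 Å median shift — and (b)
  threefold water density within 4 Å of residues 520, 588 and 658.
  "Threefold" is defined against the *accessible* part of the shell: the
  generator Monte-Carlo-estimates the shell volume outside the 2 Å
  exclusion zone and adds `(f−1)·ρ·V_acc` extra waters there, so the
  counting oracle `waters-in-shell / (ρ·V_acc) ≈ f` holds without
  geometric fudge factors;
* 3 replicates × 500 frames per system spanning a nominal 1000 ns,
  equilibration fraction 0.4 — the replicate design of the motivating
  study at toy scale. All randomness flows from one integer seed;
  identical seed and parameters give byte-identical DCD output.

What the world does **not** emulate: real solvation shells (no
water–water correlation, so absolute g(r) peak shapes are meaningless
here), force-field physics, correlated protein dynamics (jitter is
i.i.d.), or box-density response to the core inflation. A green recovery
test therefore establishes that the *analysis machinery* measures planted
contrasts correctly — not that the toy reproduces full-scale MD numbers.
The full-scale medians are retained as unreachable-at-desk-scale context
only.

Two small systematic offsets are accepted and documented rather than
corrected, because they are common mode between the systems and cancel in
WT-minus-mutant contrasts: the protein's excluded volume concentrates
bulk water slightly (g ≈ 1.05–1.1 far from a buried residue), and the
mutant's extra enrichment waters inflate the global density estimate by
about 2%.

## Numerical choices

* RDF shell volumes use `4π r_mid² Δr` (the stated contract), not the
  exact `4π/3 (r₂³−r₁³)`; the difference is `Δr²/(12 r²)` — under 0.1%
  beyond 1 Å at Δr = 0.1 Å — and the binning (`floor(r/Δr)`,
  round-half-even minimum image) is shared bit-exactly with the
  brute-force oracle used in tests.
* The neighborhood and contact criteria are closed intervals (`≤ cutoff`);
  boundary residues are included.
* Kabsch degeneracy: fewer than 3 points or a (near-)collinear reference
  is an error, not a silent answer; reflections are corrected via the
  determinant sign so returned rotations are always proper.
* Median = mean of the two central order statistics at even n (the
  convention of the sort-based oracle in the tests); histograms use
  equal-width bins spanning the sample range, with a ±0.5 guard band for
  zero-variance samples so counts always sum to n.
* DCD coordinates are float32 (≈ 1e-6 relative precision); PDB
  coordinates carry 3 decimals. Round-trip tests assert at format
  precision, not exactness.
* Water placement rejection caps at 200 resampling rounds and then
  errors ("density/box infeasible") instead of spinning.
* Box handling is orthorhombic-only throughout; triclinic input is an
  explicit error at parse time.

## Design decisions that were genuinely open

* **Site of the RDF.** Atom, center of mass, or minimum distance were all
  defensible; heavy-atom center of geometry was chosen for exact
  normalization and testability (see table above).
* **Excluding the mutated residue from the compared set.** The site
  residue differs chemically between systems, so its own SASA/RDF are not
  comparable; neighborhoods are built on the shared reference and exclude
  it, consistent with ranking tables that list residues other than the
  site.
* **Ranking by |ΣΔg|.** The WT-minus-mutant convention makes wetter-mutant
  residues negative, yet those are precisely the interesting ones;
  "largest difference" is read as magnitude, with the sign always
  reported.
* **Enrichment against accessible volume.** Defining the planted factor
  relative to the geometric shell volume would make the planted truth
  depend on how much protein the shell happens to contain; the
  accessible-volume definition keeps the oracle exact for buried residues.
* **Fixed water counts per frame.** Resampling a Poisson-varying water
  number would break the fixed-topology contract of trajectory formats;
  extra enrichment waters are instead a fixed, manifest-recorded count.

## Known limitations

* SASA ignores periodic images; valid for compact solutes far from their
  images (enforced implicitly by the r_max ≤ L/2 check on the RDF side
  only).
* The DCD reader/writer covers the CHARMM-style orthorhombic dialect it
  emits (cross-checked against MDAnalysis); exotic variants (fixed atoms,
  4D, big-endian) are out of scope.
* `ΣΔg` depends on binning; comparisons are only made between profiles on
  identical bins, and the accumulation range is part of the reported
  convention.
* Per-replicate RDF SDs with three replicates are noisy; they are
  descriptive error bars, not inferential intervals.
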