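# mutsolv

Trajectory analysis for asking a focused structural question: **does a point
mutation open a protein's buried hydrophobic core to water?** The motivating
case is an autism-associated tryptophan-to-arginine substitution (W647R) in
the EF-hand region of the extracellular domain of Hevin/SPARCL1, where
improper folding exposes hydrophobic residues, recruits the ER chaperone BIP
and triggers the unfolded protein response. `mutsolv` implements the
comparative MD post-processing that detects this signature, for matched
wild-type and mutant solvated ensembles from any MD engine.

## What it computes

Given WT and mutant ensembles (topology + replicate trajectories, with
orthorhombic boxes) and the mutation-site residue, the pipeline runs:

1. **RMSD time series** — each frame is Kabsch-superposed (SVD with
   reflection correction) on its replicate's initial structure;
   `RMSD = min_{R,t} sqrt( Σᵢ wᵢ |R xᵢ + t − yᵢ|² / Σᵢ wᵢ )`.
2. **Neighborhood selection** — all residues with any heavy atom within
   8 Å (closed interval) of the site residue in the reference structure.
3. **Per-residue SASA distributions** — Shrake–Rupley with probe 1.4 Å,
   960 lattice points, Bondi radii; per-residue areas pooled over
   post-equilibration frames of all replicates.
4. **Per-residue water RDFs** — g(r) of water oxygens around the residue's
   heavy-atom center of geometry, minimum-image distances, shell
   normalization `n_b / (4π r_b² Δr ρ_bulk)`, mean and SD across replicates.
5. **Ranking statistic** — the cumulative RDF difference per residue,

   `ΣΔg = Σ_r [ g(r)_WT − g(r)_mut ]`,

   ranked by magnitude; the top-N residues are the headline
   solvation-shift set.
6. **Hydrophobic core Rg** — the hydrophobic members (ALA, VAL, LEU, ILE,
   MET, PHE, TRP, CYS, TYR) of the top-ranked set form the core; its
   mass-weighted radius of gyration is sampled per frame and summarized as
   distributions and medians (the WT-vs-mutant median shift is the headline
   number; at full MD scale the motivating system shifts 8.847 → 9.675 Å).

The first 40% of every replicate is discarded as equilibration (fraction
configurable), mirroring the 0.4 µs / 1 µs split of the motivating study.

A deterministic **synthetic generator** builds solvated mini-protein
ensembles with planted ground truth — core Rg inflation, local water
enrichment, thermal jitter — so every stage is validated by
parameter-recovery tests without running microsecond MD.

## Worked example

```r
library(mutsolv)

# matched synthetic pair: water enrichment planted at residues 520/588/658,
# core Rg inflated +0.8 A in the "mutant" (3 replicates x 500 frames each)
pair <- synthetic_comparison(1)
report <- run_comparison(pair$wt$ensemble, pair$mut$ensemble,
                         site_residue = 647, output_dir = "demo_out")
print(report)
```

prints (exact output, seed 1):

```
Comparison report
  neighborhood: 10 residues around site 647
  top-ranked residues: Y588, V520, I658, L616, T628, I521, D517, F630, K582, Y590 
  hydrophobic core: 588, 520, 658, 616, 521, 630, 590 
  core Rg medians: WT = 3.061 A, W647R = 3.847 A (diff +0.786 A)
```

Reading it: the three planted residues (V520, Y588, I658) occupy the top
three ranks of the ΣΔg table (their sums are negative — the mutant has
*more* water around them, and ranking is by magnitude); the recovered core
Rg median shift (+0.786 Å) matches the planted +0.8 Å within sampling
noise. `demo_out/` holds `rmsd.tsv`, `sasa.tsv`, `sasa_summary.tsv`,
per-residue `rdf_<label>_<residue>.tsv`, `ranking.tsv`, `rg.tsv`,
`rg_summary.tsv`, `core.json`, `report.json` and `run.log`.

Real data goes through the same route from files:

```r
report <- run_comparison_config("analysis.cfg")   # flat key: value config
```

or the command line (`inst/cli/mutsolv`):

```sh
Rscript inst/cli/mutsolv synth --mode mutant --seed 7 --out synth/
Rscript inst/cli/mutsolv run --config analysis.cfg
```

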