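# tetherscope

Most eukaryotic proteins carry several domains on one chain, yet the same
fold is often also found alone as a single-domain protein. `tetherscope`
asks, for a given domain observed both ways, what the tethered neighbours
do to it: does the domain's conformation shift, does its residue-residue
communication network rewire, do its slow collective motions and
residue-level energetic frustration change? The package is aimed at
structural bioinformaticians comparing multi-domain ("MD") and isolated
("ID") crystal forms of the same (or a homologous) domain, and it ships a
seeded synthetic-structure generator so the entire pipeline can be
exercised, and its detectors validated, without downloading a single PDB
entry.

## What it computes

For a pair of structures sharing a common domain, mapped residue-by-residue
by global sequence alignment:

* **Structural deviation** — optimal least-squares (Kabsch) superposition of
  the mapped Cα sets, global RMSD, and a GDT score at a 4 Å cutoff
  (the largest fraction of residues fitting under one rigid superposition,
  found by a seed-extend search). Residues whose Cα distance exceeds
  mean + 2σ of the distance distribution are flagged as locally deviating
  regions, and the pair is categorized by whether those regions fall on the
  domain–domain interface (any atom pair across domains closer than the sum
  of van der Waals radii + 0.5 Å).
* **Network rewiring** — an unweighted Cα contact network (edges at ≤ 5 Å)
  per member; communicability centrality, coc(i) = [e^A]_ii (the
  factorial-weighted count of closed walks through residue *i*), z-scored
  within the domain; residues with |coc_MD − coc_ID| > 1.5 are flagged.
* **Dynamics** — anisotropic network model normal modes at a 15 Å cutoff
  with distance-dependent springs γ(d) ∝ 1/d²; the low-frequency modes
  carrying 80 % of the variance; normalized summed square fluctuations
  (with 5 residues trimmed per terminus); residue–residue cross-correlation
  matrices C_ij ∈ [−1, 1]; the Rv coefficient
  tr(AB)/√(tr(AA)·tr(BB)) between the members' matrices; and the
  fraction of strongly coupled pairs (|C_ij| ≥ 0.7).
* **Frustration** — per-residue and per-contact frustration indices: the
  Z-score of the native contact energy against decoy ensembles (exhaustive
  amino-acid substitutions for the mutational index and SRLF; resampled
  structural contexts for the configurational index), classified as
  minimally (> 0.78), neutrally, or highly (< −1) frustrated, under a
  pluggable 20×20 contact potential.
* **Control constructs** — in-silico amputation (drop the tethered
  domains), domain swap (rigidly graft the ID into the MD scaffold), and
  homolog chimeras with automatic junction-clash trimming (up to 9
  residues per junction side), mirroring the controls used to separate
  tethering effects from crystal-packing artefacts.

## Worked example

```r
library(tetherscope)

# a synthetic MD/ID pair: 60-residue common domain tethered to a
# 50-residue partner with ~12 interface contacts, 0.2 A coordinate noise
spec <- synthetic_spec(domain_sizes = c(60, 50), interface_contacts = 12,
                       noise_sd = 0.2, seed = 42)
pair <- make_multidomain(spec)

cfg <- analysis_config(radii = c(C = 2.75))  # effective CA radius for CA-only beads
report <- analyze_pair(pair$md, pair$id, pair$common, cfg)
report
#> pair_report: synth-MD vs synth-ID
#>   RMSD 0.4995 A  GDT 100.00  (100-GDT 0.00)  category: non-interface-only
#>   centrality flags: 4
#>   Rv 0.8533  coupling MD 0.0017  ID 0.0045
#>   frustration class changes: SRLF 0  MFI 0  CFI 4
```

Reading the numbers: the two copies of the common domain differ only by
the planted 0.2 Å noise, so the global deviation is small (RMSD ≈ 0.5 Å,
every residue fits under 4 Å, hence GDT 100 and 100−GDT 0) and the flagged
residues sit away from the interface. Four residues changed normalized
communicability by more than 1.5, the cross-correlation matrices agree
imperfectly (Rv 0.85), and four contacts changed configurational
frustration class. `write_pair_report(report, "out/")` dumps
`summary.json` plus per-residue TSV tables.

Real structures enter the same way: `read_structure("file.pdb")`,
`domain_def()` with SCOPe-style residue ranges, then `analyze_pair()`.
Homologous single/multi-domain pairs with functional-residue lists go
through `analyze_homolog_pair()`, which also builds and scores the
chimera.

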