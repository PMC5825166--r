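---
title: "Methods: comparing a protein domain in tethered and isolated forms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing a protein domain in tethered and isolated forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherscope)
```

`tetherscope` compares a protein domain crystallized in a multi-domain
context (MD) against the same or a homologous domain in isolation (ID),
along four axes: conformation, contact-network communicability,
elastic-network dynamics, and energetic frustration. This vignette is the
package's own account of the models behind each stage, the parameters that
matter, and the choices made where the design was genuinely open.

## Input model and residue mapping

Structures are single polypeptide chains; heteroatoms and waters are
dropped on reading, alternate locations resolve to the highest-occupancy
conformer (ties: first in file), and multi-model files contribute only
their first model. The package does no missing-residue modelling: every
pairwise stage restricts itself to residues resolved in *both* members,
via a residue mapping built by global sequence alignment (match +1,
mismatch −1, linear gap −2). In identical-domain mode only identical
aligned columns are mapped and an identity below 0.9 aborts the pairing —
identical-domain pairs are expected to differ only by short terminal
extensions. Homolog mode maps every aligned non-gap column and reports the
identity fraction.

Domain–domain interface residues are those with any atom strictly closer
than the partners' van der Waals radii sum + 0.5 Å to an atom of another
domain. No authoritative radii set exists for this criterion, so the
table is configuration: the default (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80, H 1.20 Å) covers heavy atoms of crystal structures; hydrogens
absent from X-ray models are simply never considered. Cα-only synthetic
structures use an enlarged effective carbon radius (2.75 Å, giving a 6 Å
bead criterion) because a 3.9 Å threshold is below the closest approach
of two Cα beads.

## Structural deviation

Mapped Cα sets are superposed by the Kabsch algorithm (SVD of the
covariance matrix, reflection branch excluded so the rotation is proper).
RMSD is computed over the full mapped set — not over a
subset chosen by a structure aligner — so one number means one thing.

GDT at a single 4 Å threshold is the largest fraction of residues that fit
simultaneously under one rigid superposition. The search is seed-extend:
every contiguous window of lengths 4, N/4, N/2 and N is superposed, the
within-cutoff set is re-superposed until stable (20-round cap), and every
iterate is scored; ties prefer the larger set, then the lower RMSD over
the included set. Two hardening steps close the gap to exhaustive
enumeration: a shrink pass drops the worst-fitting residue from the full
set one at a time, and for chains of ≤ 12 residues every 4-residue
combination also seeds the search — at those sizes the only optimal fit
set can be reachable from a single non-contiguous quadruple, and the
enumeration is cheap. The in-package tests hold the heuristic to equality
with an exhaustive-subset oracle at N ≤ 12.

Locally deviating regions are residues whose post-superposition Cα
distance exceeds the mean of the distance distribution by more than twice
its population standard deviation (divide-by-N; deterministic on small N,
where the sample convention would inflate the threshold). A 10⁻⁶ Å floor
under the rule keeps numerically-zero distances on identical structures
from being flagged. A pair is then categorized by whether its flagged
regions lie on the interface, off it, both, or nowhere.

## Contact networks and communicability

The residue network is unweighted and undirected with an edge wherever
the Cα–Cα distance is ≤ 5 Å. Communicability centrality is the diagonal
of the matrix exponential of the adjacency — the sum over closed walks of
every length through a node, weighted 1/k! — computed by
eigendecomposition of the symmetric adjacency. Raw values are z-scored
within the domain before comparison: the flagging threshold
|Δcoc| > 1.5 is only meaningful on a scale-free axis, and z-scoring is
the simplest normalization that makes it so. By default the MD network is
built on the common domain alone, so a flag means *intra-domain rewiring*
rather than the trivial extra edges contributed by the tethered domain; a
`network_scope = "whole"` flag switches to whole-protein networks with
restriction afterwards.

## Elastic-network dynamics

The anisotropic network model connects Cα beads within 15 Å. The spring
constant is distance-dependent — closer contacts are stiffer — with
γ(d) = γ₀(d₀/d)², d₀ = 1 Å, γ₀ = 1 (arbitrary units). The inverse-square
form is one standard choice among several; it is a configurable function
argument, and results that depend on its exact shape should be read with
that in mind. The Hessian superblock for a contacting pair is
−γ(d)/d² · r rᵀ, diagonals are negated row sums (translation
invariance), and the spectrum comes from a dense symmetric
eigendecomposition. Zero modes are detected at λ < 10⁻⁸ · λ_max; six are
expected for a connected, non-planar system, and a disconnected contact
graph is reported as a warning rather than an error. The two-bead dimer
is admitted as a well-defined special case (one stretch mode of stiffness
2γ(d)); collinear systems of three or more beads are rejected because a
pairwise-distance energy has no transverse stiffness there.

Mode variance is proportional to 1/λ; modes are taken in ascending-λ
order until they carry 80 % of the variance. Fluctuations are
per-residue sums of (1/λ)|v(i)|² over that set; five residues are
trimmed from each chain terminus (termini dominate raw ENM fluctuations)
and the remainder is z-scored *after* restriction to the common domain.
Cross-correlations C_ij are mode-set covariances normalized to unit
diagonal, restricted to the mapped common-domain residues so both
members' matrices have identical dimensions, and compared by the Rv
coefficient tr(AB)/√(tr(AA)tr(BB)). The coupling fraction counts
off-diagonal pairs with |C_ij| ≥ 0.7, inclusive.

## Frustration

The frustration machinery follows the decoy/Z-score framework: an index
is (mean(E_decoys) − E_native)/sd(E_decoys) with the sample (n−1) sd, so
a native more stable than its decoys scores positive, and classes are
minimal (> 0.78), neutral, high (< −1), boundaries inclusive to neutral.
Contacts are Cα pairs at ≤ 5 Å with sequence separation ≥ 2.

The energy model is deliberately simple and pluggable: a symmetric 20×20
contact table scaled by an inverse-square distance weight (reference
4 Å), with an optional contact-count burial term (off by default). The
shipped table is a hydrophobicity product built from Kyte–Doolittle
values mapped to [0, 1] — hydrophobic–hydrophobic contacts are most
favourable, which is the dominant eigenmode of empirical contact
potentials. This is a fidelity limitation stated openly: the package
reproduces the frustration *framework* (decoy construction, Z-scoring,
classification), not the numeric indices of any five-term
associative-memory energy function. Because indices are Z-scores, every
index is invariant to a positive rescaling of the table, which the tests
assert.

Mutational decoys enumerate all 400 ordered amino-acid pairs (native
included once as written) whenever the decoy budget allows, so those
indices are seed-free; configurational decoys re-evaluate the native
pair in contexts resampled from the structure's own empirical
distribution of contact distances and burial counts, with an explicit
seed. Resampling continuous distances rather than binned distance
classes was a design choice — it needs no bin boundaries and a chi-square
test in the suite confirms the resampled contexts follow the empirical
distribution. Degenerate ensembles (zero spread, isolated residues)
yield an `undefined` class rather than a number.

## Control constructs

Amputation extracts the common domain from MD bit-identically. The swap
construct superposes ID onto MD's common domain by Kabsch on the mapped
Cα and replaces the domain in place under MD numbering. Chimeras graft a
single-domain homolog into a multi-domain scaffold: superpose on the
mapped Cα of the homologous domain, excise, ligate. While any
inter-parent atom pair is closer than 2.0 Å, one residue is removed from
a junction terminus — alternating sides, starting with the N-terminal
side of the downstream parent, at most 9 per side, the junction chosen
nearest the worst clash — and the per-junction trim counts plus full
residue provenance are recorded. Gene-duplicated scaffolds take a list
of graft sites. No junction geometry is rebuilt or minimized afterwards:
the downstream elastic-network and contact analyses are distance-based
and tolerate a stretched peptide link, but the constructs are *not*
physically refined models.

## The synthetic generator, and what passing tests mean

`make_domain()` produces Cα traces: ideal helices (rise 1.5 Å,
100°/residue, radius set so consecutive Cα sit 3.8 Å apart) or compact
self-avoiding walks (3.8 Å steps, non-adjacent beads ≥ 4 Å apart,
confined to a sphere of radius 3.3·n^⅓ + 3 Å so the chain is globular).
`make_multidomain()` tethers a 50-residue partner to a 60-residue common
domain through a 4-residue linker, translating the partner along a
seeded direction until the cross-domain 6 Å Cα contact count lands
within ±20 % of the 12-contact target; the isolated member is the same
common domain with an independent 0.2 Å noise draw. These defaults are
the package's study conditions: domains large enough to survive 5+5
terminal trimming with room to spare, small enough that a dense 3N
eigendecomposition is instant, noise at the scale of coordinate
uncertainty between independently refined crystal forms, and an
interface of realistic sparsity. Hinge rotations, terminal truncations,
and planted rigid displacements (`perturb()`) supply known ground truth
for the detectors.

What the generator does *not* emulate: side chains, secondary-structure
packing, sequence–structure consistency (sequences are random), crystal
contacts, and real interface chemistry. Passing the recovery tests
therefore shows that the detectors find what they are defined to find
under controlled geometry and noise — not that the biological effect
sizes on real crystal pairs will match. The directional properties the
suite asserts — interface residues rigidified in the tethered member,
within-domain coupling raised — are qualitative signatures of adding
elastic contacts to one face of a domain, and they are evaluated as
rates over seeded replicates (a replicate whose interface lies entirely
inside the trimmed termini is excluded as unscorable).

## Statistics and reporting

The two-sample KS test uses the asymptotic Kolmogorov p-value (the exact
small-sample form is only relevant below the sizes the pipeline
compares, and the suite checks the D statistic against direct ECDF
enumeration). Spearman correlation is mid-rank Pearson; the upper
quartile uses type-7 linear interpolation; no multiple-testing
correction is applied anywhere. Reports round scores to four decimals in
`summary.json` and keep full precision in the TSV tables. Two runs with
the same configuration and seeds produce identical outputs; every
stochastic stage (configurational decoys, synthetic generation) takes an
explicit seed, and the acceptance script derives all of its seeds from
one `--seed` argument.

## Known limitations

* The contact potential is a stand-in with the right symmetries, not a
  fitted statistical potential; absolute frustration indices should not
  be compared against other software, only within-pipeline contrasts.
* The ANM spring form is conventional, not fitted; Rv and coupling
  fractions shift with γ(d), though the MD-vs-ID *directions* are stable
  in the suite's replicate tests.
* Interface detection treats sequence-adjacent residues across a
  domain boundary like any other atom pair; junction residues of a
  contiguous multi-domain chain therefore count as interface.
* No structure repair: pairs with large unresolved regions lose those
  regions from every comparison rather than having them modelled.
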