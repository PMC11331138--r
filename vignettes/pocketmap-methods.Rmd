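---
title: "Methods: mapping receptor-peptide binding pockets from conservation and predicted complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping receptor-peptide binding pockets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketmap)
```

## The problem

Plant leucine-rich-repeat receptor kinases (LRR-RKs) perceive short secreted
signaling peptides, but solved structures of peptide-receptor complexes are
rare. When a peptide family is recognizable only by a short conserved motif
(here an SxS serine pair at mature positions 5 and 7) embedded in otherwise
divergent 13-15-residue peptides, two independent lines of evidence can
triangulate the binding site without crystallography:

1. **Conservation**: across validated receptor homologues, ligand-contacting
   surface residues stay conserved while the rest of the exposed ectodomain
   surface diversifies. Projecting alignment conservation onto the repeat
   architecture (repeat conservation mapping, RCM) reveals such patches.
2. **Predicted complexes**: AI structure predictors emit candidate
   receptor-peptide complexes with an interface confidence score (ipTM).
   Filtering by confidence and intersecting hydrogen-bond contacts across
   models yields consensus pockets.

`pocketmap` implements the full chain - mining candidate genes by synteny,
building peptide profiles, curating receptors by repeat architecture,
computing RCM, calling consensus pockets, and testing whether the predicted
contacts are enriched in conserved cells - together with a seeded synthetic
data generator so every stage is testable without external genomes or
structure predictions.

## Synthetic study conditions

The generator's defaults are the package's reference conditions; all tests
and examples run at these sizes.

| parameter | default | meaning |
|---|---|---|
| `n_taxa` | 37 | receptor homologues in the family alignment |
| `n_repeats` | 24 | LRR units per ectodomain (the curation criterion) |
| `tree_depth` | 2 subs/site | root-to-tip height of the coalescent tree |
| `background_rate` | 3.0 | substitution rate at exposed non-patch sites |
| `patch_rate` | 0.01 | substitution rate inside the planted patch |
| `patch_cells` | repeats 1-11, positions 1-3 | planted conserved patch |
| `n_clusters` x `n_species` | 10 x 8 | peptide families x members |
| `mature_length` | 13 | mature peptide window (bioactive peptides of this family are 13-15mers) |
| `divergence` | 0.2 | per-site substitution probability between family members |
| `n_models` / `n_decoy_models` | 12 / 3 | confident / low-confidence toy complexes |

Why these values: the receptor family size matches a realistic validated
homologue panel; the strongly diversified background (expected ~6
substitutions per exposed background site root-to-tip) against a
near-invariant patch reproduces the qualitative contrast that makes RCM
informative - functional patches read as near-invariant while the
surrounding exposed surface approaches substitution saturation. The patch
spans the concave (ligand-facing) positions of the N-terminal repeats and
was sized at design time so that it occupies most - but not all - of the
top quintile of smoothed grid cells; a patch much larger than a fifth of
the grid could not be returned intact by a quantile call at the default
`q = 0.8`, and a much smaller one would make the default pocket residues
fall outside it. The fixed 73-residue N-cap places the default pocket
residues 246/268 (peptide position 5) and 292/294/316 (position 7) at
repeats 8-11, inside the patch.

### What the generator emulates, and what it does not

The canonical 24-residue unit follows the plant LRR framework
("LxxLxLxxNxLxGxIPxx"-style) with ten fixed anchor residues; evolution is
per-site independent replacement along a random coalescent tree, with no
indels inside repeats - this mirrors the downstream curation rule (equal
repeat counts, no gaps outside repeats) and keeps family alignments
gap-free by construction. Toy complexes carry only N, CA, C, O, CB and one
polar side-chain pseudo-atom per residue, placed so that planted contacts
sit at exact hydrogen-bond geometry (2.9 A donor-acceptor, donor angle
at least 120 degrees) while every non-planted residue pair stays beyond the
4.0 A contact cutoff by a guard margin of at least 0.5 A.

Real data differ in ways the generator deliberately omits: indel evolution
and alignment uncertainty, rate heterogeneity along sites and lineages,
repeat-length variation, side-chain rotamers and packing, correlated
substitution between interacting residues, and annotation noise in gene
models. Passing tests therefore demonstrate the correctness and calibration
of the machinery under the stated statistical structure - not robustness of
the pipeline to misalignment or mis-annotation.

## Module notes and design choices

### Locus mining

Coordinates are 0-based half-open internally; the GFF3 reader converts at
the boundary. The locus window is count-based (genes on each side of the
anchor block; default 10) because the source analyses do not state a window.
Similarity links use optimal local alignment (BLOSUM62, gap open 11 /
extend 1) with Karlin-Altschul statistics (lambda = 0.267, K = 0.041, the
standard gapped-BLOSUM62 parameterisation) over the pairwise search space
`m x n`; exact parity with any particular BLAST release is not a goal. The
E-value filter is strictly `evalue < evalue_max` with the conventional
1e-6 default. Candidate extraction is the transitive closure over links,
restricted to locus members, and is independent of locus processing order.

### Peptide catalog

Profiles are position-specific scoring matrices rather than profile HMMs:
synthetic mature windows are gap-free by construction, so position-specific
indel states would be dead weight; the PSSM is documented as a simplified
stand-in wherever a profile-HMM search would be used at scale. Frequencies
use `(counts + alpha * background) / (n + alpha)` with `alpha = 1` and a
uniform background by default; log-odds are in bits.

Clustering is single linkage over local-alignment identity
(matches / alignment length, threshold 0.45). Identity alone proved
insufficient: the score-optimal local alignment of two *unrelated*
sequences is typically a short segment with high identity, which would
merge everything. An alignment-coverage floor (alignment length at least
half the shorter sequence, `coverage_min = 0.5`) restores the intended
behavior; both thresholds are exposed.

Mature-window extraction returns the profile-optimal window of the
profile's length, ties broken at the smallest offset; 15mer peptides are
handled by building a 15-column profile. Motif statistics report
per-position information content `IC_j = log2(20) - H_j` (Shannon entropy
in bits, gaps excluded) and the fractions of SxS and SxT peptides at the
motif positions.

### Receptor curation and phylogeny

The repeat detector scans greedily left-to-right with the canonical unit,
tolerating up to 2 anchor mismatches per unit; curation keeps candidates
whose repeat count equals the expected 24 and whose alignment rows have no
gaps outside repeat segments, recording a machine-readable reason for every
rejection. Pairwise similarity reports both BLOSUM-positive similarity (as
percent) and identity; the distance matrix is `1 - identity`.

The tree stage is neighbor joining rather than maximum likelihood with
bootstraps: downstream analysis consumes only the seed-containing clade
(topology), not branch support, and NJ provably recovers the topology on
additive distances - a property the test suite exercises on seeded random
trees. Negative NJ branch lengths are clamped to zero with a warning.
Clade extraction roots at the designated outgroup and returns the MRCA
subtree of the seeds; the package exposes the ectodomain-only versus
full-protein choice simply through which sequences are supplied, and makes
no attempt to reconcile disagreements between the two - that judgement is
left to the analyst.

### Repeat conservation mapping

The per-column statistic is one minus the normalized Shannon entropy of the
alpha-pseudocounted residue frequencies - bounded in [0, 1], zero for a
uniform column, one for an invariant one. Gaps are excluded from counts and
the gap fraction is carried alongside rather than silently folded in. The
statistic is pluggable: a substitution-matrix alternative (fraction of
BLOSUM62-positive residue pairs) ships behind `method = "blosum"`, because
the original RCM literature does not print its exact per-cell formula.

Regional smoothing averages the 5 x 5 neighborhood with weights
`1 / (1 + Chebyshev distance)` - center 1, first ring 1/2, second ring 1/3 -
chosen for strict center dominance and simplicity; the kernel is a plain R
function argument and can be replaced. At grid edges the window truncates
and weights renormalize over present cells, so edge scores remain weighted
means of real data rather than being diluted by padding. Conserved regions
are the cells at or above the `q = 0.8` quantile of the smoothed map;
contiguity is not required.

### Complex pockets

ipTM thresholds follow the printed values literally and strictly: an AFM
model is confident only when `iptm > 0.84`; AF3 models are confident above
0.8, in the gray zone in (0.6, 0.8], rejected otherwise. Boundary values
demote. Contact and hydrogen-bond criteria are standard structural-biology
defaults (4.0 A minimum heavy-atom distance; 3.5 A donor-acceptor distance
among N/O atoms with a 120-degree donor angle), configurable because the
source analyses print no cutoffs. Hydrogens are ignored; the donor angle is
checked only when the donor's antecedent heavy atom exists in the model,
and a pair is kept when at least one orientation is geometrically
consistent with donation. Peptide positions are numbered 1..13 (or 15) from
the mature N-terminus and receptor numbering follows the author numbering
of the input structure, so pockets print as residue numbers like D246 or
H316. Consensus keeps a residue at a position when it appears in at least
`min_support` (default one half) of the confident models.

Superposition is a standard Kabsch least-squares fit on paired C-alpha
atoms with the proper-rotation correction (det = +1); it is cross-checked
in the tests against an independent reference implementation.

### Enrichment

The claim "predicted contacts fall within conserved regions" is formalized
as a one-sided permutation test: the observed statistic is the mean
*regional* (smoothed) conservation over the contact cells - matching what
an RCM display shows - and the null resamples the same number of cells
uniformly without replacement from the whole exposed grid, by default
unstratified because the claim contrasts contact cells against the
ectodomain surface at large (a row-stratified null would instead condition
on the repeat profile; it can be built by resampling within rows of the
tidied map). The p-value uses the add-one rule
`p = (1 + #{null >= observed}) / (1 + N_perm)` and is therefore never zero.
This statistic and null are this package's own formalization - the source
analyses assert the overlap qualitatively - and every report labels them as
such.

## Numerical choices and degenerate inputs

- Alignment traceback ties are resolved by the alignment engine's
  deterministic convention (Biostrings); cluster numbering is by smallest
  member id; mature-window ties take the smallest offset; hit tables sort
  by score, then id, then offset.
- `build_profile` rejects all-gap columns; `column_conservation` rejects
  all-gap columns; `extract_mature_peptide` rejects precursors shorter than
  the window; `enrichment_test` rejects empty cell sets and cell sets
  larger than the grid; empty loci yield empty link tables (not errors);
  zero detected repeats is a valid annotation.
- The toy-complex generator rejects geometrically infeasible contact
  requests (a receptor residue contacting two peptide positions, or more
  than five residues at one position) rather than emitting a file that
  violates its own guarantees.
- All generators are deterministic given `sim_config(seed)`; derived seeds
  for sub-streams stay far below 2^31.

## Problem sizes used by the tests

The suite runs the full default conditions (37 x 24-repeat receptors,
80 precursors plus decoys, 15 toy complexes of ~4,200 atoms each), 200
repetitions of the null calibration at 199 permutations, 999 permutations
for the patch enrichment, and 50 random trees of up to 12 taxa for the NJ
property - sizes chosen so the complete suite runs in well under five
minutes on one core while still exercising every stage at its default
geometry.

## Known limitations

- The PSSM scan has no E-value calibration; thresholds are in bits and
  chosen empirically against the planted truth.
- Center-star alignment is O(n^2) in sequence count and not a replacement
  for a progressive aligner on large clusters.
- The mmCIF reader covers the `atom_site` loop emitted by this package,
  not the full mmCIF dictionary.
- Signal peptides, subtilase cleavage and receptor-coreceptor energetics
  are not modelled; mature-window selection is profile-optimal, not
  biochemical.
- Enrichment p-values inherit the granularity of `N_perm` and the
  spatial correlation induced by smoothing: contact cells adjacent to the
  same conserved patch are not independent evidence.
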