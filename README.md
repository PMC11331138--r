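# pocketmap

Inferring the ligand-binding pockets of leucine-rich-repeat receptor
kinases (LRR-RKs) by combining comparative genomics with AI-predicted
complex structures.

Short secreted signaling peptides (13–15 residues, recognizable only by a
conserved SxS serine motif at mature positions 5 and 7) are perceived by
LRR-RK ectodomains, but experimental structures of such complexes are rare.
`pocketmap` triangulates the binding site from two independent signals:

- **Repeat conservation mapping (RCM).** Validated receptor homologues are
  aligned and each solvent-exposed position of each 24-residue LRR unit
  becomes a cell of a repeat × position grid. Per-column conservation is
  `1 − H/log₂20` (Shannon entropy of the pseudocounted residue
  frequencies, gaps excluded), smoothed over the 5 × 5 neighborhood with
  center weights `1/(1 + Chebyshev distance)`. Cells above the 0.8
  quantile are called conserved.
- **Consensus pockets from predicted complexes.** Predicted
  receptor–peptide models are filtered by interface confidence (AFM:
  ipTM > 0.84; AF3: ipTM > 0.8 confident, 0.6–0.8 gray zone). For each
  confident model, hydrogen bonds (N/O pairs ≤ 3.5 Å, donor angle ≥ 120°)
  between receptor residues and the motif serines define per-position
  pockets; a residue enters the consensus when at least half of the models
  support it.
- **Overlap statistic.** Whether the consensus pocket residues sit in
  conserved cells is quantified by a one-sided permutation test: observed =
  mean regional conservation over the pocket cells; null = random cell
  sets of the same size; `p = (1 + #{null ≥ obs}) / (1 + N_perm)`.

Upstream, the package mines candidate genes by synteny (anchor-flanked
locus windows, local-alignment links with Karlin–Altschul E-values,
transitive closure), clusters peptide precursors by local-alignment
identity, builds position-specific scoring profiles (bit log-odds with
pseudocounts) to scan proteomes and extract mature windows, curates
receptor candidates by their repeat architecture (24 LRRs, no gaps outside
repeats), and extracts the seed clade from a neighbor-joining tree.

A seeded synthetic-data generator (`sim_config()`, `generate_*()`)
emulates every input — receptor families with a planted conserved patch,
precursor families with the planted motif, anchor-flanked gene tables, and
toy receptor–peptide complexes with exact planted hydrogen-bond geometry —
so the whole pipeline is testable end to end with known ground truth.

## Worked example

```r
library(pocketmap)
cfg <- sim_config(seed = 1)

# 1. receptor family and conservation map
fam <- generate_receptor_family(cfg)
ref <- names(fam$alignment)[1]
ann <- detect_lrr_repeats(fam$alignment[[ref]])
ann
#> <repeat_annotation> 24 repeats of 24 residues
grid <- build_lrr_grid(fam$alignment, ann, ref)
map <- rcm_map(fam$alignment, grid)
map
#> <rcm_map> 24 repeats x 8 positions, window 5, regional range [0.172, 1.000]

# 2. consensus pockets from the toy model ensemble
ens <- sim_complex_ensemble(cfg)
confident <- ens$models[filter_models(ens$models, "afm")$status == "confident"]
calls <- lapply(confident, function(m) call_pockets(hydrogen_bonds(m)))
consensus <- consensus_pockets(calls, min_support = 0.5)
consensus
#> # A tibble: 5 × 4
#>   position residue support n_models
#>      <int>   <int>   <int>    <int>
#> 1        5     246      12       12
#> 2        5     268      12       12
#> 3        7     292      12       12
#> 4        7     294      12       12
#> 5        7     316      12       12

# 3. are the pockets in conserved cells?
cells <- map_residues_to_grid(unique(consensus$residue), grid)
enrichment_test(cells, map, n_perm = 999, seed = 1)
#> <enrichment_result> observed 0.7058 over 5 cells; p = 0.004 (999 permutations)
```

Reading the output: the repeat detector confirms the 24-unit curation
architecture; the conservation map spans the full regional range, with the
planted N-terminal concave patch at the top; all twelve confident models
agree on the same two pockets — residues 246/268 at peptide position 5 and
292/294/316 at position 7 (support 12/12); and those five residues sit in
cells whose mean smoothed conservation (0.71) is exceeded by essentially no
random cell set (p ≈ 0.004), i.e. the predicted contacts fall squarely
within the conserved surface.

`autoplot(map)`, `autoplot(enrichment_test(...))` and
`autoplot(motif_statistics(...))` give the corresponding heatmap, null
histogram and information-content profile; `tidy()`/`glance()` methods
return tibbles for downstream use.

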