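# Simulation configuration and the canonical LRR repeat unit.

#' The canonical plant LRR unit used throughout the package
#'
#' Plant LRR ectodomains are built from tandem ~24-residue units with a
#' conserved hydrophobic framework ("LxxLxLxxNxLxGxIPxx"-style) and variable,
#' largely solvent-exposed positions in between. The package fixes one such
#' 24-residue framework: ten anchor positions hold their consensus residue
#' (L/N/G/I/P), all other positions are free. The first three variable
#' positions of the beta-strand segment face the concave, ligand-contacting
#' side of the solenoid.
#'
#' @return A list with elements `length` (24), `anchor_pos` (integer
#'   positions of fixed framework residues within the unit), `anchor_res`
#'   (their residues), and `exposed_offsets` (default solvent-exposed
#'   positions, the variable positions of the strand and ascent segments).
#' @export
lrr_unit <- function() {
  list(
    length = 24L,
    anchor_pos = c(1L, 4L, 6L, 9L, 11L, 13L, 15L, 16L, 19L, 22L),
    anchor_res = c("L", "L", "L", "N", "L", "G", "I", "P", "L", "L"),
    exposed_offsets = c(2L, 3L, 5L, 7L, 8L, 10L, 12L, 14L)
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with validation.
#' Defaults define the package's reference study conditions: a 37-homologue
#' receptor family of 24 LRR units evolved along a coalescent tree of depth
#' 2 substitutions/site, with a near-invariant concave-face patch covering
#' LRR 1-11 at the first three exposed positions against a strongly
#' diversified exposed background; peptide families of 10 clusters
#' by 8 species carrying an S5/S7 serine motif in a 13-residue mature window;
#' and toy receptor-peptide complexes whose planted hydrogen-bond contacts
#' reproduce the S5 pocket (residues 246/268) and S7 pocket (292/294/316).
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_species Species count for peptide and locus simulations.
#' @param n_taxa Taxa in the simulated receptor family alignment.
#' @param tree_depth Root-to-tip height of the generating tree, in
#'   substitutions per site.
#' @param n_repeats LRR units per receptor ectodomain.
#' @param patch_cells Two-column matrix (repeat index, exposed-position
#'   index) of grid cells planted as conserved.
#' @param background_rate,patch_rate Per-site substitution rates (events per
#'   site per unit branch length) outside and inside the patch;
#'   `patch_rate <= background_rate` is required (equality yields the
#'   no-patch null control used for calibration).
#' @param motif Named integer vector: required residue at fixed mature-window
#'   positions, e.g. `c(S = 5, S = 7)` for the SxS motif.
#' @param mature_length Mature peptide length in residues (13-15 by default
#'   bounds; minimal bioactive peptides of this family are 13-15mers).
#' @param n_clusters Peptide families to simulate.
#' @param divergence Per-site substitution probability between family members
#'   at non-motif mature positions (and propeptide positions).
#' @param locus_window Genes simulated on each side of the anchor pair.
#' @param n_decoys Unrelated decoy genes/sequences per species.
#' @param n_models,n_decoy_models Confident and low-confidence structure
#'   models in the toy complex ensemble.
#' @param contacts Two-column matrix (receptor residue number, peptide
#'   position) of planted hydrogen-bond contacts.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_species = 8L,
                       n_taxa = 37L,
                       tree_depth = 2,
                       n_repeats = 24L,
                       patch_cells = default_patch_cells(),
                       background_rate = 3.0,
                       patch_rate = 0.01,
                       motif = c(S = 5L, S = 7L),
                       mature_length = 13L,
                       n_clusters = 10L,
                       divergence = 0.2,
                       locus_window = 5L,
                       n_decoys = 6L,
                       n_models = 12L,
                       n_decoy_models = 3L,
                       contacts = default_contacts()) {
  cfg <- list(
    seed = as.integer(seed), n_species = as.integer(n_species),
    n_taxa = as.integer(n_taxa), tree_depth = tree_depth,
    n_repeats = as.integer(n_repeats), patch_cells = patch_cells,
    background_rate = background_rate, patch_rate = patch_rate,
    motif = motif, mature_length = as.integer(mature_length),
    n_clusters = as.integer(n_clusters), divergence = divergence,
    locus_window = as.integer(locus_window), n_decoys = as.integer(n_decoys),
    n_models = as.integer(n_models),
    n_decoy_models = as.integer(n_decoy_models), contacts = contacts
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default planted conserved patch
#'
#' LRR repeats 1-11 at the first three solvent-exposed positions of each
#' unit: a contiguous concave-face patch in the N-terminal half of the
#' ectodomain, emulating a ligand-binding region spanning the first LRRs
#' and containing the default binding-pocket residues.
#'
#' @return Integer matrix with columns `repeat` and `pos`.
#' @export
default_patch_cells <- function() {
  cells <- expand.grid(rep = 1:11, pos = 1:3)
  m <- as.matrix(cells)
  colnames(m) <- c("repeat", "pos")
  m
}

#' Default planted receptor-peptide contacts
#'
#' The two pockets reported for the SxS serine motif: peptide position 5
#' hydrogen-bonds receptor residues 246 and 268, position 7 bonds residues
#' 292, 294 and 316.
#'
#' @return Integer matrix with columns `residue` and `position`.
#' @export
default_contacts <- function() {
  m <- cbind(residue = c(246L, 268L, 292L, 294L, 316L),
             position = c(5L, 5L, 7L, 7L, 7L))
  m
}

validate_sim_config <- function(cfg) {
  unit <- lrr_unit()
  if (cfg$patch_rate > cfg$background_rate)
    abort("`patch_rate` must not exceed `background_rate` (equality gives the no-patch null control).")
  if (cfg$mature_length < 3L)
    abort("`mature_length` must be at least 3 residues.")
  if (any(cfg$motif > cfg$mature_length))
    abort("motif positions must lie within the mature window.")
  pc <- cfg$patch_cells
  if (!is.matrix(pc) || ncol(pc) != 2)
    abort("`patch_cells` must be a two-column matrix (repeat, pos).")
  n_exposed <- length(unit$exposed_offsets)
  bad <- pc[, 1] < 1 | pc[, 1] > cfg$n_repeats | pc[, 2] < 1 | pc[, 2] > n_exposed
  if (any(bad))
    abort(sprintf(
      "patch cell outside grid bounds (%d repeats x %d exposed positions): %s",
      cfg$n_repeats, n_exposed,
      paste(sprintf("(%d,%d)", pc[bad, 1], pc[bad, 2]), collapse = ", ")))
  ct <- cfg$contacts
  if (!is.matrix(ct) || ncol(ct) != 2)
    abort("`contacts` must be a two-column matrix (residue, position).")
  if (any(ct[, 2] < 1 | ct[, 2] > cfg$mature_length))
    abort("planted contact peptide positions must lie within the mature window.")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d taxa x %d LRRs | tree depth %.2f subs/site\n",
              x$seed, x$n_taxa, x$n_repeats, x$tree_depth))
  cat(sprintf("  rates: background %.3f, patch %.3f | patch %d cells\n",
              x$background_rate, x$patch_rate, nrow(x$patch_cells)))
  cat(sprintf("  peptides: %d clusters x %d species, mature %dmer, motif %s\n",
              x$n_clusters, x$n_species, x$mature_length,
              paste(sprintf("%s%d", names(x$motif), x$motif), collapse = "/")))
  invisible(x)
}
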