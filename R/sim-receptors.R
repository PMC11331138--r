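# Simulated LRR receptor families: tandem canonical repeat units between
# fixed caps, evolved site-independently along a coalescent tree, with a
# planted conserved surface patch against a diversified background.

# Fixed N-terminal cap (signal peptide + LRR N-cap, 73 aa) and C-terminal
# cap (LRR C-cap, 30 aa). The N-cap length sets the author numbering of
# every repeat residue: repeat r position p is residue 73 + 24*(r-1) + p,
# which places the default pockets at residues 246/268 (S5, repeats 8-9)
# and 292/294/316 (S7, repeats 10-11), inside the planted conserved patch.
# Both caps are chosen to contain no window matching the repeat framework.
NCAP <- paste0("MRLLSKTLFLVLLLFFFPAISSDAQELRALMELKSSTTDPQDREAFKSQ",
               "HSDPNNVMSSWDPTQVDPCTWFHV")
CCAP <- "SGNKDMCGSPMPKCSSSSKKKRNVTDAMVV"

#' Residue numbering of an LRR grid cell
#'
#' Maps (repeat, exposed-position index) cells to 1-based residue numbers in
#' the reference receptor, and back.
#'
#' @param cells Two-column matrix (repeat, pos index).
#' @param n_cap Length of the N-terminal cap preceding repeat 1.
#' @return Integer vector of residue numbers.
#' @export
cell_to_residue <- function(cells, n_cap = nchar(NCAP)) {
  unit <- lrr_unit()
  n_cap + (cells[, 1] - 1L) * unit$length + unit$exposed_offsets[cells[, 2]]
}

#' Build the curation-reference receptor ectodomain
#'
#' A single canonical receptor: `n_repeats` copies of the 24-residue plant
#' LRR unit (framework anchors fixed, variable positions drawn once from the
#' background composition) between fixed N- and C-terminal caps. This is the
#' root sequence of [generate_receptor_family()] and the fixture on which
#' the repeat detector is expected to report the curation repeat count.
#'
#' @param cfg A [sim_config()].
#' @return Length-one named character vector (name `"ref"`).
#' @export
sim_reference_receptor <- function(cfg = sim_config()) {
  unit <- lrr_unit()
  with_seed(derive_seed(cfg$seed, 101L), {
    reps <- vapply(seq_len(cfg$n_repeats), function(r) {
      u <- character(unit$length)
      u[unit$anchor_pos] <- unit$anchor_res
      free <- setdiff(seq_len(unit$length), unit$anchor_pos)
      u[free] <- seq_to_chars(random_aa(length(free)))
      chars_to_seq(u)
    }, character(1))
    setNames(paste0(NCAP, paste(reps, collapse = ""), CCAP), "ref")
  })
}

#' Simulate an aligned receptor homologue family with a planted patch
#'
#' Evolves the reference ectodomain along a random coalescent tree scaled to
#' `cfg$tree_depth` substitutions/site. Framework anchors and caps are held
#' fixed (no indels, so the emitted alignment is gap-free by construction);
#' sites in `cfg$patch_cells` substitute at `patch_rate`, all other variable
#' repeat positions at `background_rate`. A substitution always changes the
#' residue, so `patch_rate = 0` leaves patch columns identical.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `receptor_family_sim`: list with `alignment`
#'   (named character, gap-free, equal lengths), `tree` (`ape::phylo`),
#'   `truth` (planted patch cells and residues, generating tree in Newick,
#'   reference id), and `cfg`.
#' @export
generate_receptor_family <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  unit <- lrr_unit()
  ref <- seq_to_chars(unname(sim_reference_receptor(cfg)))
  L <- length(ref)
  n_cap <- nchar(NCAP)

  # per-site substitution rate
  rate <- numeric(L)  # caps stay 0
  patch_key <- paste(cfg$patch_cells[, 1], cfg$patch_cells[, 2])
  for (r in seq_len(cfg$n_repeats)) {
    base <- n_cap + (r - 1L) * unit$length
    for (p in seq_len(unit$length)) {
      if (p %in% unit$anchor_pos) next
      e <- match(p, unit$exposed_offsets)
      in_patch <- !is.na(e) && (paste(r, e) %in% patch_key)
      rate[base + p] <- if (in_patch) cfg$patch_rate else cfg$background_rate
    }
  }

  comp <- aa_composition()
  with_seed(derive_seed(cfg$seed, 102L), {
    tree <- ape::rcoal(cfg$n_taxa,
                       tip.label = sprintf("rk%02d", seq_len(cfg$n_taxa)))
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * cfg$tree_depth / depth

    n_tip <- ape::Ntip(tree)
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[n_tip + 1L]] <- ref  # root
    tr <- reorder(tree, "cladewise")  # parents before children
    for (k in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[k, 1]; child <- tr$edge[k, 2]
      el <- tr$edge.length[k]
      s <- seqs[[parent]]
      p_sub <- 1 - exp(-rate * el)
      hit <- which(runif(L) < p_sub)
      for (i in hit) {
        pool <- comp[names(comp) != s[i]]
        s[i] <- sample(names(pool), 1L, prob = pool)
      }
      seqs[[child]] <- s
    }
    aln <- vapply(seq_len(n_tip), function(i) chars_to_seq(seqs[[i]]),
                  character(1))
    names(aln) <- tree$tip.label
  })

  truth <- list(
    planted_patch = cfg$patch_cells,
    planted_patch_residues = cell_to_residue(cfg$patch_cells, n_cap),
    generating_tree = ape::write.tree(tree),
    reference_id = tree$tip.label[1L],
    n_cap = n_cap
  )
  structure(list(alignment = aln, tree = tree, truth = truth, cfg = cfg),
            class = "receptor_family_sim")
}

#' @export
print.receptor_family_sim <- function(x, ...) {
  cat(sprintf("<receptor_family_sim> %d taxa, %d sites (gap-free), %d patch cells\n",
              length(x$alignment), nchar(x$alignment[[1]]),
              nrow(x$truth$planted_patch)))
  invisible(x)
}
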