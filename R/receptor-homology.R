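# Receptor curation by LRR repeat architecture, similarity matrices,
# neighbor-joining trees and seed-clade extraction.

#' Detect tandem LRR units in a receptor sequence
#'
#' Greedy left-to-right scan with the canonical plant LRR framework: a
#' 24-residue window matches when at most `max_mismatch` of its framework
#' anchor positions deviate from the consensus anchors; matches do not
#' overlap. Zero repeats is a valid result.
#'
#' @param sequence Protein sequence.
#' @param unit Repeat definition, default [lrr_unit()].
#' @param max_mismatch Anchor mismatches tolerated per unit (default 2).
#' @return Object of class `repeat_annotation`: list with `repeats`
#'   (tibble `start`, `end`, 1-based inclusive residue coordinates) and
#'   `n_repeats`.
#' @export
detect_lrr_repeats <- function(sequence, unit = lrr_unit(),
                               max_mismatch = 2L) {
  s <- seq_to_chars(sequence)
  L <- length(s)
  starts <- integer(0)
  pos <- 1L
  while (pos + unit$length - 1L <= L) {
    mism <- sum(s[pos + unit$anchor_pos - 1L] != unit$anchor_res)
    if (mism <= max_mismatch) {
      starts <- c(starts, pos)
      pos <- pos + unit$length
    } else pos <- pos + 1L
  }
  structure(list(
    repeats = tibble(start = starts, end = starts + unit$length - 1L),
    n_repeats = length(starts), unit = unit),
    class = "repeat_annotation")
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat(sprintf("<repeat_annotation> %d repeats of %d residues\n",
              x$n_repeats, x$unit$length))
  invisible(x)
}

#' Curate receptor candidates by repeat architecture
#'
#' Keeps a candidate iff its detected repeat count equals
#' `expected_repeats` and, when an alignment row is supplied, the row has
#' no gaps outside the detected repeat segments. Every rejection carries a
#' machine-readable reason (`"repeat_count"` or `"gap_outside_repeats"`);
#' kept and rejected rows partition the input.
#'
#' @param candidates Tibble with columns `id`, `sequence`.
#' @param expected_repeats Required repeat count (default 24, the curation
#'   criterion for this receptor family).
#' @param alignment Optional named character vector of gapped rows (names
#'   matching `id`).
#' @param ... Passed to [detect_lrr_repeats()].
#' @return List with tibbles `kept` (`id`, `sequence`, `n_repeats`) and
#'   `rejected` (`id`, `reason`).
#' @export
curation_filter <- function(candidates, expected_repeats = 24L,
                            alignment = NULL, ...) {
  rows <- purrr::map(seq_len(nrow(candidates)), function(k) {
    id <- candidates$id[k]
    ann <- detect_lrr_repeats(candidates$sequence[k], ...)
    reason <- NA_character_
    if (ann$n_repeats != expected_repeats) {
      reason <- "repeat_count"
    } else if (!is.null(alignment) && id %in% names(alignment)) {
      row <- seq_to_chars(alignment[[id]])
      res_before <- cumsum(row != "-")
      gap_pos <- res_before[row == "-"]  # residue index preceding each gap
      inside <- vapply(gap_pos, function(g) {
        any(ann$repeats$start <= g & g < ann$repeats$end)
      }, logical(1))
      if (length(gap_pos) && !all(inside)) reason <- "gap_outside_repeats"
    }
    tibble(id = id, sequence = candidates$sequence[k],
           n_repeats = ann$n_repeats, reason = reason)
  }) |> bind_rows()
  list(
    kept = rows |> filter(is.na(.data$reason)) |>
      select("id", "sequence", "n_repeats"),
    rejected = rows |> filter(!is.na(.data$reason)) |>
      select("id", "reason")
  )
}

#' Pairwise similarity and distance matrices
#'
#' Global alignment for every pair; similarity is the fraction of
#' positive-scoring (BLOSUM62) aligned pairs over the alignment length,
#' identity the fraction of identical pairs; distance is `1 - identity`.
#'
#' @param seqs Named character vector.
#' @return Object of class `seq_distance`: list with `distance` and
#'   `similarity` matrices (taxa x taxa; similarity in percent).
#' @export
similarity_matrix <- function(seqs) {
  n <- length(seqs)
  ids <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sim <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      g <- global_identity(seqs[[i]], seqs[[j]])
      d[i, j] <- d[j, i] <- 1 - g$identity
      sim[i, j] <- sim[j, i] <- 100 * g$similarity
    }
  }
  structure(list(distance = d, similarity = sim), class = "seq_distance")
}

#' @export
print.seq_distance <- function(x, ...) {
  cat(sprintf("<seq_distance> %d taxa, mean similarity %.1f%%\n",
              nrow(x$distance), mean(x$similarity[upper.tri(x$similarity)])))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Saitou-Nei Q criterion) via `ape::nj()`;
#' negative branch lengths are clamped to zero with a warning.
#'
#' @param d A `seq_distance` object or a symmetric distance matrix.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- if (inherits(d, "seq_distance")) d$distance else as.matrix(d)
  if (nrow(m) == 2) {
    # two taxa: the tree is the single edge of length d(A,B)
    tree <- structure(list(
      edge = matrix(c(3L, 3L, 1L, 2L), 2),
      edge.length = rep(m[1, 2] / 2, 2),
      tip.label = rownames(m), Nnode = 1L), class = "phylo")
    return(tree)
  }
  tree <- ape::nj(m)
  if (any(tree$edge.length < 0)) {
    warn(sprintf("%d negative NJ branch length(s) clamped to 0",
                 sum(tree$edge.length < 0)))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Extract the minimal rooted clade containing all seed taxa
#'
#' Roots the tree at `outgroup`, then returns the MRCA subtree of the
#' seeds.
#'
#' @param tree An `ape::phylo`.
#' @param outgroup Taxon used to root the tree.
#' @param seeds Character vector of seed taxa.
#' @return Object of class `receptor_clade`: list with `tips` (leaf labels
#'   of the clade) and `tree` (the clade as `phylo`, or `NULL` for a
#'   single-leaf clade).
#' @export
extract_clade <- function(tree, outgroup, seeds) {
  stopifnot(outgroup %in% tree$tip.label)
  missing <- setdiff(seeds, tree$tip.label)
  if (length(missing))
    abort(sprintf("seed taxa not in tree: %s", paste(missing, collapse = ", ")))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  seeds <- unique(seeds)
  if (length(seeds) == 1)
    return(structure(list(tips = seeds, tree = NULL),
                     class = "receptor_clade"))
  node <- ape::getMRCA(rooted, seeds)
  sub <- ape::extract.clade(rooted, node)
  structure(list(tips = sub$tip.label, tree = sub), class = "receptor_clade")
}

#' @export
print.receptor_clade <- function(x, ...) {
  cat(sprintf("<receptor_clade> %d tips: %s\n", length(x$tips),
              paste(head(x$tips, 8), collapse = ", ")))
  invisible(x)
}
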