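# Peptide precursor catalog: single-linkage clustering on local-alignment
# identity, center-star cluster alignments, position-specific scoring
# profiles (an explicit simplified stand-in for profile HMMs), proteome
# scanning, mature-window extraction and motif statistics.

#' Cluster precursor records by local-alignment identity
#'
#' Builds the graph whose edges join pairs with local-alignment identity
#' (matches / alignment length) at least `identity_min` and alignment
#' coverage (alignment length / shorter sequence) at least `coverage_min`,
#' and returns its single-linkage connected components. Clusters are
#' numbered deterministically by their smallest member id.
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param identity_min Minimum local identity for an edge (default 0.45).
#' @param coverage_min Minimum coverage of the shorter sequence (default
#'   0.5); guards against spurious high-identity micro-alignments between
#'   unrelated sequences.
#' @return Tibble with columns `id` and `cluster` (integer).
#' @export
cluster_precursors <- function(records, identity_min = 0.45,
                               coverage_min = 0.5) {
  if (nrow(records) == 0)
    return(tibble(id = character(), cluster = integer()))
  ids <- records$id
  seqs <- setNames(records$sequence, ids)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1 && identity_min <= 1) {
    for (j in 2:n) {
      ii <- 1:(j - 1)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(seqs[ii]), Biostrings::AAString(seqs[[j]]),
        type = "local", substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1)
      len <- Biostrings::nchar(pa)
      idn <- ifelse(len > 0, Biostrings::nmatch(pa) / len, 0)
      cov <- len / pmin(nchar(seqs[ii]), nchar(seqs[[j]]))
      for (i in ii[idn >= identity_min & cov >= coverage_min]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # number clusters by smallest member id
  key <- tapply(ids, comp, min)
  ord <- names(sort(key))
  tibble(id = ids, cluster = match(as.character(comp), ord))
}

#' Align the members of one cluster
#'
#' Center-star multiple alignment (see [center_star_align()]).
#'
#' @param seqs Named character vector of member sequences.
#' @return Named character vector of gapped rows.
#' @export
align_cluster <- function(seqs) center_star_align(seqs)

#' Build a position-specific scoring profile from an alignment
#'
#' Position frequencies are `(counts + alpha * background) / (n + alpha)`
#' over non-gap residues; log-odds are `log2(freq / background)` in bits.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @param alpha Pseudocount weight (default 1, Laplace scaled by the
#'   background).
#' @param background Named numeric over [aa_alphabet()]; default uniform.
#' @return Object of class `peptide_profile`: `length`, `log_odds`
#'   (position x residue, bits), `freq`, `background`, `alpha`,
#'   `consensus`.
#' @export
build_profile <- function(alignment, alpha = 1,
                          background = setNames(rep(1 / 20, 20), aa_alphabet())) {
  if (length(alignment) == 0) abort("empty alignment.")
  chars <- lapply(alignment, seq_to_chars)
  L <- unique(lengths(chars))
  if (length(L) != 1) abort("alignment rows differ in length.")
  m <- do.call(rbind, chars)
  aa <- aa_alphabet()
  freq <- matrix(NA_real_, L, 20, dimnames = list(NULL, aa))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% aa]
    if (length(col) == 0)
      abort(sprintf("column %d contains only gaps; cannot build profile.", j))
    counts <- table(factor(col, levels = aa))
    freq[j, ] <- (as.numeric(counts) + alpha * background[aa]) /
      (length(col) + alpha)
  }
  log_odds <- log2(sweep(freq, 2, background[aa], "/"))
  structure(list(length = L, log_odds = log_odds, freq = freq,
                 background = background, alpha = alpha,
                 consensus = paste(aa[apply(log_odds, 1, which.max)],
                                   collapse = "")),
            class = "peptide_profile")
}

#' @export
print.peptide_profile <- function(x, ...) {
  cat(sprintf("<peptide_profile> length %d, alpha %g, consensus %s\n",
              x$length, x$alpha, x$consensus))
  invisible(x)
}

score_windows <- function(profile, sequence) {
  L <- profile$length
  n <- nchar(sequence)
  if (n < L) return(numeric(0))
  idx <- match(seq_to_chars(sequence), aa_alphabet())
  lo <- profile$log_odds
  vapply(seq_len(n - L + 1), function(o) {
    w <- idx[o:(o + L - 1)]
    ok <- !is.na(w)  # unknown residues (X) score 0
    sum(lo[cbind(which(ok), w[ok])])
  }, numeric(1))
}

#' Scan a proteome with a scoring profile
#'
#' Sliding-window log-odds sum at every offset of every protein; hits with
#' score at least `bitscore_min`, sorted by score descending then (id,
#' offset). Unknown residues (X) contribute zero.
#'
#' @param profile A [build_profile()] object.
#' @param proteome Named character vector of protein sequences.
#' @param bitscore_min Minimum window score in bits.
#' @return Tibble with columns `id`, `offset` (1-based), `score`.
#' @export
scan_proteome <- function(profile, proteome, bitscore_min = 0) {
  hits <- purrr::imap(proteome, function(s, nm) {
    sc <- score_windows(profile, s)
    if (!length(sc)) return(NULL)
    keep <- which(sc >= bitscore_min)
    if (!length(keep)) return(NULL)
    tibble(id = nm, offset = keep, score = sc[keep])
  }) |> bind_rows()
  if (nrow(hits) == 0)
    return(tibble(id = character(), offset = integer(), score = numeric()))
  hits |> arrange(dplyr::desc(.data$score), .data$id, .data$offset)
}

#' Extract the mature peptide window from a precursor
#'
#' Returns the window of the profile's length maximizing the profile score
#' (ties broken by the smallest offset) and annotates which configured
#' motif positions the window satisfies.
#'
#' @param sequence Precursor protein sequence.
#' @param profile A [build_profile()] object; its length is the mature
#'   length (13 by default presets, 15 via a longer profile).
#' @param motif Named integer vector as in [sim_config()].
#' @param parent_id Identifier copied into the result.
#' @return One-row tibble: `parent_id`, `sequence`, `offset`, `length`,
#'   `motif_ok`, `motif_positions` (list column of satisfied positions).
#' @export
extract_mature_peptide <- function(sequence, profile,
                                   motif = c(S = 5L, S = 7L),
                                   parent_id = NA_character_) {
  if (nchar(sequence) < profile$length)
    abort(sprintf("precursor (%d aa) shorter than the mature window (%d aa).",
                  nchar(sequence), profile$length))
  sc <- score_windows(profile, sequence)
  o <- which.max(sc)  # which.max returns the first (smallest) offset on ties
  win <- substr(sequence, o, o + profile$length - 1)
  wc <- seq_to_chars(win)
  ok <- wc[unname(motif)] == names(motif)
  tibble(parent_id = parent_id, sequence = win, offset = as.integer(o),
         length = profile$length, motif_ok = all(ok),
         motif_positions = list(unname(motif)[ok]))
}

#' Motif statistics over a set of mature peptides
#'
#' Per-position residue frequencies (with `alpha` pseudocount), information
#' content `IC_j = log2(20) - H_j` in bits, and the fractions of peptides
#' carrying the SxS (serine at both motif positions) and SxT (serine then
#' threonine) motifs.
#'
#' @param peptides Character vector of equal-length mature peptides.
#' @param motif_positions Integer pair, default `c(5, 7)`.
#' @param alpha Pseudocount weight (default 0: plain observed frequencies).
#' @return Object of class `motif_summary`: `freq` (position x residue),
#'   `ic` (bits), `fraction_sxs`, `fraction_sxt`, `n`.
#' @export
motif_statistics <- function(peptides, motif_positions = c(5L, 7L),
                             alpha = 0) {
  if (length(peptides) == 0) abort("no peptides supplied.")
  L <- unique(nchar(peptides))
  if (length(L) != 1) abort("peptides must share one length.")
  prof <- build_profile(setNames(peptides, seq_along(peptides)),
                        alpha = alpha)
  h <- apply(prof$freq, 1, function(p) -sum(ifelse(p > 0, p * log2(p), 0)))
  chars <- do.call(rbind, lapply(peptides, seq_to_chars))
  p1 <- chars[, motif_positions[1]]
  p2 <- chars[, motif_positions[2]]
  structure(list(freq = prof$freq, ic = log2(20) - h,
                 fraction_sxs = mean(p1 == "S" & p2 == "S"),
                 fraction_sxt = mean(p1 == "S" & p2 == "T"),
                 n = length(peptides)),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat(sprintf("<motif_summary> n=%d | SxS %.2f, SxT %.2f | mean IC %.2f bits\n",
              x$n, x$fraction_sxs, x$fraction_sxt, mean(x$ic)))
  invisible(x)
}
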