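# Pairwise alignment helpers shared by locus linking, clustering and
# receptor similarity, plus the center-star multiple aligner used for
# peptide clusters.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

pw_align <- function(a, b, type = c("local", "global"),
                     gap_open = 11, gap_ext = 1) {
  type <- match.arg(type)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = if (type == "local") "local" else "global",
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = FALSE)
}

aligned_strings <- function(pa) {
  c(pattern = as.character(Biostrings::alignedPattern(pa)),
    subject = as.character(Biostrings::alignedSubject(pa)))
}

# Karlin-Altschul statistics for gapped BLOSUM62 (gap open 11 / extend 1),
# the standard protein-search parameterisation. Search space is m*n of the
# two sequences; exact parity with any BLAST release is not a goal.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Bit score and E-value for a local alignment raw score
#'
#' @param raw Raw BLOSUM62 local-alignment score.
#' @param m,n Lengths of the two sequences.
#' @return `bit_score()` a bit score; `ka_evalue()` an E-value (>= 0).
#' @export
bit_score <- function(raw) (KA_LAMBDA * raw - log(KA_K)) / log(2)

#' @rdname bit_score
#' @export
ka_evalue <- function(raw, m, n) m * n * 2^(-bit_score(raw))

# Local-alignment identity and coverage between two sequences: identity is
# matches / alignment length over the optimal local alignment; coverage is
# alignment length / length of the shorter sequence.
local_identity <- function(a, b) {
  pa <- pw_align(a, b, "local")
  s <- aligned_strings(pa)
  x <- seq_to_chars(s[["pattern"]]); y <- seq_to_chars(s[["subject"]])
  len <- length(x)
  if (len == 0) return(list(identity = 0, coverage = 0))
  list(identity = sum(x == y & x != "-") / len,
       coverage = len / min(nchar(a), nchar(b)))
}

# Global-alignment identity and BLOSUM-positive similarity (positive-scoring
# aligned pairs / alignment length).
global_identity <- function(a, b) {
  pa <- pw_align(a, b, "global")
  s <- aligned_strings(pa)
  x <- seq_to_chars(s[["pattern"]]); y <- seq_to_chars(s[["subject"]])
  len <- length(x)
  sub <- blosum62()
  ok <- x != "-" & y != "-"
  pos <- sum(ok & sub[cbind(match(x, rownames(sub)),
                            match(y, colnames(sub)))] > 0, na.rm = TRUE)
  list(identity = sum(x == y & ok) / len, similarity = pos / len,
       length = len)
}

#' Center-star multiple alignment
#'
#' Aligns a set of sequences by choosing the center sequence maximizing the
#' summed pairwise global alignment score against all others (ties broken
#' by name order), then merging each optimal center-sequence pairwise
#' alignment into a growing master alignment ("once a gap, always a gap").
#' Deterministic for fixed input order by name.
#'
#' @param seqs Named character vector (>= 1 sequence).
#' @return Named character vector of equal-length gapped rows.
#' @export
center_star_align <- function(seqs) {
  if (length(seqs) == 0) abort("cannot align an empty set of sequences.")
  seqs <- seqs[order(names(seqs))]
  if (length(seqs) == 1) return(seqs)
  n <- length(seqs)
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    score[i, j] <- score[j, i] <- s
  }
  center <- which.max(rowSums(score))

  # master state: rows = aligned strings; map = center residue index per
  # master column (NA for columns where the center has a gap)
  rows <- list()
  rows[[names(seqs)[center]]] <- seq_to_chars(seqs[[center]])
  map <- seq_len(nchar(seqs[[center]]))

  for (k in setdiff(seq_len(n), center)) {
    pa <- pw_align(seqs[[center]], seqs[[k]], "global")
    s <- aligned_strings(pa)
    c_aln <- seq_to_chars(s[["pattern"]]); k_aln <- seq_to_chars(s[["subject"]])
    pair_map <- cumsum(c_aln != "-")
    pair_map[c_aln == "-"] <- NA

    new_rows <- lapply(rows, function(r) character(0))
    new_krow <- character(0)
    new_map <- integer(0)
    i <- 1L; j <- 1L
    while (i <= length(map) || j <= length(pair_map)) {
      mi <- if (i <= length(map)) map[i] else NA
      pj <- if (j <= length(pair_map)) pair_map[j] else NA
      if (i <= length(map) && j <= length(pair_map) &&
          !is.na(mi) && !is.na(pj) && mi == pj) {
        for (nm in names(rows)) new_rows[[nm]] <- c(new_rows[[nm]], rows[[nm]][i])
        new_krow <- c(new_krow, k_aln[j])
        new_map <- c(new_map, mi)
        i <- i + 1L; j <- j + 1L
      } else if (i <= length(map) && is.na(mi)) {
        for (nm in names(rows)) new_rows[[nm]] <- c(new_rows[[nm]], rows[[nm]][i])
        new_krow <- c(new_krow, "-")
        new_map <- c(new_map, NA)
        i <- i + 1L
      } else {
        for (nm in names(rows)) new_rows[[nm]] <- c(new_rows[[nm]], "-")
        new_krow <- c(new_krow, k_aln[j])
        new_map <- c(new_map, NA)
        j <- j + 1L
      }
    }
    rows <- new_rows
    rows[[names(seqs)[k]]] <- new_krow
    map <- new_map
  }
  out <- vapply(rows, chars_to_seq, character(1))
  out[names(seqs)]
}
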