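# Repeat Conservation Mapping: project per-column alignment conservation
# onto the repeat x solvent-exposed-position grid and smooth it with a
# center-weighted regional window.

#' Build the LRR grid mapping cells to alignment columns
#'
#' For each repeat of the reference receptor, the configured
#' solvent-exposed offsets within the repeat unit become grid cells, each
#' mapped to its alignment column via the (gap-free inside repeats)
#' reference row.
#'
#' @param alignment Named character vector of gapped rows including the
#'   reference.
#' @param annotation [detect_lrr_repeats()] result for the ungapped
#'   reference sequence.
#' @param reference Name of the reference row.
#' @param exposed_offsets 1-based offsets within the repeat unit treated as
#'   solvent exposed; default the variable strand/ascent positions of
#'   [lrr_unit()].
#' @return Object of class `lrr_grid`: tibble with columns `rep`, `pos`
#'   (exposed-position index), `offset`, `residue` (1-based reference
#'   numbering), `column` (alignment column); attributes `n_rep`, `n_pos`,
#'   `reference`.
#' @export
build_lrr_grid <- function(alignment, annotation, reference,
                           exposed_offsets = lrr_unit()$exposed_offsets) {
  if (length(exposed_offsets) == 0)
    abort("`exposed_offsets` must name at least one position per repeat.")
  if (!reference %in% names(alignment))
    abort(sprintf("reference '%s' not found in alignment.", reference))
  row <- seq_to_chars(alignment[[reference]])
  col_of_res <- which(row != "-")
  reps <- annotation$repeats
  cells <- purrr::map(seq_len(nrow(reps)), function(r) {
    len <- reps$end[r] - reps$start[r] + 1L
    if (max(exposed_offsets) > len)
      abort(sprintf("repeat %d (%d residues) shorter than offset %d",
                    r, len, max(exposed_offsets)))
    residue <- reps$start[r] + exposed_offsets - 1L
    tibble(rep = r, pos = seq_along(exposed_offsets),
           offset = as.integer(exposed_offsets), residue = residue,
           column = col_of_res[residue])
  }) |> bind_rows()
  structure(cells, class = c("lrr_grid", class(cells)),
            n_rep = nrow(reps), n_pos = length(exposed_offsets),
            reference = reference)
}

#' Per-column conservation score
#'
#' `method = "entropy"` (default): one minus the normalized Shannon entropy
#' of the alpha-pseudocounted residue frequencies, in `[0, 1]`. Gaps are
#' excluded from the counts; the gap fraction is returned as an attribute.
#' `method = "blosum"`: fraction of residue pairs in the column with a
#' positive BLOSUM62 score (a substitution-matrix mean-pairwise-similarity
#' alternative).
#'
#' @param column Character vector of residues (one per row of the
#'   alignment), possibly with `"-"` gaps.
#' @param alpha Pseudocount weight (default 0).
#' @param method Conservation statistic.
#' @return Numeric scalar in `[0, 1]` with attribute `gap_fraction`.
#' @export
column_conservation <- function(column, alpha = 0,
                                method = c("entropy", "blosum")) {
  method <- match.arg(method)
  gap_fraction <- mean(!column %in% aa_alphabet())
  col <- column[column %in% aa_alphabet()]
  if (length(col) == 0)
    abort("column contains no residues (all gaps).")
  score <- if (method == "entropy") {
    aa <- aa_alphabet()
    counts <- as.numeric(table(factor(col, levels = aa)))
    p <- (counts + alpha / 20) / (length(col) + alpha)
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    1 - h / log2(20)
  } else {
    if (length(col) == 1) 1 else {
      sub <- blosum62()
      pr <- outer(col, col, function(a, b)
        sub[cbind(match(a, rownames(sub)), match(b, colnames(sub)))] > 0)
      mean(pr[upper.tri(pr)])
    }
  }
  structure(score, gap_fraction = gap_fraction)
}

# default center-weighted kernel: weight 1/(1 + Chebyshev distance)
chebyshev_kernel <- function(d) 1 / (1 + d)

#' Center-weighted regional conservation scores
#'
#' Each cell becomes the weighted mean of the raw scores over the
#' `window x window` neighborhood centered on it; the default kernel
#' weights a neighbor by `1 / (1 + Chebyshev distance)` (center 1, first
#' ring 1/2, second ring 1/3). At grid edges the window truncates and the
#' weights renormalize over the present cells, so edge scores remain means
#' of real data.
#'
#' @param raw Numeric matrix of per-cell conservation (repeats x positions).
#' @param window Odd window size (default 5).
#' @param kernel Function of Chebyshev distance returning a non-negative
#'   weight.
#' @return Matrix of regional scores, same shape as `raw`.
#' @export
regional_score <- function(raw, window = 5L, kernel = chebyshev_kernel) {
  if (window %% 2 != 1) abort("`window` must be odd.")
  h <- window %/% 2
  nr <- nrow(raw); nc <- ncol(raw)
  out <- raw
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - h):min(nr, i + h)
    jj <- max(1, j - h):min(nc, j + h)
    w <- kernel(outer(abs(ii - i), abs(jj - j), pmax))
    out[i, j] <- sum(w * raw[ii, jj, drop = FALSE]) / sum(w)
  }
  out
}

#' Repeat conservation map of a homologue alignment
#'
#' Computes the raw per-cell conservation (via [column_conservation()]) for
#' every grid cell and smooths it with [regional_score()].
#'
#' @param alignment Named character vector of gapped rows.
#' @param grid [build_lrr_grid()] result.
#' @param alpha,method Passed to [column_conservation()].
#' @param window,kernel Passed to [regional_score()].
#' @return Object of class `rcm_map`: list with `regional` and `raw`
#'   matrices (repeats x positions), `gap_fraction` matrix, `window`,
#'   `grid`.
#' @export
rcm_map <- function(alignment, grid, alpha = 0, method = "entropy",
                    window = 5L, kernel = chebyshev_kernel) {
  rows <- do.call(rbind, lapply(alignment, seq_to_chars))
  n_rep <- attr(grid, "n_rep"); n_pos <- attr(grid, "n_pos")
  raw <- matrix(NA_real_, n_rep, n_pos)
  gapf <- matrix(NA_real_, n_rep, n_pos)
  for (k in seq_len(nrow(grid))) {
    sc <- column_conservation(rows[, grid$column[k]], alpha = alpha,
                              method = method)
    raw[grid$rep[k], grid$pos[k]] <- as.numeric(sc)
    gapf[grid$rep[k], grid$pos[k]] <- attr(sc, "gap_fraction")
  }
  structure(list(regional = regional_score(raw, window, kernel), raw = raw,
                 gap_fraction = gapf, window = window, grid = grid),
            class = "rcm_map")
}

#' @export
print.rcm_map <- function(x, ...) {
  cat(sprintf("<rcm_map> %d repeats x %d positions, window %d, regional range [%.3f, %.3f]\n",
              nrow(x$regional), ncol(x$regional), x$window,
              min(x$regional), max(x$regional)))
  invisible(x)
}

#' Call conserved regions from a regional conservation map
#'
#' Cells whose regional score is at least the `q`-quantile of the map;
#' contiguity is not required.
#'
#' @param map An [rcm_map()] result (or a numeric matrix of regional
#'   scores).
#' @param q Quantile threshold in `[0, 1]` (default 0.8).
#' @return Tibble `rep`, `pos`, `score`.
#' @export
conserved_regions <- function(map, q = 0.8) {
  m <- if (inherits(map, "rcm_map")) map$regional else map
  thr <- quantile(m, q, na.rm = TRUE)
  idx <- which(m >= thr, arr.ind = TRUE)
  tibble(rep = idx[, 1], pos = idx[, 2], score = m[idx]) |>
    arrange(.data$rep, .data$pos)
}
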