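# Synteny-anchored locus extraction and cross-species similarity links.

#' Extract an anchor-flanked locus window from a gene table
#'
#' Returns the anchors plus all genes within `window` genes on each side of
#' the anchor block (count-based window on the anchors' contig), preserving
#' coordinate order. Coordinates are 0-based half-open; member order is by
#' ascending start regardless of strand.
#'
#' @param table One-species gene table (columns `gene_id`, `contig`,
#'   `start`, `end`, `strand`, `species`).
#' @param anchors Character vector of anchor gene ids present in `table`.
#' @param window Genes kept on each side of the anchor block (default 10).
#' @return Object of class `gene_locus`: tibble of members with attributes
#'   `anchors`, `species`, `window`.
#' @export
extract_locus_window <- function(table, anchors, window = 10L) {
  species <- unique(table$species)
  if (length(species) != 1)
    abort("`table` must contain a single species; split multi-species tables first.")
  missing <- setdiff(anchors, table$gene_id)
  if (length(missing))
    abort(sprintf("anchor(s) %s not found in species %s",
                  paste(missing, collapse = ", "), species))
  contigs <- unique(table$contig[table$gene_id %in% anchors])
  if (length(contigs) != 1)
    abort(sprintf("anchors of species %s lie on different contigs (%s)",
                  species, paste(contigs, collapse = ", ")))
  genes <- table |> filter(.data$contig == contigs) |> arrange(.data$start)
  idx <- which(genes$gene_id %in% anchors)
  lo <- max(1L, min(idx) - window)
  hi <- min(nrow(genes), max(idx) + window)
  members <- genes[lo:hi, ]
  structure(members, class = c("gene_locus", class(members)),
            anchors = anchors, species = species, window = window)
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s: %d members, anchors %s\n",
              attr(x, "species"), nrow(x),
              paste(attr(x, "anchors"), collapse = ", ")))
  NextMethod()
}

#' Similarity links between two loci
#'
#' All-vs-all local alignment (BLOSUM62, affine gaps) between the member
#' proteins of two loci; E-values follow Karlin-Altschul statistics on the
#' pairwise search space. Links with `evalue < evalue_max` (strictly less)
#' are returned. Pairs without a protein sequence are skipped. An empty
#' locus yields an empty link table.
#'
#' @param locus_a,locus_b [extract_locus_window()] results (or tibbles with
#'   a `gene_id` column).
#' @param proteins Named character vector keyed by gene id.
#' @param evalue_max E-value threshold, default `1e-6`.
#' @return Tibble `gene_a`, `gene_b`, `score` (bits), `evalue`.
#' @export
link_loci <- function(locus_a, locus_b, proteins, evalue_max = 1e-6) {
  empty <- tibble(gene_a = character(), gene_b = character(),
                  score = numeric(), evalue = numeric())
  ids_a <- intersect(locus_a$gene_id, names(proteins))
  ids_b <- intersect(locus_b$gene_id, names(proteins))
  if (!length(ids_a) || !length(ids_b)) return(empty)
  links <- purrr::map(ids_a, function(a) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins[ids_b]),
      Biostrings::AAString(proteins[[a]]),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    tibble(gene_a = a, gene_b = ids_b,
           score = bit_score(pa),
           evalue = ka_evalue(pa, nchar(proteins[[a]]),
                              nchar(proteins[ids_b])))
  }) |> bind_rows()
  links |> filter(.data$evalue < evalue_max) |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Candidate genes by transitive closure over locus links
#'
#' Starting from the seed genes, follows similarity links transitively,
#' restricted to locus members, and annotates each candidate with its
#' species and locus of origin. Independent of locus processing order.
#'
#' @param loci List of [extract_locus_window()] results.
#' @param links Tibble of links (rows with `gene_a`, `gene_b`), e.g. rows
#'   combined from [link_loci()] over locus pairs.
#' @param seed_ids Character vector of seed gene ids.
#' @return Tibble `gene_id`, `species`, `locus` (index into `loci`),
#'   `seed` (logical).
#' @export
candidate_genes <- function(loci, links, seed_ids) {
  membership <- purrr::imap(loci, function(l, i) {
    tibble(gene_id = l$gene_id, species = attr(l, "species"), locus = i)
  }) |> bind_rows() |> distinct(.data$gene_id, .keep_all = TRUE)
  adj <- list()
  if (nrow(links)) {
    for (k in seq_len(nrow(links))) {
      a <- links$gene_a[k]; b <- links$gene_b[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- unique(seed_ids)
  queue <- seen
  while (length(queue)) {
    nb <- unique(unlist(adj[queue], use.names = FALSE))
    nb <- setdiff(intersect(nb, membership$gene_id), seen)
    seen <- c(seen, nb)
    queue <- nb
  }
  membership |> filter(.data$gene_id %in% seen) |>
    mutate(seed = .data$gene_id %in% seed_ids) |>
    arrange(.data$gene_id)
}
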