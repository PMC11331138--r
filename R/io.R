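# File-format adapters. Sequences travel as named character vectors inside
# the package; Biostrings handles FASTA, rtracklayer-free TSV/GFF3 readers
# cover gene tables.

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's named-character
#' sequence convention.
#'
#' @param file Path.
#' @param seqs Named character vector of protein sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, file) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), file)
  invisible(file)
}

#' Read and write gene tables
#'
#' The package's TSV dialect has columns
#' `gene_id contig start end strand species` with 0-based half-open
#' coordinates. `read_gene_gff3()` converts GFF3 gene records (1-based
#' inclusive) to the same internal convention.
#'
#' @param file Path.
#' @param table Gene-table tibble.
#' @param species Species label to attach to GFF3 records.
#' @param feature GFF3 feature type to keep.
#' @return A tibble in the internal convention.
#' @export
read_gene_table <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "start", "end", "strand", "species")
  if (!all(need %in% names(x)))
    abort(sprintf("gene table must have columns: %s",
                  paste(need, collapse = " ")))
  as_tibble(x[, need]) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

#' @rdname read_gene_table
#' @export
write_gene_table <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname read_gene_table
#' @export
read_gene_gff3 <- function(file, species, feature = "gene") {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1)) == 9L]
  m <- do.call(rbind, f)
  keep <- m[, 3] == feature
  m <- m[keep, , drop = FALSE]
  attr9 <- m[, 9]
  id <- sub(".*ID=([^;]+).*", "\\1", attr9)
  tibble(
    gene_id = id, contig = m[, 1],
    # GFF3 is 1-based inclusive; internal convention is 0-based half-open
    start = as.integer(m[, 4]) - 1L, end = as.integer(m[, 5]),
    strand = m[, 7], species = species
  )
}
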