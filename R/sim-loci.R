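# Simulated multi-species gene tables: a conserved anchor-flanked locus with
# inserted candidate genes, decoy genes elsewhere, and per-gene proteins.

#' Simulate per-species gene tables with a conserved anchor-flanked locus
#'
#' Each species receives one contig on which, in order: `cfg$n_decoys`
#' decoy genes, anchor A, `n_candidates` inserted candidate genes, anchor B,
#' and `cfg$n_decoys` more decoys. Anchor and candidate proteins are
#' orthologous across species (mutated at `cfg$divergence` per site from a
#' shared core); decoy proteins are independent random sequences.
#' Coordinates are 0-based half-open; strands are random except that
#' orthologues keep their strand.
#'
#' @param cfg A [sim_config()].
#' @param n_candidates Candidate genes inserted between the anchors.
#' @return Object of class `gene_tables_sim`: `tables` (tibble `gene_id`,
#'   `contig`, `start`, `end`, `strand`, `species`), `proteins` (named
#'   character), `truth` (anchor ids and planted candidate ids per species).
#' @export
generate_gene_tables <- function(cfg = sim_config(), n_candidates = 2L) {
  validate_sim_config(cfg)
  mutate_protein <- function(core, p) {
    s <- seq_to_chars(core)
    mut <- which(runif(length(s)) < p)
    for (i in mut) {
      pool <- aa_composition()
      pool <- pool[names(pool) != s[i]]
      s[i] <- sample(names(pool), 1L, prob = pool)
    }
    chars_to_seq(s)
  }

  with_seed(derive_seed(cfg$seed, 401L), {
    anchor_cores <- c(A = random_aa(180), B = random_aa(160))
    cand_cores <- vapply(seq_len(n_candidates), function(i) random_aa(200),
                         character(1))
    strands <- list(anchor = sample(c("+", "-"), 2, replace = TRUE),
                    cand = sample(c("+", "-"), n_candidates, replace = TRUE))

    out <- purrr::map(seq_len(cfg$n_species), function(sp) {
      species <- sprintf("sp%02d", sp)
      ids <- c(sprintf("%s_d%02d", species, seq_len(cfg$n_decoys)),
               sprintf("%s_anchorA", species),
               sprintf("%s_cand%02d", species, seq_len(n_candidates)),
               sprintf("%s_anchorB", species),
               sprintf("%s_d%02d", species,
                       cfg$n_decoys + seq_len(cfg$n_decoys)))
      n <- length(ids)
      prot <- character(n)
      strand <- character(n)
      role <- c(rep("decoy", cfg$n_decoys), "anchor",
                rep("cand", n_candidates), "anchor", rep("decoy", cfg$n_decoys))
      ai <- 0L; ci <- 0L
      for (k in seq_len(n)) {
        if (role[k] == "anchor") {
          ai <- ai + 1L
          prot[k] <- mutate_protein(anchor_cores[ai], cfg$divergence)
          strand[k] <- strands$anchor[ai]
        } else if (role[k] == "cand") {
          ci <- ci + 1L
          prot[k] <- mutate_protein(cand_cores[ci], cfg$divergence)
          strand[k] <- strands$cand[ci]
        } else {
          prot[k] <- random_aa(sample(120:250, 1L))
          strand[k] <- sample(c("+", "-"), 1L)
        }
      }
      glen <- nchar(prot) * 3L + 3L
      gaps <- sample(200:2000, n, replace = TRUE)
      start <- cumsum(gaps) + c(0L, cumsum(glen)[-n])
      tibble(gene_id = ids, contig = "chr1", start = start,
             end = start + glen, strand = strand, species = species,
             role = role, protein = prot)
    }) |> bind_rows()
  })

  truth <- list(
    anchors = out |> filter(.data$role == "anchor") |>
      select("gene_id", "species"),
    planted_members = out |> filter(.data$role == "cand") |>
      select("gene_id", "species")
  )
  structure(list(
    tables = out |> select("gene_id", "contig", "start", "end", "strand",
                           "species"),
    proteins = setNames(out$protein, out$gene_id),
    truth = truth, cfg = cfg
  ), class = "gene_tables_sim")
}

#' @export
print.gene_tables_sim <- function(x, ...) {
  cat(sprintf("<gene_tables_sim> %d genes across %d species\n",
              nrow(x$tables), length(unique(x$tables$species))))
  invisible(x)
}
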