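# Simulated peptide precursor families: clusters of homologous precursors
# sharing a short fixed-position serine motif inside an otherwise divergent
# mature window, plus unrelated decoy proteins.

#' Simulate peptide precursor families
#'
#' Each of `cfg$n_clusters` families has a cluster-specific precursor core:
#' an N-terminal propeptide (25-40 residues), a mature window of
#' `cfg$mature_length` residues carrying the motif at its fixed positions,
#' and a short C-terminal tail. One precursor per species is emitted by
#' mutating every non-motif position independently with probability
#' `cfg$divergence`; motif positions are held fixed, so every emitted mature
#' window satisfies the motif by construction. A minority of clusters (every
#' fifth) carry the SxT variant: threonine replaces serine at the last motif
#' position. `cfg$n_decoys` unrelated random proteins are emitted alongside.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `precursor_set_sim`: `records` (tibble with
#'   `id`, `species`, `cluster`, `sequence`), `decoys` (tibble `id`,
#'   `sequence`), and `truth` (per-record mature offset, motif positions,
#'   cluster membership).
#' @export
generate_precursor_set <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  if (max(cfg$motif) > cfg$mature_length)
    abort("motif does not fit inside the mature window.")
  motif_pos <- unname(cfg$motif)
  motif_res <- names(cfg$motif)

  with_seed(derive_seed(cfg$seed, 201L), {
    recs <- purrr::map(seq_len(cfg$n_clusters), function(cl) {
      res <- motif_res
      if (cl %% 5L == 0L) res[length(res)] <- "T"  # SxT minority clusters
      pro_len <- sample(25:40, 1L)
      tail_len <- sample(10:20, 1L)
      mature <- seq_to_chars(random_aa(cfg$mature_length))
      mature[motif_pos] <- res
      core <- c(seq_to_chars(random_aa(pro_len)), mature,
                seq_to_chars(random_aa(tail_len)))
      fixed_abs <- pro_len + motif_pos  # absolute indices of motif residues
      purrr::map(seq_len(cfg$n_species), function(sp) {
        s <- core
        mut <- which(runif(length(s)) < cfg$divergence)
        mut <- setdiff(mut, fixed_abs)
        for (i in mut) {
          pool <- aa_composition()
          pool <- pool[names(pool) != s[i]]
          s[i] <- sample(names(pool), 1L, prob = pool)
        }
        tibble(
          id = sprintf("c%02d_sp%02d", cl, sp),
          species = sprintf("sp%02d", sp),
          cluster = cl,
          sequence = chars_to_seq(s),
          mature_offset = pro_len + 1L
        )
      }) |> bind_rows()
    }) |> bind_rows()

    decoys <- tibble(
      id = sprintf("decoy%02d", seq_len(cfg$n_decoys)),
      sequence = vapply(seq_len(cfg$n_decoys),
                        function(i) random_aa(sample(50:90, 1L)), character(1))
    )
  })

  truth <- list(
    membership = recs |> select("id", "cluster"),
    mature_offsets = setNames(recs$mature_offset, recs$id),
    motif = cfg$motif,
    decoy_ids = decoys$id
  )
  structure(
    list(records = recs |> select(-"mature_offset"), decoys = decoys,
         truth = truth, cfg = cfg),
    class = "precursor_set_sim")
}

#' @export
print.precursor_set_sim <- function(x, ...) {
  cat(sprintf("<precursor_set_sim> %d records in %d clusters, %d decoys\n",
              nrow(x$records), x$cfg$n_clusters, nrow(x$decoys)))
  invisible(x)
}
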