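# Clustering, profiles, proteome scanning, mature windows and motif stats.

test_that("clustering separates families and respects the threshold", {
  # all identical: one cluster
  recs <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = rep(strrep("ACDEFGHIKLMNPQRSTVWY", 3), 3))
  expect_equal(unique(cluster_precursors(recs)$cluster), 1L)
  # impossible threshold: all singletons
  singl <- cluster_precursors(recs, identity_min = 1.01)
  expect_equal(sort(singl$cluster), 1:3)
  # empty input: empty output
  expect_equal(nrow(cluster_precursors(recs[0, ])), 0L)
  # two tight families, far apart, threshold between
  set.seed(31)
  core1 <- pocketmap:::random_aa(60)
  core2 <- pocketmap:::random_aa(60)
  jiggle <- function(core, k) {
    s <- strsplit(core, "")[[1]]
    idx <- sample(length(s), 6)  # ~90% identity within a family
    s[idx] <- sample(pocketmap::aa_alphabet(), 6, replace = TRUE)
    paste(s, collapse = "")
  }
  recs2 <- tibble::tibble(
    id = c("f1a", "f1b", "f1c", "f2a", "f2b", "f2c"),
    sequence = c(jiggle(core1), jiggle(core1), jiggle(core1),
                 jiggle(core2), jiggle(core2), jiggle(core2)))
  cl <- cluster_precursors(recs2, identity_min = 0.5)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(length(unique(cl$cluster[1:3])), 1L)
  expect_equal(length(unique(cl$cluster[4:6])), 1L)
})

test_that("default preset clustering reproduces the planted partition", {
  ps <- default_precursors()
  recs <- dplyr::bind_rows(ps$records[, c("id", "sequence")], ps$decoys)
  cl <- cluster_precursors(recs)
  joined <- dplyr::inner_join(cl, ps$truth$membership, by = "id")
  tab <- table(joined$cluster.x, joined$cluster.y)
  # one-to-one mapping between inferred and planted clusters
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # decoys stay singletons outside the planted clusters
  decoy_cl <- cl$cluster[cl$id %in% ps$truth$decoy_ids]
  expect_false(any(decoy_cl %in% joined$cluster.x))
  expect_equal(length(unique(decoy_cl)), length(decoy_cl))
})

test_that("center-star alignment matches the pairwise optimum for pairs", {
  # identical members: gap-free
  aln <- align_cluster(c(a = "MKSSTT", b = "MKSSTT"))
  expect_false(any(grepl("-", aln, fixed = TRUE)))
  # two sequences: equals the optimal pairwise global alignment
  s <- c(x = "MKTAYIAKQR", y = "MKTAYQR")
  aln2 <- align_cluster(s)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s[["x"]]), Biostrings::AAString(s[["y"]]),
    type = "global",
    substitutionMatrix = pocketmap:::blosum62(),
    gapOpening = 11, gapExtension = 1)
  expect_identical(unname(aln2["x"]),
                   as.character(Biostrings::alignedPattern(pa)))
  expect_identical(unname(aln2["y"]),
                   as.character(Biostrings::alignedSubject(pa)))
  expect_error(align_cluster(character(0)), "empty")
})

test_that("profile arithmetic follows the pseudocount formula", {
  # single sequence, alpha 0: indicator frequencies, log2(20) at residue
  p1 <- build_profile(c(a = "AC"), alpha = 0)
  expect_equal(unname(p1$freq[1, "A"]), 1)
  expect_equal(unname(p1$log_odds[1, "A"]), log2(20))
  expect_equal(unname(p1$freq[1, "C"]), 0)
  expect_true(is.infinite(p1$log_odds[1, "C"]))
  # column {A:3, G:1}, alpha 1, uniform background: freq(A) = 3.05/5
  p2 <- build_profile(c(s1 = "A", s2 = "A", s3 = "A", s4 = "G"), alpha = 1)
  expect_equal(unname(p2$freq[1, "A"]), (3 + 0.05) / 5)
  expect_equal(unname(p2$freq[1, "G"]), (1 + 0.05) / 5)
  expect_equal(sum(p2$freq[1, ]), 1)
  # all-gap column rejected
  expect_error(build_profile(c(a = "A-C", b = "A-C")), "only gaps")
})

test_that("proteome scanning is optimal at the consensus and monotone", {
  ps <- default_precursors()
  cfg <- ps$cfg
  ids <- ps$truth$membership$id[ps$truth$membership$cluster == 1]
  off <- ps$truth$mature_offsets[ids]
  seqs <- setNames(ps$records$sequence[match(ids, ps$records$id)], ids)
  mats <- setNames(substr(seqs, off, off + cfg$mature_length - 1), ids)
  prof <- build_profile(mats)
  # PSSM optimality: consensus scores at least as high as any mature window
  cons_score <- pocketmap:::score_windows(prof, prof$consensus)
  for (m in mats)
    expect_lte(pocketmap:::score_windows(prof, m), cons_score)
  # consensus embedded in a decoy: maximal score at the embedding offset
  decoy <- paste0(ps$decoys$sequence[1], prof$consensus,
                  ps$decoys$sequence[2])
  hits <- scan_proteome(prof, c(planted = decoy), bitscore_min = 0)
  expect_equal(hits$offset[1], nchar(ps$decoys$sequence[1]) + 1L)
  # raising the threshold never adds hits
  prev <- nrow(hits)
  for (thr in c(5, 15, 30, 60)) {
    n <- nrow(scan_proteome(prof, c(planted = decoy), bitscore_min = thr))
    expect_lte(n, prev)
    prev <- n
  }
  # window longer than the protein: no hits, no error
  expect_equal(nrow(scan_proteome(prof, c(short = "MKT"))), 0L)
})

test_that("planted homologues are recovered with zero decoy hits", {
  ps <- default_precursors()
  cfg <- ps$cfg
  ids <- ps$truth$membership$id[ps$truth$membership$cluster == 1]
  off <- ps$truth$mature_offsets[ids]
  seqs <- setNames(ps$records$sequence[match(ids, ps$records$id)], ids)
  mats <- setNames(substr(seqs, off, off + cfg$mature_length - 1), ids)
  prof <- build_profile(mats)
  proteome <- c(seqs, setNames(ps$decoys$sequence, ps$decoys$id))
  hits <- scan_proteome(prof, proteome, bitscore_min = 0)
  best <- hits |> dplyr::group_by(id) |> dplyr::slice_max(score, n = 1)
  planted_scores <- best$score[best$id %in% ids]
  thr <- min(planted_scores)  # admit all planted homologues
  admitted <- scan_proteome(prof, proteome, bitscore_min = thr)
  expect_true(all(ids %in% admitted$id))
  expect_false(any(ps$decoys$id %in% admitted$id))
})

test_that("mature-window extraction hits the planted window and tie rule", {
  ps <- default_precursors()
  cfg <- ps$cfg
  ids <- ps$truth$membership$id[ps$truth$membership$cluster == 2]
  off <- ps$truth$mature_offsets[ids]
  seqs <- setNames(ps$records$sequence[match(ids, ps$records$id)], ids)
  mats <- setNames(substr(seqs, off, off + cfg$mature_length - 1), ids)
  prof <- build_profile(mats)
  mp <- extract_mature_peptide(seqs[[1]], prof, parent_id = ids[1])
  expect_equal(mp$offset, unname(off[1]))
  expect_equal(mp$length, 13L)
  expect_true(mp$motif_ok)
  # two identical best windows: smallest offset wins
  dup <- paste0("WWW", mats[[1]], "WWWWW", mats[[1]], "WWW")
  mp2 <- extract_mature_peptide(dup, prof)
  expect_equal(mp2$offset, 4L)
  expect_error(extract_mature_peptide("MKT", prof), "shorter")
})

test_that("motif statistics report entropy and motif fractions exactly", {
  # all peptides identical: IC = log2(20) everywhere
  same <- rep("SASASAS", 4)
  ms <- motif_statistics(same, motif_positions = c(1, 3))
  expect_equal(unname(ms$ic), rep(log2(20), 7))
  # one position uniform over the 20 residues: IC 0 there
  varied <- paste0("A", pocketmap::aa_alphabet(), "C")
  ms2 <- motif_statistics(varied, motif_positions = c(1, 3))
  expect_equal(unname(ms2$ic[2]), 0)
  expect_equal(unname(ms2$ic[1]), log2(20))
  # 6 of 8 SxS, 2 SxT at positions 5 and 7
  peps <- c(rep("AAAASASAAAAAA", 6), rep("AAAASATAAAAAA", 2))
  ms3 <- motif_statistics(peps)
  expect_equal(ms3$fraction_sxs, 0.75)
  expect_equal(ms3$fraction_sxt, 0.25)
})
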