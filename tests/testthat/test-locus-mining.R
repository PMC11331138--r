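# Synteny window extraction, similarity links and transitive candidates.

tiny_table <- function() {
  tibble::tibble(
    gene_id = c("g1", "anchorA", "anchorB", "g2", "g3"),
    contig = "chr1",
    start = c(0L, 1000L, 2000L, 3000L, 4000L),
    end = c(500L, 1500L, 2500L, 3500L, 4500L),
    strand = c("+", "-", "-", "+", "+"),
    species = "spX")
}

test_that("window extraction honors the count window and ordering", {
  tab <- tiny_table()
  loc0 <- extract_locus_window(tab, c("anchorA", "anchorB"), window = 0)
  expect_identical(loc0$gene_id, c("anchorA", "anchorB"))
  loc1 <- extract_locus_window(tab, c("anchorA", "anchorB"), window = 1)
  expect_identical(loc1$gene_id, c("g1", "anchorA", "anchorB", "g2"))
  # minus-strand anchors do not change ascending-start order
  expect_true(all(diff(loc1$start) > 0))
  expect_error(extract_locus_window(tab, "nope", window = 1),
               "nope.*spX|spX.*nope")
})

test_that("windows recover planted candidates against simulation truth", {
  gt <- generate_gene_tables(sim_config(seed = 8, n_species = 4),
                             n_candidates = 2)
  for (sp in sprintf("sp%02d", 1:4)) {
    a <- gt$truth$anchors$gene_id[gt$truth$anchors$species == sp]
    loc <- extract_locus_window(dplyr::filter(gt$tables, species == sp),
                                a, window = 5)
    planted <- gt$truth$planted_members$gene_id[
      gt$truth$planted_members$species == sp]
    expect_true(all(planted %in% loc$gene_id))
  }
})

test_that("locus links behave like a calibrated similarity search", {
  gt <- generate_gene_tables(sim_config(seed = 9, n_species = 2),
                             n_candidates = 1)
  mk <- function(sp) {
    a <- gt$truth$anchors$gene_id[gt$truth$anchors$species == sp]
    extract_locus_window(dplyr::filter(gt$tables, species == sp), a,
                         window = 3)
  }
  la <- mk("sp01"); lb <- mk("sp02")
  links <- link_loci(la, lb, gt$proteins)
  # orthologous anchors and candidate link, decoys do not
  expect_setequal(
    paste(links$gene_a, links$gene_b),
    c("sp01_anchorA sp02_anchorA", "sp01_anchorB sp02_anchorB",
      "sp01_cand01 sp02_cand01"))
  expect_true(all(links$evalue < 1e-6))
  # a locus linked to an identical copy of itself: every member links
  proteins2 <- gt$proteins
  names(proteins2) <- paste0(names(proteins2), "_copy")
  lb_copy <- la
  lb_copy$gene_id <- paste0(la$gene_id, "_copy")
  links_self <- link_loci(la, lb_copy, c(gt$proteins, proteins2))
  self <- dplyr::filter(links_self,
                        gene_b == paste0(gene_a, "_copy"))
  expect_equal(nrow(self), nrow(la))
  expect_true(all(self$evalue < 1e-30))
  # shuffled sequences yield no links at the default threshold
  shuf <- vapply(gt$proteins[la$gene_id], function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1))
  names(shuf) <- paste0(la$gene_id, "_shuf")
  lb_shuf <- la
  lb_shuf$gene_id <- names(shuf)
  expect_equal(nrow(link_loci(la, lb_shuf, c(gt$proteins, shuf))), 0L)
})

test_that("links are symmetric and monotone in the E-value threshold", {
  gt <- generate_gene_tables(sim_config(seed = 10, n_species = 2),
                             n_candidates = 1)
  mk <- function(sp) {
    a <- gt$truth$anchors$gene_id[gt$truth$anchors$species == sp]
    extract_locus_window(dplyr::filter(gt$tables, species == sp), a,
                         window = 2)
  }
  la <- mk("sp01"); lb <- mk("sp02")
  ab <- link_loci(la, lb, gt$proteins, evalue_max = 1e-3)
  ba <- link_loci(lb, la, gt$proteins, evalue_max = 1e-3)
  expect_setequal(paste(ab$gene_a, ab$gene_b), paste(ba$gene_b, ba$gene_a))
  # strictness is monotone
  for (e in c(1e-3, 1e-6, 1e-12, 1e-30)) {
    sub <- link_loci(la, lb, gt$proteins, evalue_max = e)
    expect_true(all(paste(sub$gene_a, sub$gene_b) %in%
                      paste(ab$gene_a, ab$gene_b)))
  }
})

test_that("two identical proteins among decoys give exactly one link", {
  set.seed(42)
  prot <- c(p1 = pocketmap:::random_aa(200))
  prot["p2"] <- prot[["p1"]]
  prot["d1"] <- pocketmap:::random_aa(200)
  prot["d2"] <- pocketmap:::random_aa(200)
  mk_loc <- function(ids, sp) {
    tab <- tibble::tibble(gene_id = ids, contig = "c", species = sp,
                          start = seq(0, by = 1000,
                                      length.out = length(ids)),
                          end = seq(600, by = 1000,
                                    length.out = length(ids)),
                          strand = "+")
    extract_locus_window(tab, ids[1], window = 10)
  }
  links <- link_loci(mk_loc(c("p1", "d1"), "s1"),
                     mk_loc(c("p2", "d2"), "s2"), prot)
  expect_equal(nrow(links), 1L)
  expect_equal(links$gene_a, "p1")
  expect_equal(links$gene_b, "p2")
})

test_that("candidate closure is transitive and order independent", {
  loci <- list(
    structure(tibble::tibble(gene_id = c("a", "b")), species = "s1"),
    structure(tibble::tibble(gene_id = c("c", "d")), species = "s2"))
  links <- tibble::tibble(gene_a = c("a", "b"), gene_b = c("b", "c"),
                          score = 1, evalue = 0)
  # no links: candidates are the seeds
  none <- candidate_genes(loci, links[0, ], "a")
  expect_identical(none$gene_id, "a")
  # chain a-b, b-c: c reached from a; d not
  cand <- candidate_genes(loci, links, "a")
  expect_setequal(cand$gene_id, c("a", "b", "c"))
  # locus order does not matter
  cand_rev <- candidate_genes(rev(loci), links, "a")
  expect_setequal(cand_rev$gene_id, cand$gene_id)
})

test_that("full mining recovers the planted locus members", {
  cfg <- sim_config(seed = 1, n_species = 4)
  gt <- generate_gene_tables(cfg, n_candidates = 2)
  loci <- lapply(sprintf("sp%02d", 1:4), function(sp) {
    a <- gt$truth$anchors$gene_id[gt$truth$anchors$species == sp]
    extract_locus_window(dplyr::filter(gt$tables, species == sp), a,
                         window = 5)
  })
  links <- dplyr::bind_rows(lapply(2:4, function(i)
    link_loci(loci[[1]], loci[[i]], gt$proteins)))
  seeds <- gt$truth$planted_members$gene_id[
    gt$truth$planted_members$species == "sp01"]
  cand <- candidate_genes(loci, links, seeds)
  expect_setequal(cand$gene_id, gt$truth$planted_members$gene_id)
})

test_that("GFF3 reader converts to 0-based half-open coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA;Name=geneA",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tsrc\tgene\t501\t700\t.\t-\t.\tID=gB"), gff)
  tab <- read_gene_gff3(gff, species = "spZ")
  expect_equal(tab$gene_id, c("gA", "gB"))
  expect_equal(tab$start, c(100L, 500L))
  expect_equal(tab$end, c(200L, 700L))
  expect_equal(tab$strand, c("+", "-"))
})
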