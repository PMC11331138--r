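# Structure parsing, confidence filtering, contacts, hydrogen bonds,
# pocket calls, consensus, and superposition.

# minimal hand-built two-residue model for geometric edge cases
mini_model <- function(d = 3.0, rec_elety = "OG", pep_elety = "OG",
                       rec_element = "O", pep_element = "O",
                       rec_cb = NULL, pep_cb = NULL) {
  atoms <- tibble::tibble(
    chain = c("A", "B"), resno = c(10L, 1L), resid = c("SER", "SER"),
    elety = c(rec_elety, pep_elety), element = c(rec_element, pep_element),
    x = c(d, 0), y = 0, z = 0)
  if (!is.null(rec_cb))
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      chain = "A", resno = 10L, resid = "SER", elety = "CB",
      element = "C", x = rec_cb[1], y = rec_cb[2], z = rec_cb[3]))
  if (!is.null(pep_cb))
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      chain = "B", resno = 1L, resid = "SER", elety = "CB",
      element = "C", x = pep_cb[1], y = pep_cb[2], z = pep_cb[3]))
  pocketmap:::new_structure_model(atoms,
                                  roles = c(A = "receptor", B = "peptide"))
}

test_that("structure files round-trip and formats agree", {
  m <- generate_toy_complex(sim_config(seed = 13), jitter = 0.05)
  pdb <- tempfile(fileext = ".pdb"); cif <- tempfile(fileext = ".cif")
  write_structure_pdb(m, pdb)
  write_structure_mmcif(m, cif)
  side <- tempfile(fileext = ".json")
  write_confidence_sidecar(setNames(0.91, basename(pdb)), side)
  mp <- parse_structure(pdb, c(A = "receptor", B = "peptide"), side)
  expect_equal(mp$iptm, 0.91)
  expect_equal(as.data.frame(mp$atoms[, c("x", "y", "z")]),
               as.data.frame(m$atoms[, c("x", "y", "z")]))
  # write -> parse -> write is byte-stable
  pdb2 <- tempfile(fileext = ".pdb")
  write_structure_pdb(mp, pdb2)
  expect_identical(readLines(pdb), readLines(pdb2))
  # mmCIF and PDB yield identical residue/atom sets
  mc <- parse_structure(cif, c(A = "receptor", B = "peptide"))
  expect_equal(as.data.frame(mc$atoms), as.data.frame(mp$atoms))
  # unknown chain role rejected; missing sidecar entry flagged
  expect_error(parse_structure(pdb, c(A = "receptor")), "without a role")
  expect_warning(parse_structure(pdb, c(A = "receptor", B = "peptide"),
                                 setNames(0.9, "other.pdb")), "no confidence")
})

test_that("confidence filtering applies strict printed thresholds", {
  tab <- tibble::tibble(model_id = sprintf("m%d", 1:6),
                        iptm = c(0.85, 0.84, 0.81, 0.80, 0.61, NA))
  afm <- filter_models(tab, "afm")
  expect_equal(afm$status,
               c("confident", "rejected", "rejected", "rejected",
                 "rejected", "no_score"))
  af3 <- filter_models(tab, "af3")
  expect_equal(af3$status,
               c("confident", "confident", "confident", "gray", "gray",
                 "no_score"))
  expect_equal(filter_models(tibble::tibble(model_id = "x", iptm = 0.59),
                             "af3")$status, "rejected")
})

test_that("contacts respect the distance cutoff on minimal geometry", {
  expect_equal(nrow(find_contacts(mini_model(3.0), cutoff = 4.0)), 1L)
  expect_equal(nrow(find_contacts(mini_model(4.5), cutoff = 4.0)), 0L)
  hit <- find_contacts(mini_model(3.0))
  expect_equal(hit$rec_resno, 10L)
  expect_equal(hit$pep_pos, 1L)
  expect_equal(hit$min_dist, 3.0)
})

test_that("contact extraction equals the brute-force oracle on toy models", {
  for (seed in c(2, 3)) {
    m <- generate_toy_complex(sim_config(seed = seed), jitter = 0.08)
    got <- find_contacts(m)
    want <- oracle_contacts(m)
    expect_equal(paste(got$rec_resno, got$pep_pos),
                 paste(want$rec_resno, want$pep_pos))
    expect_equal(got$min_dist, want$min_dist, tolerance = 1e-9)
  }
})

test_that("hydrogen bonds demand polar elements, distance and angle", {
  m <- generate_toy_complex(sim_config(seed = 14))
  hb <- hydrogen_bonds(m)
  truth <- attr(m, "truth")
  expect_setequal(paste(hb$rec_resno, hb$pep_pos),
                  paste(truth$planted_contacts[, 1],
                        truth$planted_contacts[, 2]))
  # N...O at 3.8 A: too far
  expect_equal(nrow(hydrogen_bonds(mini_model(3.8))), 0L)
  # carbon pair at 2.9 A: a contact but never a hydrogen bond
  cc <- mini_model(2.9, rec_elety = "CB", pep_elety = "CB",
                   rec_element = "C", pep_element = "C")
  expect_equal(nrow(find_contacts(cc)), 1L)
  expect_equal(nrow(hydrogen_bonds(cc)), 0L)
  # donor angle: both antecedents between donor and acceptor fails the
  # 120-degree requirement in both orientations
  bad <- mini_model(3.0, rec_cb = c(1.5, 0, 0), pep_cb = c(1.5, 0, 0))
  expect_equal(nrow(hydrogen_bonds(bad)), 0L)
  good <- mini_model(3.0, rec_cb = c(4.5, 0, 0), pep_cb = c(-1.5, 0, 0))
  expect_equal(nrow(hydrogen_bonds(good)), 1L)
  # a single failing orientation does not veto the pair when the other
  # side's geometry is consistent with donation
  mixed <- mini_model(3.0, rec_cb = c(1.5, 0, 0), pep_cb = c(-1.5, 0, 0))
  expect_equal(nrow(hydrogen_bonds(mixed)), 1L)
})

test_that("pocket calls report planted pockets and honor empty cases", {
  m <- generate_toy_complex(sim_config(seed = 15))
  hb <- hydrogen_bonds(m)
  ct <- find_contacts(m)
  pc <- call_pockets(hb, contacts = ct)
  expect_equal(pc$residue[pc$position == 5], c(246L, 268L))
  expect_equal(pc$residue[pc$position == 7], c(292L, 294L, 316L))
  # no contacts at a requested position: empty pocket
  expect_equal(nrow(call_pockets(hb, positions = 9L)), 0L)
  # no positions requested: empty call
  expect_equal(nrow(call_pockets(hb, positions = integer(0))), 0L)
})

test_that("consensus pockets aggregate support and stay monotone", {
  mk_call <- function(res5) tibble::tibble(position = 5L, residue = res5)
  calls <- list(mk_call(246L), mk_call(246L), mk_call(246L), mk_call(999L))
  cp <- consensus_pockets(calls, min_support = 0.5)
  expect_equal(cp$residue, 246L)
  expect_equal(cp$support, 3L)
  expect_equal(cp$n_models, 4L)
  # residue in 1 of 4 models dropped at 0.5
  expect_false(999L %in% cp$residue)
  # disjoint calls at full support: empty consensus
  disjoint <- list(mk_call(1L), mk_call(2L))
  expect_equal(nrow(consensus_pockets(disjoint, min_support = 1)), 0L)
  # monotone in min_support
  prev <- Inf
  for (s in c(0.25, 0.5, 0.75, 1)) {
    n <- nrow(consensus_pockets(calls, min_support = s))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("ensemble consensus equals the planted pockets exactly", {
  ens <- default_ensemble()
  flt <- filter_models(ens$models, "afm")
  conf <- ens$models[flt$status == "confident"]
  expect_length(conf, 12L)
  calls <- lapply(conf, function(m) call_pockets(hydrogen_bonds(m)))
  cp <- consensus_pockets(calls, min_support = 0.5)
  expect_true(all(cp$support == 12L))
  want <- attr(ens$models[[1]], "truth")$planted_contacts
  expect_setequal(paste(cp$residue, cp$position),
                  paste(want[, 1], want[, 2]))
})

test_that("superposition is exact, symmetric and rigid-invariant", {
  m <- generate_toy_complex(sim_config(seed = 16))
  expect_lt(superpose(m, m)$rmsd, 1e-9)
  # rotated + translated copy: rmsd 0 within tolerance
  set.seed(7)
  rot <- random_rotation()
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  xyz2 <- xyz %*% t(rot)
  m2$atoms$x <- xyz2[, 1] + 5.5
  m2$atoms$y <- xyz2[, 2] - 3.1
  m2$atoms$z <- xyz2[, 3] + 0.7
  fit <- superpose(m, m2)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # symmetry and invariance under rigid pre-transformation
  m3 <- generate_toy_complex(sim_config(seed = 16), jitter = 0.2,
                             seed = 161L)
  expect_equal(superpose(m, m3)$rmsd, superpose(m3, m)$rmsd,
               tolerance = 1e-9)
  m3_moved <- m3
  xyz3 <- as.matrix(m3$atoms[, c("x", "y", "z")]) %*% t(rot)
  m3_moved$atoms$x <- xyz3[, 1] + 1
  m3_moved$atoms$y <- xyz3[, 2] + 2
  m3_moved$atoms$z <- xyz3[, 3] + 3
  expect_equal(superpose(m, m3_moved)$rmsd, superpose(m, m3)$rmsd,
               tolerance = 1e-6)
})

test_that("superposition agrees with an independent reference fit", {
  m <- generate_toy_complex(sim_config(seed = 18))
  m2 <- generate_toy_complex(sim_config(seed = 18), jitter = 0.3,
                             seed = 181L)
  ours <- superpose(m, m2)
  a <- as.matrix(m$atoms[m$atoms$elety == "CA", c("x", "y", "z")])
  b <- as.matrix(m2$atoms[m2$atoms$elety == "CA", c("x", "y", "z")])
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - b)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})
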