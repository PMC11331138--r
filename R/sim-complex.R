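# Toy receptor-peptide complexes: a pseudo-atomic receptor solenoid with an
# extended peptide along its axis, planted hydrogen-bond contacts at exact
# geometry, and everything else kept outside the contact cutoff by a guard
# margin.

AA1TO3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
            H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
            P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
            W = "TRP", Y = "TYR")

polar_atom_name <- function(resid) {
  switch(resid, SER = "OG", THR = "OG1", ASP = "OD1", ASN = "OD1",
         GLU = "OE1", GLN = "OE1", HIS = "NE2", TYR = "OH", LYS = "NZ",
         ARG = "NH1", "OX")
}

pocket_resid <- function(resno) {
  switch(as.character(resno),
         "246" = "ASP", "268" = "ASN", "292" = "SER",
         "294" = "HIS", "316" = "HIS", "SER")
}

# six pseudo-atoms for one residue given CA position and two unit vectors:
# `u` points from backbone toward the side chain, `t` is a transverse axis.
residue_atoms <- function(resno, resid, ca, u, t) {
  pa <- polar_atom_name(resid)
  pos <- rbind(
    N  = ca + 1.2 * t + c(0, 0, 1.0),
    CA = ca,
    C  = ca - 1.2 * t + c(0, 0, -1.0),
    O  = ca - 1.2 * t + c(0, 0, -2.2),
    CB = ca + 1.53 * u,
    PX = ca + 2.93 * u
  )
  tibble(resno = resno, resid = resid,
         elety = c("N", "CA", "C", "O", "CB", pa),
         element = c("N", "C", "C", "O", "C", substr(pa, 1, 1)),
         x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Simulate a toy receptor-peptide complex with planted contacts
#'
#' Receptor residues carry N/CA/C/O/CB plus one polar side-chain
#' pseudo-atom and lie on a superhelical solenoid of radius 16 A around the
#' z axis; the peptide runs fully extended along that axis (one residue per
#' 4 A). For every planted contact the two polar atoms are placed 2.9 A
#' apart with donor geometry satisfying the default hydrogen-bond criteria;
#' every non-planted receptor-peptide residue pair stays beyond the 4.0 A
#' contact cutoff by a guard margin of at least 0.5 A (verified property,
#' not just intent). At most five contacts can share a peptide position and
#' a receptor residue can contact only one position; other requests are
#' geometrically infeasible and rejected.
#'
#' @param cfg A [sim_config()].
#' @param iptm Confidence score recorded on the model.
#' @param model_id Model identifier (used as chain-agnostic file stem).
#' @param contacts Planted contacts, two-column matrix (receptor residue,
#'   peptide position); defaults to `cfg$contacts`.
#' @param jitter Half-width (A) of uniform coordinate noise; kept small
#'   enough by callers to preserve the planted/non-planted separation.
#' @param seed RNG seed for peptide sequence and jitter.
#' @return A `structure_model` with attribute `truth` (list with
#'   `planted_contacts` and per-position pocket sets).
#' @export
generate_toy_complex <- function(cfg = sim_config(), iptm = 0.9,
                                 model_id = "model_01",
                                 contacts = cfg$contacts, jitter = 0,
                                 seed = derive_seed(cfg$seed, 301L)) {
  validate_sim_config(cfg)
  unit <- lrr_unit()
  n_res <- nchar(NCAP) + cfg$n_repeats * unit$length + nchar(CCAP)
  contacts <- unique(contacts[, 1:2, drop = FALSE])
  if (nrow(contacts)) {
    if (any(contacts[, 1] < 1 | contacts[, 1] > n_res))
      abort("planted contact references a receptor residue outside the chain.")
    if (anyDuplicated(contacts[, 1]))
      abort(paste("geometric placement infeasible: a receptor residue cannot",
                  "contact more than one peptide position."))
    if (any(table(contacts[, 2]) > 5))
      abort("geometric placement infeasible: >5 contacts at one peptide position.")
  }

  with_seed(seed, {
    pep <- seq_to_chars(random_aa(cfg$mature_length))
    pep[unname(cfg$motif)] <- names(cfg$motif)

    # peptide chain B along the z axis
    xhat <- c(1, 0, 0)
    pep_atoms <- purrr::map(seq_along(pep), function(i) {
      residue_atoms(i, AA1TO3[[pep[i]]], ca = c(0, 0, 4 * i),
                    u = xhat, t = c(0, 1, 0))
    }) |> bind_rows() |> mutate(chain = "B")

    # receptor chain A on the solenoid; planted residues re-seated near
    # their peptide partner with per-position azimuth spread
    phis <- c(0, 36, -36, 50, -50) * pi / 180
    k_at_pos <- integer(max(c(contacts[, 2], 1)))
    rec_atoms <- purrr::map(seq_len(n_res), function(j) {
      hit <- which(contacts[, 1] == j)
      if (length(hit) == 1L) {
        pos <- contacts[hit, 2]
        k_at_pos[pos] <<- k_at_pos[pos] + 1L
        phi <- phis[k_at_pos[pos]]
        dir <- c(cos(phi), sin(phi), 0)
        og_pep <- c(2.93, 0, 4 * pos)
        # CA seated so that the polar atom (ca - 2.93*dir) lies exactly
        # 2.9 A from the peptide's polar atom; u = -dir points the side
        # chain back toward the peptide
        ca <- og_pep + (2.9 + 2.93) * dir
        residue_atoms(j, pocket_resid(j), ca = ca, u = -dir,
                      t = c(-dir[2], dir[1], 0))
      } else {
        th <- 2 * pi * j / 72
        u <- -c(cos(th), sin(th), 0)          # inward
        ca <- c(16 * cos(th), 16 * sin(th), 0.25 * j)
        residue_atoms(j, "LEU", ca = ca, u = u, t = c(-sin(th), cos(th), 0))
      }
    }) |> bind_rows() |> mutate(chain = "A")

    atoms <- bind_rows(rec_atoms, pep_atoms) |>
      select("chain", "resno", "resid", "elety", "element", "x", "y", "z")
    if (jitter > 0) {
      n <- nrow(atoms)
      atoms$x <- atoms$x + runif(n, -jitter, jitter)
      atoms$y <- atoms$y + runif(n, -jitter, jitter)
      atoms$z <- atoms$z + runif(n, -jitter, jitter)
    }
    atoms <- atoms |> mutate(x = round(.data$x, 3), y = round(.data$y, 3),
                             z = round(.data$z, 3))
  })

  truth <- list(
    planted_contacts = contacts,
    pockets = split(contacts[, 1], contacts[, 2]),
    peptide_sequence = chars_to_seq(pep)
  )
  model <- new_structure_model(atoms,
                               roles = c(A = "receptor", B = "peptide"),
                               iptm = iptm, model_id = model_id)
  attr(model, "truth") <- truth
  model
}

#' Simulate a toy model ensemble with confidence scores
#'
#' `cfg$n_models` confident models (ipTM 0.86-0.97) share the planted
#' pockets up to small coordinate jitter; `cfg$n_decoy_models` low-scoring
#' decoys (ipTM below the AFM acceptance threshold) carry contacts at
#' unrelated receptor residues.
#'
#' @param cfg A [sim_config()].
#' @return List with `models` (list of `structure_model`), `sidecar` (named
#'   ipTM vector keyed by `<model_id>.pdb`), and `truth`.
#' @export
sim_complex_ensemble <- function(cfg = sim_config()) {
  n <- cfg$n_models
  iptms <- round(seq(0.86, 0.97, length.out = n), 3)
  models <- purrr::map(seq_len(n), function(i) {
    generate_toy_complex(cfg, iptm = iptms[i],
                         model_id = sprintf("model_%02d", i),
                         jitter = 0.08,
                         seed = derive_seed(cfg$seed, 310L + i))
  })
  decoy_contacts <- cbind(residue = c(400L, 424L), position = c(5L, 7L))
  decoy_iptms <- round(seq(0.55, 0.82, length.out = cfg$n_decoy_models), 3)
  decoys <- purrr::map(seq_len(cfg$n_decoy_models), function(i) {
    generate_toy_complex(cfg, iptm = decoy_iptms[i],
                         model_id = sprintf("decoy_%02d", i),
                         contacts = decoy_contacts, jitter = 0.08,
                         seed = derive_seed(cfg$seed, 350L + i))
  })
  models <- c(models, decoys)
  sidecar <- setNames(vapply(models, function(m) m$iptm, numeric(1)),
                      vapply(models, function(m) paste0(m$model_id, ".pdb"),
                             character(1)))
  list(models = models, sidecar = sidecar,
       truth = attr(models[[1]], "truth"))
}
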