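# Contact and pocket analysis of predicted receptor-peptide complexes:
# confidence filtering, heavy-atom contacts, geometric hydrogen bonds,
# per-position pocket calls and cross-model consensus.

#' Filter structure models by interface confidence
#'
#' `scheme = "afm"`: confident iff `iptm > 0.84` (strict, matching the
#' printed threshold), otherwise rejected. `scheme = "af3"`: confident iff
#' `iptm > 0.8`; gray zone when `0.6 < iptm <= 0.8`; otherwise rejected.
#' Models without a score are rejected with status `"no_score"`.
#'
#' @param models List of `structure_model` objects (or a tibble with
#'   `model_id` and `iptm`).
#' @param scheme Confidence scheme.
#' @return Tibble `model_id`, `iptm`, `status` in
#'   `c("confident", "gray", "rejected", "no_score")`.
#' @export
filter_models <- function(models, scheme = c("afm", "af3")) {
  scheme <- match.arg(scheme)
  tab <- if (is.data.frame(models)) as_tibble(models)
         else tibble(model_id = vapply(models, function(m) m$model_id,
                                       character(1)),
                     iptm = vapply(models, function(m) m$iptm, numeric(1)))
  tab |> mutate(status = dplyr::case_when(
    is.na(.data$iptm) ~ "no_score",
    scheme == "afm" & .data$iptm > 0.84 ~ "confident",
    scheme == "afm" ~ "rejected",
    .data$iptm > 0.8 ~ "confident",
    .data$iptm > 0.6 ~ "gray",
    TRUE ~ "rejected"))
}

# residue-pair minimum heavy-atom distances between two atom tables
residue_pair_distances <- function(rec, pep) {
  rc <- as.matrix(rec[, c("x", "y", "z")])
  pc <- as.matrix(pep[, c("x", "y", "z")])
  d2 <- outer(rowSums(rc^2), rowSums(pc^2), "+") - 2 * rc %*% t(pc)
  d2[d2 < 0] <- 0
  tibble(
    rec_row = rep(seq_len(nrow(rec)), times = nrow(pep)),
    pep_row = rep(seq_len(nrow(pep)), each = nrow(rec)),
    dist = sqrt(as.vector(d2))
  )
}

#' Receptor-peptide contacts of a structure model
#'
#' For every (receptor residue, peptide residue) pair the minimum
#' heavy-atom distance is computed; pairs within `cutoff` are emitted.
#'
#' @param model A `structure_model` with receptor and peptide roles.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.0).
#' @return Tibble `rec_chain`, `rec_resno`, `rec_resid`, `pep_pos`,
#'   `min_dist`, sorted by peptide position then receptor residue.
#' @export
find_contacts <- function(model, cutoff = 4.0) {
  rec <- role_atoms(model, "receptor") |> filter(.data$element != "H")
  pep <- role_atoms(model, "peptide") |> filter(.data$element != "H")
  if (!nrow(rec) || !nrow(pep))
    abort("model lacks receptor or peptide atoms.")
  pairs <- residue_pair_distances(rec, pep) |>
    mutate(rec_chain = rec$chain[.data$rec_row],
           rec_resno = rec$resno[.data$rec_row],
           rec_resid = rec$resid[.data$rec_row],
           pep_pos = pep$resno[.data$pep_row]) |>
    group_by(.data$rec_chain, .data$rec_resno, .data$rec_resid,
             .data$pep_pos) |>
    summarise(min_dist = min(.data$dist), .groups = "drop")
  pairs |> filter(.data$min_dist <= cutoff) |>
    arrange(.data$pep_pos, .data$rec_resno)
}

# heavy-atom antecedents used for the donor-angle check; first present
# atom in the residue wins
HB_ANTECEDENT <- list(
  N = c("CA"), O = c("C"), OG = c("CB"), OG1 = c("CB"),
  OD1 = c("CG", "CB"), OD2 = c("CG", "CB"), ND2 = c("CG", "CB"),
  OE1 = c("CD", "CG", "CB"), OE2 = c("CD", "CG", "CB"),
  NE2 = c("CD", "CD2", "CB"), ND1 = c("CG", "CB"), NZ = c("CE", "CB"),
  NH1 = c("CZ", "CB"), NH2 = c("CZ", "CB"), NE = c("CD", "CB"),
  OH = c("CZ", "CB"), OX = c("CB")
)

hb_angle <- function(a, b, c) {
  # angle at b (degrees) between rays b->a and b->c
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Geometric hydrogen bonds between receptor and peptide
#'
#' Candidate donor-acceptor pairs are nitrogen/oxygen atom pairs across
#' the interface with distance at most `d_max`. Hydrogens are ignored
#' (predicted models may lack them); instead, when a candidate donor's
#' antecedent heavy atom is present, the antecedent-donor-acceptor angle
#' must reach `angle_min`. A pair is kept if at least one of the two
#' orientations passes.
#'
#' @param model A `structure_model`.
#' @param d_max Donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param angle_min Minimum donor angle in degrees (default 120).
#' @return Tibble `rec_resno`, `rec_resid`, `pep_pos`, `rec_atom`,
#'   `pep_atom`, `dist`.
#' @export
hydrogen_bonds <- function(model, d_max = 3.5, angle_min = 120) {
  rec <- role_atoms(model, "receptor") |> filter(.data$element %in% c("N", "O"))
  pep <- role_atoms(model, "peptide") |> filter(.data$element %in% c("N", "O"))
  out <- tibble(rec_resno = integer(), rec_resid = character(),
                pep_pos = integer(), rec_atom = character(),
                pep_atom = character(), dist = numeric())
  if (!nrow(rec) || !nrow(pep)) return(out)
  pairs <- residue_pair_distances(rec, pep) |> filter(.data$dist <= d_max)
  if (!nrow(pairs)) return(out)
  all_rec <- role_atoms(model, "receptor")
  all_pep <- role_atoms(model, "peptide")
  antecedent_xyz <- function(atoms, chain, resno, elety) {
    cand <- HB_ANTECEDENT[[elety]]
    if (is.null(cand)) cand <- "CB"
    res <- atoms |> filter(.data$chain == !!chain, .data$resno == !!resno)
    hit <- res |> filter(.data$elety %in% cand)
    if (!nrow(hit)) return(NULL)
    hit <- hit[match(cand, hit$elety)[!is.na(match(cand, hit$elety))][1], ]
    c(hit$x, hit$y, hit$z)
  }
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ra <- rec[pairs$rec_row[k], ]; pa <- pep[pairs$pep_row[k], ]
    rxyz <- c(ra$x, ra$y, ra$z); pxyz <- c(pa$x, pa$y, pa$z)
    ok_dir <- function(donor, donor_atoms, acceptor_xyz, donor_xyz) {
      ante <- antecedent_xyz(donor_atoms, donor$chain, donor$resno,
                             donor$elety)
      is.null(ante) || hb_angle(ante, donor_xyz, acceptor_xyz) >= angle_min
    }
    keep[k] <- ok_dir(ra, all_rec, pxyz, rxyz) || ok_dir(pa, all_pep, rxyz, pxyz)
  }
  pairs <- pairs[keep, ]
  tibble(rec_resno = rec$resno[pairs$rec_row],
         rec_resid = rec$resid[pairs$rec_row],
         pep_pos = pep$resno[pairs$pep_row],
         rec_atom = rec$elety[pairs$rec_row],
         pep_atom = pep$elety[pairs$pep_row],
         dist = pairs$dist) |>
    arrange(.data$pep_pos, .data$rec_resno, .data$dist)
}

#' Call binding pockets at peptide positions of interest
#'
#' For each requested peptide position, the set of receptor residues
#' hydrogen-bonded to it; contacts without a hydrogen bond are reported
#' separately in the `nonpolar` attribute.
#'
#' @param hbonds [hydrogen_bonds()] table for one model.
#' @param positions Peptide positions of interest (default the motif
#'   serines, positions 5 and 7).
#' @param contacts Optional [find_contacts()] table; its rows not backed
#'   by a hydrogen bond populate the `nonpolar` attribute.
#' @return Object of class `pocket_call`: tibble `position`, `residue`
#'   (one row per pocket residue), attribute `nonpolar`.
#' @export
call_pockets <- function(hbonds, positions = c(5L, 7L), contacts = NULL) {
  call <- hbonds |> filter(.data$pep_pos %in% positions) |>
    distinct(position = .data$pep_pos, residue = .data$rec_resno) |>
    arrange(.data$position, .data$residue)
  nonpolar <- NULL
  if (!is.null(contacts)) {
    nonpolar <- contacts |>
      dplyr::anti_join(hbonds |> distinct(.data$rec_resno, .data$pep_pos),
                       by = c("rec_resno", "pep_pos"))
  }
  structure(call, class = c("pocket_call", class(call)), nonpolar = nonpolar)
}

#' Consensus pockets across confident models
#'
#' A residue is kept at a peptide position iff it appears in at least
#' `min_support` of the models; support counts are reported. Raising
#' `min_support` never adds residues.
#'
#' @param calls List of per-model [call_pockets()] tables.
#' @param min_support Fraction of models required (default 0.5).
#' @return Tibble `position`, `residue`, `support`, `n_models`.
#' @export
consensus_pockets <- function(calls, min_support = 0.5) {
  n <- length(calls)
  if (n == 0)
    return(tibble(position = integer(), residue = integer(),
                  support = integer(), n_models = integer()))
  all <- purrr::imap(calls, function(cl, i)
    as_tibble(cl) |> mutate(model = i)) |> bind_rows()
  all |> distinct(.data$model, .data$position, .data$residue) |>
    dplyr::count(.data$position, .data$residue, name = "support") |>
    filter(.data$support >= min_support * n) |>
    mutate(n_models = n) |>
    arrange(.data$position, .data$residue)
}
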