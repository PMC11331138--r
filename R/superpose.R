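# Least-squares rigid superposition (Kabsch) of paired C-alpha atoms.

#' Kabsch superposition of two paired coordinate sets
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD
#' between `a` (mobile) and `b` (fixed): `a %*% t(rotation) + translation`
#' superposes onto `b`.
#'
#' @param a,b Numeric n x 3 matrices of paired coordinates.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#' @export
kabsch <- function(a, b) {
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b), nrow(a) >= 3)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(t(a0) %*% b0)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  list(rotation = rot, translation = as.numeric(cb - ca %*% t(rot)),
       rmsd = rmsd)
}

#' Superpose two structure models on paired C-alpha atoms
#'
#' @param model_a,model_b `structure_model` objects.
#' @param pairs Optional tibble with columns `chain_a`, `resno_a`,
#'   `chain_b`, `resno_b` naming the residue pairing; by default all
#'   (chain, residue) combinations present in both models are paired.
#' @return List with `rotation`, `translation`, `rmsd` (Angstrom) and
#'   `n_pairs`.
#' @export
superpose <- function(model_a, model_b, pairs = NULL) {
  ca_a <- model_a$atoms |> filter(.data$elety == "CA")
  ca_b <- model_b$atoms |> filter(.data$elety == "CA")
  if (is.null(pairs)) {
    shared <- dplyr::inner_join(
      ca_a |> select("chain", "resno"),
      ca_b |> select("chain", "resno"), by = c("chain", "resno"))
    pairs <- shared |> rename(chain_a = "chain", resno_a = "resno") |>
      mutate(chain_b = .data$chain_a, resno_b = .data$resno_a)
  }
  ia <- match(paste(pairs$chain_a, pairs$resno_a),
              paste(ca_a$chain, ca_a$resno))
  ib <- match(paste(pairs$chain_b, pairs$resno_b),
              paste(ca_b$chain, ca_b$resno))
  if (anyNA(ia) || anyNA(ib))
    abort("some paired residues lack a CA atom in one of the models.")
  fit <- kabsch(as.matrix(ca_a[ia, c("x", "y", "z")]),
                as.matrix(ca_b[ib, c("x", "y", "z")]))
  fit$n_pairs <- length(ia)
  fit
}
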