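# StructureModel: parsed complex coordinates with chain roles and an
# interface confidence (ipTM) score.

new_structure_model <- function(atoms, roles, iptm = NA_real_,
                                model_id = "model") {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resid", "elety", "element",
                  "x", "y", "z") %in% names(atoms)))
  if (!all(unique(atoms$chain) %in% names(roles)))
    abort(sprintf("chains without a role: %s",
                  paste(setdiff(unique(atoms$chain), names(roles)),
                        collapse = ", ")))
  structure(list(atoms = as_tibble(atoms), roles = roles,
                 iptm = iptm, model_id = model_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, chains %s, ipTM %s\n",
              x$model_id, nrow(x$atoms),
              paste(sprintf("%s(%s)", names(x$roles), x$roles), collapse = " "),
              ifelse(is.na(x$iptm), "absent", sprintf("%.2f", x$iptm))))
  invisible(x)
}

role_atoms <- function(model, role) {
  ch <- names(model$roles)[model$roles == role]
  model$atoms |> filter(.data$chain %in% ch)
}

#' Parse a predicted complex structure
#'
#' Reads a PDB or mmCIF file, labels each chain with its role, and attaches
#' the ipTM score found in the sidecar (JSON mapping file name to score).
#' Author residue numbering is preserved, so receptor residue 246 reports
#' as 246. A model whose sidecar entry is missing loads with `iptm = NA`
#' and a warning; [filter_models()] rejects such models.
#'
#' @param file Path to a `.pdb` or `.cif` file.
#' @param roles Named character vector mapping chain id to role, e.g.
#'   `c(A = "receptor", B = "peptide")`.
#' @param sidecar Optional path to the confidence JSON, or a named numeric
#'   vector of scores keyed by file basename.
#' @return A `structure_model`.
#' @export
parse_structure <- function(file, roles, sidecar = NULL) {
  ext <- tolower(tools::file_ext(file))
  atoms <- if (ext %in% c("cif", "mmcif")) read_mmcif_atoms(file)
           else read_pdb_atoms(file)
  iptm <- NA_real_
  if (!is.null(sidecar)) {
    scores <- if (is.character(sidecar) && length(sidecar) == 1 &&
                  file.exists(sidecar)) {
      unlist(jsonlite::read_json(sidecar))
    } else sidecar
    key <- basename(file)
    if (key %in% names(scores)) iptm <- as.numeric(scores[[key]])
    else warn(sprintf("no confidence score for '%s' in sidecar; ipTM absent",
                      key))
  }
  new_structure_model(atoms, roles, iptm = iptm,
                      model_id = tools::file_path_sans_ext(basename(file)))
}

read_pdb_atoms <- function(file) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  el <- a$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- substr(gsub("[0-9]", "", a$elety), 1, 1)
  tibble(chain = a$chain, resno = as.integer(a$resno), resid = a$resid,
         elety = a$elety, element = toupper(trimws(el)),
         x = a$x, y = a$y, z = a$z)
}

#' Write a structure model to PDB
#'
#' @param model A `structure_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(model, file) {
  a <- model$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, elesy = a$element)
  invisible(file)
}

# Minimal mmCIF atom_site writer/reader covering the fields this package
# emits; not a general mmCIF parser.
#' @rdname write_structure_pdb
#' @export
write_structure_mmcif <- function(model, file) {
  a <- model$atoms
  lines <- c(
    sprintf("data_%s", model$model_id),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f",
            seq_len(nrow(a)), a$element, a$elety, a$resid, a$chain,
            a$resno, a$x, a$y, a$z)
  )
  writeLines(lines, file)
  invisible(file)
}

read_mmcif_atoms <- function(file) {
  lines <- readLines(file)
  fields <- grep("^_atom_site\\.", lines, value = TRUE)
  fields <- sub("^_atom_site\\.", "", trimws(fields))
  rows <- grep("^(ATOM|HETATM)\\s", lines, value = TRUE)
  if (!length(rows)) abort("no atom_site records found in mmCIF file.")
  mat <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
  if (ncol(mat) != length(fields))
    abort("atom_site rows do not match the declared field list.")
  colnames(mat) <- fields
  tibble(chain = mat[, "auth_asym_id"],
         resno = as.integer(mat[, "auth_seq_id"]),
         resid = mat[, "label_comp_id"],
         elety = mat[, "label_atom_id"],
         element = toupper(mat[, "type_symbol"]),
         x = as.numeric(mat[, "Cartn_x"]),
         y = as.numeric(mat[, "Cartn_y"]),
         z = as.numeric(mat[, "Cartn_z"]))
}

#' Read or write an ipTM confidence sidecar
#'
#' JSON object mapping model file name to its ipTM score.
#'
#' @param scores Named numeric vector.
#' @param file Path.
#' @return `read_confidence_sidecar()` returns a named numeric vector.
#' @export
write_confidence_sidecar <- function(scores, file) {
  jsonlite::write_json(as.list(scores), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_confidence_sidecar
#' @export
read_confidence_sidecar <- function(file) {
  unlist(jsonlite::read_json(file))
}
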