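# Overlay of consensus pockets on the conservation map and the permutation
# enrichment test formalizing "predicted contacts fall within conserved
# regions" (the test itself is this package's formalization; the source
# analyses assert the overlap qualitatively).

#' Map receptor residues to LRR grid cells
#'
#' Each residue number maps to its grid cell via the reference repeat
#' annotation; residues outside solvent-exposed cells are reported as
#' unmapped with a reason rather than dropped.
#'
#' @param residues Integer vector of 1-based receptor residue numbers.
#' @param grid A [build_lrr_grid()] result.
#' @return Tibble `residue`, `rep`, `pos`, `mapped`, `reason`.
#' @export
map_residues_to_grid <- function(residues, grid) {
  g <- as_tibble(grid)
  out <- tibble(residue = as.integer(residues)) |>
    left_join(g |> select("residue", "rep", "pos"), by = "residue") |>
    mutate(mapped = !is.na(.data$rep),
           reason = ifelse(.data$mapped, NA_character_,
                           "not a solvent-exposed repeat position"))
  out
}

#' Permutation enrichment of conservation at contact cells
#'
#' Observed statistic: mean regional conservation over the given cells.
#' Null: `n_perm` draws of the same number of cells uniformly without
#' replacement from the whole grid. One-sided p-value with the add-one
#' rule, `p = (1 + #{null >= observed}) / (1 + n_perm)`, so p is never 0.
#'
#' @param cells Tibble with columns `rep`, `pos` (e.g. mapped pocket
#'   residues or [conserved_regions()] rows).
#' @param map An [rcm_map()] result.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutation draws.
#' @return Object of class `enrichment_result`: `observed`, `null`
#'   (numeric vector), `p_value`, `n_perm`, `n_cells`, `seed`.
#' @export
enrichment_test <- function(cells, map, n_perm = 999L, seed = 1L) {
  m <- map$regional
  n_cells <- nrow(cells)
  if (n_cells == 0) abort("no cells supplied.")
  if (n_cells > length(m)) abort("more cells than grid positions.")
  idx <- cbind(cells$rep, cells$pos)
  if (any(idx[, 1] < 1 | idx[, 1] > nrow(m) | idx[, 2] < 1 | idx[, 2] > ncol(m)))
    abort("cell outside the grid.")
  observed <- mean(m[idx])
  vals <- as.vector(m)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    mean(vals[sample.int(length(vals), n_cells)]), numeric(1)))
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (1 + n_perm),
                 n_perm = as.integer(n_perm), n_cells = n_cells,
                 seed = as.integer(seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> observed %.4f over %d cells; p = %.4g (%d permutations)\n",
              x$observed, x$n_cells, x$p_value, x$n_perm))
  invisible(x)
}

#' Combined pipeline report
#'
#' Assembles stage outputs into one bundle with deterministic field order;
#' absent stages are marked absent rather than failing. `write_report()`
#' serializes the bundle as JSON (plus TSV matrices);
#' `validate_report()` checks a bundle against the shipped schema
#' (`inst/schema/report-schema.json`).
#'
#' @param candidates [candidate_genes()] tibble.
#' @param clusters [cluster_precursors()] tibble.
#' @param clade [extract_clade()] result.
#' @param rcm [rcm_map()] result.
#' @param pockets [consensus_pockets()] tibble.
#' @param enrichment [enrichment_test()] result.
#' @param config A [sim_config()] or arbitrary named list echoed verbatim.
#' @return Object of class `pipeline_report` (a named list).
#' @export
build_report <- function(candidates = NULL, clusters = NULL, clade = NULL,
                         rcm = NULL, pockets = NULL, enrichment = NULL,
                         config = NULL) {
  stage <- function(x, f) if (is.null(x)) list(present = FALSE)
                          else c(list(present = TRUE), f(x))
  rep <- list(
    package = "pocketmap",
    version = as.character(utils::packageVersion("pocketmap")),
    config = if (is.null(config)) list() else unclass(config),
    candidates = stage(candidates, function(x)
      list(n = nrow(x), ids = x$gene_id)),
    clusters = stage(clusters, function(x)
      list(n_records = nrow(x), n_clusters = length(unique(x$cluster)))),
    clade = stage(clade, function(x)
      list(n_tips = length(x$tips), tips = x$tips)),
    rcm = stage(rcm, function(x)
      list(n_rep = nrow(x$regional), n_pos = ncol(x$regional),
           regional = apply(x$regional, 1, as.numeric, simplify = FALSE),
           raw = apply(x$raw, 1, as.numeric, simplify = FALSE))),
    pockets = stage(pockets, function(x)
      list(calls = purrr::pmap(x, function(position, residue, support,
                                           n_models, ...)
        list(position = position, residue = residue, support = support,
             n_models = n_models)))),
    enrichment = stage(enrichment, function(x)
      list(observed = x$observed, p_value = x$p_value, n_perm = x$n_perm,
           n_cells = x$n_cells, seed = x$seed,
           note = "permutation formalization of contact/conservation overlap"))
  )
  structure(rep, class = "pipeline_report")
}

#' @rdname build_report
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # patch_cells/contacts matrices serialize as row lists for stability
  cfg <- report$config
  for (nm in c("patch_cells", "contacts"))
    if (!is.null(cfg[[nm]]) && is.matrix(cfg[[nm]]))
      cfg[[nm]] <- apply(cfg[[nm]], 1, as.integer, simplify = FALSE)
  report$config <- cfg
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (isTRUE(report$rcm$present)) {
    write.table(do.call(rbind, report$rcm$regional),
                file.path(dir, "rcm_regional.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    write.table(do.call(rbind, report$rcm$raw),
                file.path(dir, "rcm_raw.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(file.path(dir, "report.json"))
}

#' @rdname build_report
#' @param x A `pipeline_report`, or a path to a report JSON.
#' @param schema Path to the schema JSON.
#' @export
validate_report <- function(x, schema = system.file("schema",
                                                    "report-schema.json",
                                                    package = "pocketmap")) {
  rep <- if (is.character(x)) jsonlite::read_json(x) else unclass(x)
  sch <- jsonlite::read_json(schema)
  missing <- setdiff(unlist(sch$required), names(rep))
  if (length(missing))
    abort(sprintf("report missing required fields: %s",
                  paste(missing, collapse = ", ")))
  for (nm in names(sch$stages)) {
    if (!is.list(rep[[nm]]) || is.null(rep[[nm]]$present))
      abort(sprintf("stage '%s' must be an object with a 'present' flag", nm))
    if (isTRUE(rep[[nm]]$present)) {
      need <- unlist(sch$stages[[nm]])
      miss <- setdiff(need, names(rep[[nm]]))
      if (length(miss))
        abort(sprintf("stage '%s' missing: %s", nm,
                      paste(miss, collapse = ", ")))
    }
  }
  invisible(TRUE)
}
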