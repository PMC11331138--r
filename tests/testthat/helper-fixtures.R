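# Shared fixtures, built once per test run. All default-preset objects are
# deterministic (seed 1 study conditions).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env, inherits = FALSE)
}

default_family <- function() {
  fixture("family", generate_receptor_family(sim_config()))
}

default_grid <- function() {
  fixture("grid", {
    fam <- default_family()
    ref <- names(fam$alignment)[1]
    build_lrr_grid(fam$alignment, detect_lrr_repeats(fam$alignment[[ref]]),
                   ref)
  })
}

default_rcm <- function() {
  fixture("rcm", rcm_map(default_family()$alignment, default_grid()))
}

default_precursors <- function() {
  fixture("precursors", generate_precursor_set(sim_config()))
}

default_ensemble <- function() {
  fixture("ensemble", sim_complex_ensemble(sim_config()))
}

# null study conditions: no planted patch
null_rcm <- function() {
  fixture("null_rcm", {
    cfg <- sim_config(seed = 3, patch_rate = 3, background_rate = 3)
    fam <- generate_receptor_family(cfg)
    ref <- names(fam$alignment)[1]
    grid <- build_lrr_grid(fam$alignment,
                           detect_lrr_repeats(fam$alignment[[ref]]), ref)
    rcm_map(fam$alignment, grid)
  })
}

# independent all-pairs contact oracle: plain loops over residues, direct
# distance arithmetic (no shared code with find_contacts)
oracle_contacts <- function(model, cutoff = 4.0) {
  rec <- model$atoms[model$atoms$chain %in%
                       names(model$roles)[model$roles == "receptor"], ]
  pep <- model$atoms[model$atoms$chain %in%
                       names(model$roles)[model$roles == "peptide"], ]
  rec <- rec[rec$element != "H", ]
  pep <- pep[pep$element != "H", ]
  rf <- factor(rec$resno)
  pf <- factor(pep$resno)
  d <- sqrt(outer(rec$x, pep$x, "-")^2 + outer(rec$y, pep$y, "-")^2 +
              outer(rec$z, pep$z, "-")^2)
  mins <- tapply(as.vector(d),
                 list(rec = rf[row(d)], pep = pf[col(d)]), min)
  hits <- which(mins <= cutoff, arr.ind = TRUE)
  out <- data.frame(
    rec_resno = as.integer(rownames(mins)[hits[, 1]]),
    pep_pos = as.integer(colnames(mins)[hits[, 2]]),
    min_dist = mins[hits])
  out[order(out$pep_pos, out$rec_resno), ]
}

# random proper rotation matrix
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# canonical repeat unit string with consensus anchors and fixed 'A' at
# variable positions (used to construct receptor fixtures by hand)
canonical_unit <- function(fill = "A") {
  u <- lrr_unit()
  s <- rep(fill, u$length)
  s[u$anchor_pos] <- u$anchor_res
  paste(s, collapse = "")
}
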