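# broom-style tidiers for the package's result objects.

#' @export
tidy.rcm_map <- function(x, ...) {
  g <- as_tibble(x$grid)
  g |> mutate(raw = x$raw[cbind(.data$rep, .data$pos)],
              regional = x$regional[cbind(.data$rep, .data$pos)],
              gap_fraction = x$gap_fraction[cbind(.data$rep, .data$pos)])
}

#' @export
glance.rcm_map <- function(x, ...) {
  tibble(n_rep = nrow(x$regional), n_pos = ncol(x$regional),
         window = x$window,
         raw_mean = mean(x$raw), regional_min = min(x$regional),
         regional_max = max(x$regional))
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(draw = seq_along(x$null), null_mean = x$null)
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(observed = x$observed, p_value = x$p_value, n_perm = x$n_perm,
         n_cells = x$n_cells, null_mean = mean(x$null),
         null_sd = stats::sd(x$null))
}

#' @export
tidy.peptide_profile <- function(x, ...) {
  as_tibble(x$log_odds) |>
    mutate(position = row_number()) |>
    tidyr::pivot_longer(-"position", names_to = "residue",
                        values_to = "log_odds")
}

#' @export
tidy.motif_summary <- function(x, ...) {
  as_tibble(x$freq) |>
    mutate(position = row_number(), ic = x$ic) |>
    tidyr::pivot_longer(-c("position", "ic"), names_to = "residue",
                        values_to = "freq")
}

#' @export
glance.motif_summary <- function(x, ...) {
  tibble(n = x$n, fraction_sxs = x$fraction_sxs,
         fraction_sxt = x$fraction_sxt, mean_ic = mean(x$ic))
}

#' @export
tidy.seq_distance <- function(x, ...) {
  ids <- rownames(x$distance)
  tidyr::expand_grid(taxon_a = ids, taxon_b = ids) |>
    filter(.data$taxon_a < .data$taxon_b) |>
    mutate(distance = x$distance[cbind(.data$taxon_a, .data$taxon_b)],
           similarity = x$similarity[cbind(.data$taxon_a, .data$taxon_b)])
}
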