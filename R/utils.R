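# Shared constants and small helpers.

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes in alphabetical order; the column order used by
#' every profile and frequency matrix in the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Robinson-Robinson style average composition of globular proteins; used to
# draw variable positions in the simulators. Profile scoring defaults to a
# uniform background instead (see build_profile).
aa_composition <- function() {
  x <- c(A = 0.0788, C = 0.0199, D = 0.0532, E = 0.0628, F = 0.0397,
         G = 0.0701, H = 0.0229, I = 0.0513, K = 0.0595, L = 0.0901,
         M = 0.0221, N = 0.0425, P = 0.0512, Q = 0.0426, R = 0.0512,
         S = 0.0712, T = 0.0584, V = 0.0644, W = 0.0131, Y = 0.0350)
  x / sum(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_aa <- function(n, freqs = aa_composition()) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

# Stable derived seed stream: small offsets keep values well inside .Machine
# integer range for any user seed below ~2e9.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}
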