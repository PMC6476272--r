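#' Round half away from zero
#'
#' Rounding used for printed percentages in summaries. `round()` in R rounds
#' half to even; reported percentages follow the convention that 0.5 rounds
#' away from zero.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic per-stage sub-seed from a run seed. Keeps every derived seed
# a valid 32-bit R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(panel = 101L, genotypes = 211L, phenotypes = 307L,
               plates = 401L, replicate = 503L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

# p-values are never reported as exactly zero
floor_p <- function(p) {
  pmax(p, .Machine$double.xmin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
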