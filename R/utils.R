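# Internal helpers shared across modules.

#' The 20 canonical amino-acid one-letter codes, alphabetical
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Letters that occur in real FASTA but are outside the 20-letter alphabet:
# ambiguity codes (B, Z, J, X) and rare residues (U, O).
AMBIGUOUS_LETTERS <- c("B", "Z", "J", "X", "U", "O")

#' Derive a deterministic sub-seed from a master seed and an index
#'
#' Keeps every derived seed a valid 32-bit R integer so downstream
#' `set.seed()` calls are portable. Used wherever one user-facing seed must
#' drive several independent random stages (split repetitions, CV folds,
#' per-classifier fits).
#'
#' @param seed master seed (integer)
#' @param index stage or repetition index (integer, >= 0)
#' @return a single integer seed
#' @keywords internal
derive_seed <- function(seed, index) {
  # affine mix modulo a prime below 2^31; collisions across small indices
  # are impossible because the multiplier is coprime to the modulus
  p <- 2147483629
  as.integer((as.numeric(seed) %% p * 48271 + as.numeric(index) * 16807 + 1) %% p)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
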