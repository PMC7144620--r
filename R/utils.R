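#' @keywords internal
"_PACKAGE"

# Deterministic integer hashing used for substructure identifiers.
# Polynomial rolling hash over a vector of non-negative integers, modulo the
# Mersenne prime 2^31 - 1. All intermediates stay below 2^53 so the arithmetic
# is exact in doubles on every platform.
.HASH_MOD <- 2147483647
.HASH_MULT <- 131

hash_ints <- function(x) {
  stopifnot(is.numeric(x), all(x >= 0))
  h <- 7
  for (v in x) {
    h <- (h * .HASH_MULT + (v %% .HASH_MOD)) %% .HASH_MOD
  }
  h
}

# Map a character scalar to a small integer sequence for hashing.
chars_to_ints <- function(s) {
  as.integer(charToRaw(s))
}

# Round to nearest integer, ties away from zero (R's round() is banker's).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Angstrom <-> nanometre conversion at the unit boundary: thresholds are
# stored in nm, PDB coordinates are in Angstrom (1 nm = 10 Angstrom).
ang_to_nm <- function(x) x / 10
nm_to_ang <- function(x) x * 10
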