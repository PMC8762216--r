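# Internal helpers shared across modules.

# Deterministic child seeds: keep well below .Machine$integer.max so that
# seed arithmetic never overflows 32-bit integers.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

is_single_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

DNA_BASES <- c("A", "C", "G", "T")

complement_base <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A")[x]
}

# A/T and C/G pairs cannot be disambiguated across strand flips.
is_strand_ambiguous <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & complement_base(a1) == a2
}

sigmoid <- function(x) plogis(x)
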