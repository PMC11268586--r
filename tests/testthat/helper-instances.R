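# Small seeded instances shared across tests.

toy_collection <- function() site_collection(c("AGC", "CAG", "GCA"))

# brute-force placement check of the shift metric, independent of the
# implementation's scan order: try every offset k and test the overlap
# character by character
shift_by_enumeration <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  for (k in 0:na) {
    if (k + nb < na) next
    ov <- intersect(seq_len(na) - k, seq_len(nb))
    if (all(ac[ov + k] == bc[ov])) return(k)
  }
  stop("unreachable: k = nchar(a) always qualifies")
}

random_string <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# the GLPK backend ships with the environment; tests use it unconditionally

# evaluate code under a fixed seed (tests need no RNG-state restoration)
with_seed <- function(seed, code) {
  set.seed(seed)
  code
}
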