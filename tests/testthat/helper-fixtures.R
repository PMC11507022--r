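# Shared fixtures, computed once per test run.

tp <- bundled_panel()
tp_rules <- derive_diagnostic_positions(tp, "family")

# A sequence of length L (valid residues) with exactly n_mm mismatches
# to its unmutated twin; used as a Hamming/threshold oracle.
mismatch_pair <- function(n_mm, L = 100L) {
  base <- rep(c("A", "D", "K", "F", "G", "L", "S", "T", "E", "V"),
              length.out = L)
  mut <- base
  if (n_mm > 0L) {
    idx <- seq_len(n_mm)
    mut[idx] <- ifelse(base[idx] == "W", "Y", "W")
  }
  list(a = pvalb_seq("mm_a", paste(base, collapse = "")),
       b = pvalb_seq("mm_b", paste(mut, collapse = "")))
}

# Random valid residue string of length L.
random_residues <- function(L, seed) {
  set.seed(seed)
  paste(sample(AA20, L, replace = TRUE), collapse = "")
}
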