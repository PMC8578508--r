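# Shared fixture builders (everything generated in code; no binary data).

# deterministic random protein sequence (proline-free unless asked)
random_sequence <- function(n, seed, with_proline = FALSE) {
  aa <- names(hdxdimer::aa_residue_masses())
  if (!with_proline) aa <- setdiff(aa, "P")
  set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# brute-force CK2 consensus oracle: scan every window explicitly
ck2_oracle <- function(sequence, offset = 1L) {
  chars <- strsplit(sequence, "")[[1]]
  hits <- integer(0); res <- character(0)
  for (i in seq_len(max(length(chars) - 3L, 0L))) {
    if (chars[i] %in% c("S", "T") && chars[i + 3L] %in% c("E", "D")) {
      hits <- c(hits, i + offset - 1L)
      res <- c(res, chars[i])
    }
  }
  data.frame(position = hits, residue = res)
}

# brute-force exchanging positions of a peptide (first residue and prolines
# excluded), independent of the package internals
exchanging_oracle <- function(sequence_chars, start, end, offset = 1L) {
  pos <- (start + 1L):end
  if (start >= end) return(integer(0))
  keep <- sequence_chars[pos - offset + 1L] != "P"
  pos[keep]
}

# small deterministic study shared by several tests
small_study <- function(seed = 3L, ...) {
  hdxdimer::simulate_two_state_study(seed = seed, ...)
}
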