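# Independent oracles, deliberately implemented by enumeration rather than
# dynamic programming.

# Best local alignment score by brute force: a local alignment is a set of
# k matched column pairs (i1<...<ik, j1<...<jk); with a linear gap model
# its score is the sum of the column scores plus gap * (number of skipped
# positions inside each aligned window). Enumerating every choice of
# matched columns covers every possible local alignment; k = 0 gives 0.
brute_local_align <- function(a, b, match = 2, mismatch = -1, gap = -1) {
  n <- length(a); m <- length(b)
  best <- 0
  if (n == 0 || m == 0) return(best)
  for (k in seq_len(min(n, m))) {
    ia <- utils::combn(n, k)
    jb <- utils::combn(m, k)
    for (ci in seq_len(ncol(ia))) {
      I <- ia[, ci]
      spanI <- I[k] - I[1] + 1 - k
      for (cj in seq_len(ncol(jb))) {
        J <- jb[, cj]
        sc <- sum(ifelse(a[I] == b[J], match, mismatch)) +
          gap * (spanI + (J[k] - J[1] + 1 - k))
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Local alignment score via Biostrings (independent library route):
# tokens are mapped to single letters, scored with a custom substitution
# matrix; linear gaps = zero opening cost, unit extension.
biostrings_local_align <- function(a, b, match = 2, mismatch = -1, gap = -1) {
  lev <- unique(c(a, b))
  stopifnot(length(lev) <= 26)
  code <- setNames(LETTERS[seq_along(lev)], lev)
  sub <- matrix(mismatch, length(lev), length(lev),
                dimnames = list(LETTERS[seq_along(lev)],
                                LETTERS[seq_along(lev)]))
  diag(sub) <- match
  as.integer(Biostrings::pairwiseAlignment(
    paste(code[a], collapse = ""), paste(code[b], collapse = ""),
    type = "local", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = -gap, scoreOnly = TRUE))
}

random_token_seq <- function(len, alphabet = c("C", "-", "O")) {
  sample(alphabet, len, replace = TRUE)
}

# All token sequences of exactly `len` symbols over `alphabet`.
all_token_seqs <- function(len, alphabet) {
  if (len == 0) return(list(character(0)))
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), len), stringsAsFactors = FALSE))
  lapply(seq_len(nrow(grid)), function(r) as.character(unlist(grid[r, ])))
}
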