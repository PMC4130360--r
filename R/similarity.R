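# Pairwise molecule scoring: local alignment on descriptor token
# sequences (the text route) and the Tanimoto coefficient on precomputed
# binary fingerprints (the reference standard for fingerprint screening).

#' Alignment scoring scheme
#'
#' Match reward, mismatch penalty and linear gap penalty for local
#' alignment of descriptor tokens. Defaults are match +2, mismatch -1,
#' gap -1. Exact dynamic programming is used rather than heuristic
#' seeding: descriptor strings are short, and the exact local-alignment
#' score is the objective that seeded database search tools approximate.
#'
#' @param match integer > 0.
#' @param mismatch integer <= 0.
#' @param gap integer <= 0 (applied per gapped position; linear model).
#' @return object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2L, mismatch = -1L, gap = -1L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap <- as.integer(gap)
  if (match <= 0L) stop("match reward must be positive")
  if (mismatch > 0L) stop("mismatch penalty must be <= 0")
  if (gap > 0L) stop("gap penalty must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "alignment_scoring")
}

#' Local alignment score of two token sequences
#'
#' Best Smith-Waterman local alignment score under the given scoring
#' scheme. The score is a non-negative integer; either sequence empty
#' gives 0.
#'
#' @param a,b token vectors, rendered descriptor strings, or `gbmd`
#'   objects.
#' @param scoring an [alignment_scoring()].
#' @return integer raw score.
#' @export
local_align <- function(a, b, scoring = alignment_scoring()) {
  a <- as_tokens(a); b <- as_tokens(b)
  if (length(a) == 0L || length(b) == 0L) return(0L)
  lev <- unique(c(a, b))
  .sw_score(match(a, lev), match(b, lev),
            scoring$match, scoring$mismatch, scoring$gap)
}

#' Normalized text similarity of two descriptors
#'
#' Raw local-alignment score normalized by `match * max(length)`, so that
#' the score is 1 exactly when the longer sequence aligns end-to-end with
#' no penalty; two empty sequences score 0 by convention. Only relative
#' ranking matters for screening; this normalization makes scores
#' comparable across molecules of different sizes.
#'
#' @inheritParams local_align
#' @return object of class `similarity_score` with fields `raw` and
#'   `normalized` (in \[0,1\]).
#' @export
text_similarity <- function(a, b, scoring = alignment_scoring()) {
  a <- as_tokens(a); b <- as_tokens(b)
  raw <- local_align(a, b, scoring)
  denom <- scoring$match * max(length(a), length(b))
  norm <- if (denom == 0L) 0 else raw / denom
  similarity_score(raw, norm)
}

similarity_score <- function(raw, normalized) {
  structure(list(raw = raw, normalized = normalized),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity: raw = %s, normalized = %.4f>\n",
              format(x$raw), x$normalized))
  invisible(x)
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' T = c / (a + b - c) where a and b are the per-molecule counts of set
#' bits and c the count of shared set bits. Two all-zero fingerprints
#' score 0 by convention. Fingerprint lengths must agree.
#'
#' @param fa,fb [fingerprint()] objects of equal length.
#' @return object of class `similarity_score` (`raw` = shared-bit count
#'   `c`, `normalized` = the coefficient).
#' @examples
#' f1 <- fingerprint("m1", 8, c(1, 2, 3))
#' f2 <- fingerprint("m2", 8, c(2, 3, 4))
#' tanimoto(f1, f2)$normalized  # 0.5
#' @export
tanimoto <- function(fa, fb) {
  stopifnot(inherits(fa, "fingerprint"), inherits(fb, "fingerprint"))
  if (fa$length != fb$length)
    stop("fingerprint length mismatch: ", fa$length, " vs ", fb$length)
  a <- length(fa$bits); b <- length(fb$bits)
  c <- length(intersect(fa$bits, fb$bits))
  denom <- a + b - c
  similarity_score(c, if (denom == 0L) 0 else c / denom)
}
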