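# Binary fingerprints arrive precomputed (MACCS, path/circular fingerprints
# and the like are produced by external software); this package only reads
# them and scores them with the Tanimoto coefficient.

#' Construct a binary fingerprint
#'
#' @param id molecule identifier.
#' @param length total number of bit positions (> 0).
#' @param bits integer vector of set bit positions, 0-based, all < `length`.
#' @return object of class `fingerprint`.
#' @export
fingerprint <- function(id, length, bits = integer(0)) {
  length <- as.integer(length)
  bits <- sort(unique(as.integer(bits)))
  if (length <= 0L) stop("fingerprint length must be positive")
  if (any(bits < 0L | bits >= length))
    stop("bit position outside 0..length-1")
  structure(list(id = as.character(id), length = length, bits = bits),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s: %d/%d bits set>\n",
              x$id, length(x$bits), x$length))
  invisible(x)
}

#' Read fingerprints from the plain-text bit-string format
#'
#' One record per line: `<id> <length> <hex-or-01 string>`. A string made
#' only of the characters 0 and 1 whose width equals the declared length
#' is read as a literal bit string (leftmost character = bit 0); anything
#' else is read as hexadecimal, each digit contributing four bits,
#' most-significant first. A string encoding more bits than declared
#' (beyond hex padding to the next multiple of four) is an error.
#'
#' @param text single string, character vector of lines, or path to a file.
#' @return list of [fingerprint()] objects.
#' @export
read_fingerprints <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) != 3L) stop("malformed fingerprint record: ", ln)
    len <- as.integer(f[2])
    s <- f[3]
    if (grepl("^[01]+$", s) && nchar(s) == len) {
      bits <- which(strsplit(s, "")[[1]] == "1") - 1L
    } else {
      if (!grepl("^[0-9a-fA-F]+$", s))
        stop("fingerprint string is neither binary nor hex: ", ln)
      nb <- 4L * nchar(s)
      if (nb > len + 3L || nb < len)
        stop("fingerprint string encodes ", nb,
             " bits but declares length ", len, ": ", ln)
      digits <- strtoi(strsplit(s, "")[[1]], base = 16L)
      bitmat <- vapply(digits, function(d)
        as.integer(bitwAnd(d, c(8L, 4L, 2L, 1L)) > 0L), integer(4))
      bits <- which(as.vector(bitmat) == 1L) - 1L
      bits <- bits[bits < len]
    }
    fingerprint(f[1], len, bits)
  })
}
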