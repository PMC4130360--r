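# MDL MOL / SDF V2000 reading. Only the connection table is used: 2D/3D
# coordinates and stereo fields are parsed past and discarded (the
# descriptor is 2D-topological). V3000 is out of scope.

#' Parse an MDL MOL (V2000) block into a molecular graph
#'
#' Reads the counts line, atom block and bond block of a V2000 connection
#' table. Explicit hydrogens are kept (see [strip_hydrogens()]); bond
#' orders 1/2/3 map directly; the aromatic bond code 4 is rejected with a
#' message asking for a kekulized input, because the descriptor grammar
#' only defines single, double and triple bonds. Atom numbering in the
#' file is 1-based and converted at this boundary.
#'
#' @param text a single string or character vector of lines holding one
#'   MOL block (up to and including `M  END`).
#' @return a [molgraph()]; the molecule name is taken from the header line.
#' @export
parse_molfile <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (length(lines) < 4L) stop("MOL block too short: no counts line (line 4)")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) {
    # fall back to whitespace splitting for loosely formatted files
    f <- strsplit(trimws(counts), "[[:space:]]+")[[1]]
    natoms <- suppressWarnings(as.integer(f[1]))
    nbonds <- suppressWarnings(as.integer(f[2]))
  }
  if (is.na(natoms) || is.na(nbonds) || natoms < 0L || nbonds < 0L)
    stop("malformed counts line (line 4): ", counts)
  if (length(lines) < 4L + natoms + nbonds)
    stop("MOL block truncated: expected ", natoms, " atom and ",
         nbonds, " bond lines")

  elem <- character(natoms)
  for (k in seq_len(natoms)) {
    ln <- lines[4L + k]
    sym <- trimws(substr(ln, 32, 34))
    if (!nzchar(sym)) {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(f) < 4L) stop("malformed atom line ", 4L + k, ": ", ln)
      sym <- f[4]
    }
    if (!sym %in% PERIODIC_SYMBOLS)
      stop("unknown element '", sym, "' on line ", 4L + k)
    elem[k] <- sym
  }

  bi <- integer(nbonds); bj <- integer(nbonds); bo <- integer(nbonds)
  for (k in seq_len(nbonds)) {
    ln <- lines[4L + natoms + k]
    i <- suppressWarnings(as.integer(substr(ln, 1, 3)))
    j <- suppressWarnings(as.integer(substr(ln, 4, 6)))
    o <- suppressWarnings(as.integer(substr(ln, 7, 9)))
    if (is.na(i) || is.na(j) || is.na(o)) {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(f) < 3L) stop("malformed bond line ", 4L + natoms + k, ": ", ln)
      i <- as.integer(f[1]); j <- as.integer(f[2]); o <- as.integer(f[3])
    }
    if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > natoms || j > natoms)
      stop("bond endpoint out of range on line ", 4L + natoms + k, ": ", ln)
    if (o == 4L)
      stop("aromatic bond code 4 on line ", 4L + natoms + k,
           ": supply a kekulized structure (orders 1/2/3 only)")
    if (!o %in% 1:3)
      stop("unsupported bond order ", o, " on line ", 4L + natoms + k)
    bi[k] <- i; bj[k] <- j; bo[k] <- o
  }
  molgraph(elem, data.frame(i = bi, j = bj, order = bo),
           name = trimws(lines[1]))
}

#' Render a molecular graph as a V2000 MOL block
#'
#' Minimal writer for interchange with other tools: zero coordinates
#' (the descriptor is topological), orders 1/2/3, no charge or stereo
#' fields. Inverse of [parse_molfile()] up to those discarded fields.
#'
#' @param g a [molgraph()].
#' @return a single string ending in `M  END`.
#' @export
render_molfile <- function(g) {
  n <- n_atoms(g); nb <- nrow(g$bonds)
  header <- c(g$name, "  gbmd", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, g$elements)
  bonds <- if (nb > 0L)
    sprintf("%3d%3d%3d  0", g$bonds$i, g$bonds$j, g$bonds$order)
  else character(0)
  paste(c(header, counts, atoms, bonds, "M  END"), collapse = "\n")
}

#' Write molecular graphs to a multi-record SDF file
#'
#' @param graphs a [molgraph()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(graphs, path) {
  if (inherits(graphs, "molgraph")) graphs <- list(graphs)
  txt <- vapply(graphs, render_molfile, character(1))
  writeLines(paste0(txt, "\n$$$$"), path)
  invisible(path)
}

#' Parse a multi-record SDF (V2000) file
#'
#' Records are split on `$$$$` delimiter lines; the MOL block of each
#' record (up to `M  END`) is parsed with [parse_molfile()]; associated
#' data items are ignored.
#'
#' @param text a single string, character vector of lines, or a file path
#'   (a path is detected as a single line naming an existing file).
#' @return list of [molgraph()] objects.
#' @export
parse_sdf <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  recs <- split(lines, cumsum(c(0L, head(trimws(lines) == "$$$$", -1L))))
  out <- list()
  for (rec in recs) {
    rec <- rec[trimws(rec) != "$$$$"]
    endk <- which(startsWith(rec, "M  END"))
    if (length(endk) > 0L) rec <- rec[seq_len(endk[1])]
    if (all(!nzchar(trimws(rec)))) next
    out[[length(out) + 1L]] <- parse_molfile(rec)
  }
  out
}
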