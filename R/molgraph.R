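#' @useDynLib gbmd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils head read.csv write.csv
"_PACKAGE"

# Recognized element symbols (IUPAC periodic table, 1-2 characters,
# second character lower case).
PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu")

#' Construct a labeled molecular graph
#'
#' The central data model: an undirected graph whose vertices are atoms
#' (element symbols) and whose edges are bonds of order 1, 2 or 3.
#' The graph may be disconnected. Atom indices are 1-based internally;
#' file formats keep their own numbering and are converted on read/write.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param bonds data frame with integer columns `i`, `j` (atom indices)
#'   and `order` (1, 2 or 3). May have zero rows.
#' @param name optional molecule name.
#' @return An object of class `molgraph` with fields `elements`, `bonds`
#'   (with `i < j`, rows sorted), and `name`.
#' @examples
#' ethanol <- molgraph(c("C", "C", "O"),
#'                     data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))
#' @export
molgraph <- function(elements, bonds = empty_bonds(), name = "") {
  elements <- as.character(elements)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- empty_bonds()
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.integer(bonds$order))
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  g <- structure(list(elements = elements, bonds = bonds,
                      name = as.character(name)[1]),
                 class = "molgraph")
  validate_molgraph(g)
  g
}

empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0), order = integer(0))
}

#' Validate molecular-graph invariants
#'
#' Checks element symbols against the periodic table, bond orders in
#' \{1,2,3\}, index ranges, absence of self-loops and of duplicate bonds.
#'
#' @param g a [molgraph()].
#' @return `g`, invisibly; errors on violation.
#' @export
validate_molgraph <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  bad <- setdiff(unique(g$elements), PERIODIC_SYMBOLS)
  if (length(bad) > 0L)
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  b <- g$bonds
  n <- length(g$elements)
  if (nrow(b) > 0L) {
    if (any(!b$order %in% 1:3))
      stop("bond order outside {1,2,3}")
    if (any(b$i < 1L | b$j < 1L | b$i > n | b$j > n))
      stop("bond endpoint out of range")
    if (any(b$i == b$j))
      stop("self-loop bond")
    if (anyDuplicated(paste(b$i, b$j)))
      stop("duplicate bond between the same atom pair")
  }
  invisible(g)
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph%s: %d atoms, %d bonds>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              length(x$elements), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(g) length(g$elements)

# Adjacency list (list of integer neighbor vectors) and a dense bond-order
# lookup; molecules are small so dense storage is the simple, fast choice.
adjacency <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  ord <- matrix(0L, n, n)
  b <- g$bonds
  if (nrow(b) > 0L) {
    for (k in seq_len(nrow(b))) {
      i <- b$i[k]; j <- b$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
      ord[i, j] <- ord[j, i] <- b$order[k]
    }
  }
  for (i in seq_len(n)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  list(adj = adj, order = ord)
}

#' Split a molecular graph into connected components
#'
#' Components are found by breadth-first flood fill. Each component keeps
#' the original atom identities in an `orig_index` attribute so that atoms
#' remain traceable to the parent graph. Disconnected inputs are the Rule 3
#' case of the descriptor grammar.
#'
#' @param g a [molgraph()].
#' @return list of `molgraph` objects (empty list for an empty graph).
#' @export
connected_components <- function(g) {
  n <- n_atoms(g)
  if (n == 0L) return(list())
  comp <- component_membership(g)
  lapply(seq_len(max(comp)), function(cid) {
    keep <- which(comp == cid)
    remap <- match(seq_len(n), keep)
    b <- g$bonds[g$bonds$i %in% keep, , drop = FALSE]
    sub <- molgraph(g$elements[keep],
                    data.frame(i = remap[b$i], j = remap[b$j], order = b$order),
                    name = g$name)
    attr(sub, "orig_index") <- keep
    sub
  })
}

# BFS membership vector: comp[v] in 1..k, numbered by smallest contained atom.
component_membership <- function(g) {
  n <- n_atoms(g)
  a <- adjacency(g)$adj
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in a[[v]]) if (comp[u] == 0L) { comp[u] <- cid; queue <- c(queue, u) }
    }
  }
  comp
}

#' Remove explicit hydrogens
#'
#' Drops H atoms and their incident bonds, reindexing the remainder. The
#' descriptor treats molecules as heavy-atom skeletons; hydrogens present
#' in an input file are kept by the parser and removed only on request.
#'
#' @param g a [molgraph()].
#' @return a `molgraph` without H atoms.
#' @export
strip_hydrogens <- function(g) {
  keep <- which(g$elements != "H")
  remap <- match(seq_len(n_atoms(g)), keep)
  b <- g$bonds
  b <- b[!is.na(remap[b$i]) & !is.na(remap[b$j]), , drop = FALSE]
  molgraph(g$elements[keep],
           data.frame(i = remap[b$i], j = remap[b$j], order = b$order),
           name = g$name)
}

#' Parse the edge-list fixture format
#'
#' A minimal plain-text molecule format used by tests and the synthetic
#' generator: lines `atom <idx> <element>` (0-based indices in the file)
#' followed by lines `bond <i> <j> <order>`. Blank lines and `#` comments
#' are ignored.
#'
#' @param text a single string or character vector of lines.
#' @return a [molgraph()].
#' @export
parse_edgelist <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(molgraph(character(0)))
  idx <- integer(0); elem <- character(0)
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (f[1] == "atom") {
      if (length(f) != 3L) stop("malformed atom line: ", ln)
      k <- as.integer(f[2])
      if (k %in% idx) stop("duplicate atom index ", k)
      idx <- c(idx, k); elem <- c(elem, f[3])
    } else if (f[1] == "bond") {
      if (length(f) != 4L) stop("malformed bond line: ", ln)
      bi <- c(bi, as.integer(f[2])); bj <- c(bj, as.integer(f[3]))
      bo <- c(bo, as.integer(f[4]))
    } else stop("unrecognized line: ", ln)
  }
  if (length(idx) > 0L && !setequal(idx, seq_along(idx) - 1L))
    stop("atom indices must be 0..n-1 in the edge-list format")
  elem <- elem[order(idx)]
  if (length(bi) > 0L && any(!(bi %in% idx) | !(bj %in% idx)))
    stop("bond references an undeclared atom")
  molgraph(elem, data.frame(i = bi + 1L, j = bj + 1L, order = bo))
}

#' Render a molecular graph in the edge-list fixture format
#'
#' Inverse of [parse_edgelist()] (round trip is the identity on valid
#' graphs).
#'
#' @param g a [molgraph()].
#' @return a single string.
#' @export
render_edgelist <- function(g) {
  al <- sprintf("atom %d %s", seq_len(n_atoms(g)) - 1L, g$elements)
  bl <- if (nrow(g$bonds) > 0L)
    sprintf("bond %d %d %d", g$bonds$i - 1L, g$bonds$j - 1L, g$bonds$order)
  else character(0)
  paste(c(al, bl), collapse = "\n")
}
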