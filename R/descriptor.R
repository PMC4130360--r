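# Descriptor emission: canonical spanning tree plus a depth-first
# back-and-forth (Euler) tour rendered under a four-rule grammar:
#   Rule 1  atoms by element symbol (two-letter symbols end lower case)
#   Rule 2  bonds as "-", "=", "#" for orders 1, 2, 3
#   Rule 3  disconnected parts joined with "."
#   Rule 4  ring closures marked "/" at each breaking-arc endpoint

BOND_GLYPH <- c("-", "=", "#")

#' Build the canonical spanning forest of a molecular graph
#'
#' Grows a depth-first tree per connected component from the canonical
#' root, expanding children in priority-key order (see
#' [canonical_order()]). Every bond of the graph not used by a tree is a
#' breaking arc; each breaking arc closes exactly one ring, so per
#' component the number of arcs equals the cyclomatic number.
#'
#' @param g a [molgraph()] (may be disconnected).
#' @param order optional precomputed [canonical_order()]; only accepted
#'   when `g` is connected.
#' @return object of class `spanning_forest`: `tree` and `arcs` (bond data
#'   frames in the original atom indexing), `roots` (one atom index per
#'   component), and `components` (list carrying each component subgraph,
#'   its atom indices and its canonical order).
#' @export
build_spanning_forest <- function(g, order = NULL) {
  comps <- connected_components(g)
  if (!is.null(order) && length(comps) != 1L)
    stop("a precomputed order applies only to a connected graph")
  tree <- empty_bonds(); arcs <- empty_bonds(); roots <- integer(0)
  details <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    sub <- comps[[k]]
    orig <- attr(sub, "orig_index")
    ord <- if (!is.null(order)) order else canonical_order(sub)
    e <- split_tree_edges(sub, ord)
    if (nrow(e$tree) > 0L)
      tree <- rbind(tree, data.frame(i = orig[e$tree$i], j = orig[e$tree$j],
                                     order = e$tree$order))
    if (nrow(e$arcs) > 0L)
      arcs <- rbind(arcs, data.frame(i = orig[e$arcs$i], j = orig[e$arcs$j],
                                     order = e$arcs$order))
    roots <- c(roots, orig[ord$root])
    details[[k]] <- list(graph = sub, atoms = orig, order = ord)
  }
  structure(list(tree = tree, arcs = arcs, roots = roots,
                 components = details),
            class = "spanning_forest")
}

# Partition a connected component's bonds into tree edges and breaking arcs
# given its canonical order (tree edges are the parent links).
split_tree_edges <- function(sub, ord) {
  b <- sub$bonds
  v <- which(!is.na(ord$parent))
  tp <- paste(pmin(ord$parent[v], v), pmax(ord$parent[v], v))
  intree <- paste(b$i, b$j) %in% tp
  list(tree = b[intree, , drop = FALSE], arcs = b[!intree, , drop = FALSE])
}

#' @export
print.spanning_forest <- function(x, ...) {
  cat(sprintf("<spanning_forest: %d component(s), %d tree edges, %d breaking arc(s)>\n",
              length(x$roots), nrow(x$tree), nrow(x$arcs)))
  invisible(x)
}

# Euler-tour token emission for one connected component. emit(v):
#   - on the first emission of v, one "/" per breaking arc incident to v
#     (so every arc contributes exactly two ring marks over the tour);
#   - the element symbol of v;
#   - per child c in canonical order: bond glyph of (v,c), recurse into c,
#     bond glyph again, and the element symbol of v once more.
# A tree of n atoms therefore yields 2n-1 atom tokens and each tree bond
# appears exactly twice.
emit_tokens <- function(sub, trav, prep = NULL, flatten_bonds = FALSE) {
  n <- n_atoms(sub)
  bond_ord <- adjacency(sub)$order
  e <- split_tree_edges(sub, trav)
  arc_count <- integer(n)
  if (nrow(e$arcs) > 0L)
    for (k in seq_len(nrow(e$arcs))) {
      arc_count[e$arcs$i[k]] <- arc_count[e$arcs$i[k]] + 1L
      arc_count[e$arcs$j[k]] <- arc_count[e$arcs$j[k]] + 1L
    }
  ntok <- (2L * n - 1L) + 2L * (n - 1L) + 2L * nrow(e$arcs)
  toks <- character(ntok)
  pos <- 0L
  push <- function(x) { pos <<- pos + 1L; toks[pos] <<- x }
  glyph <- function(v, c) {
    if (flatten_bonds) "-" else BOND_GLYPH[bond_ord[v, c]]
  }
  seen_env <- new.env()
  seen_env$seen <- logical(n)
  emit <- function(v) {
    if (!seen_env$seen[v] && arc_count[v] > 0L)
      for (k in seq_len(arc_count[v])) push("/")
    seen_env$seen[v] <- TRUE
    push(sub$elements[v])
    for (c in trav$children[[v]]) {
      push(glyph(v, c))
      emit(c)
      push(glyph(v, c))
      push(sub$elements[v])
    }
  }
  root <- which(trav$rank == 1L)
  emit(root)
  toks[seq_len(pos)]
}

#' Emit the descriptor token list of one component of a spanning forest
#'
#' @param g the parent [molgraph()] (kept for interface symmetry; the
#'   component carries its own subgraph).
#' @param forest a [build_spanning_forest()] result.
#' @param component component number (position in `forest$components`).
#' @param flatten_bonds emit every bond as `"-"` instead of the faithful
#'   order glyphs.
#' @return character vector of tokens.
#' @export
emit_component <- function(g, forest, component, flatten_bonds = FALSE) {
  d <- forest$components[[component]]
  emit_tokens(d$graph, d$order, flatten_bonds = flatten_bonds)
}

#' Generate the canonical graph-based descriptor of a molecule
#'
#' Runs the full pipeline: connected components, Morgan canonical order,
#' depth-first spanning tree, Euler-tour emission. Components are emitted
#' independently, ordered by size (descending) then rendered text
#' (ascending), and joined with `"."`. The result is canonical: any
#' relabeling of the input atoms yields the byte-identical string.
#'
#' @param g a [molgraph()].
#' @param flatten_bonds logical; emit all bonds as `"-"` (single-bond
#'   glyph) instead of the faithful `-`/`=`/`#`. Default `FALSE`.
#' @return object of class `gbmd`: `text` (the rendered string), `tokens`
#'   (character vector), `name`. An empty graph yields the empty string.
#' @examples
#' eth <- molgraph(c("C", "C", "O"),
#'                 data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))
#' generate_gbmd(eth)$text  # "C-C-C-O-C"
#' @export
generate_gbmd <- function(g, flatten_bonds = FALSE) {
  stopifnot(inherits(g, "molgraph"))
  forest <- build_spanning_forest(g)
  parts <- lapply(seq_along(forest$components), function(k)
    emit_component(g, forest, k, flatten_bonds = flatten_bonds))
  if (length(parts) == 0L)
    return(structure(list(text = "", tokens = character(0), name = g$name),
                     class = "gbmd"))
  texts <- vapply(parts, paste, character(1), collapse = "")
  sizes <- vapply(forest$components, function(d) n_atoms(d$graph), integer(1))
  ok <- order(-sizes, texts, method = "radix")
  parts <- parts[ok]; texts <- texts[ok]
  tokens <- parts[[1]]
  for (k in seq_along(parts)[-1]) tokens <- c(tokens, ".", parts[[k]])
  structure(list(text = paste(tokens, collapse = ""), tokens = tokens,
                 name = g$name),
            class = "gbmd")
}

#' @export
print.gbmd <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' @export
format.gbmd <- function(x, ...) x$text

#' Tokenize a rendered descriptor string
#'
#' Inverse of rendering: splits a descriptor back into its token list.
#' Two-letter element symbols are unambiguous because their second
#' character is lower case (Rule 1). The en-dash sometimes used in print
#' for single bonds is normalized to ASCII `"-"`.
#'
#' @param text a single descriptor string.
#' @return character vector of tokens.
#' @export
tokenize_gbmd <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("–", "-", text)
  ch <- strsplit(text, "")[[1]]
  toks <- character(0)
  i <- 1L
  while (i <= length(ch)) {
    c1 <- ch[i]
    if (grepl("^[A-Z]$", c1)) {
      if (i < length(ch) && grepl("^[a-z]$", ch[i + 1L])) {
        toks <- c(toks, paste0(c1, ch[i + 1L])); i <- i + 2L
      } else { toks <- c(toks, c1); i <- i + 1L }
    } else if (c1 %in% c("-", "=", "#", "/", ".")) {
      toks <- c(toks, c1); i <- i + 1L
    } else {
      stop("unknown character '", c1, "' at position ", i)
    }
  }
  toks
}

#' Render a token list back to descriptor text
#'
#' @param tokens character vector of tokens (or a `gbmd` object).
#' @return single string; `tokenize_gbmd(render_gbmd(x))` recovers `x`.
#' @export
render_gbmd <- function(tokens) {
  if (inherits(tokens, "gbmd")) return(tokens$text)
  paste(tokens, collapse = "")
}

# Coerce descriptor-ish inputs (gbmd object, token vector, or rendered
# string) to a token vector.
as_tokens <- function(x) {
  if (inherits(x, "gbmd")) return(x$tokens)
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L &&
      !x %in% c("-", "=", "#", "/", "."))
    return(tokenize_gbmd(x))
  as.character(x)
}
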