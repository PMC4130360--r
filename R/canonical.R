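# Canonical atom ordering via Morgan extended connectivity with
# deterministic, input-order-independent tie-breaking.

#' Morgan extended-connectivity values
#'
#' Classic Morgan relaxation on a connected graph: EC0(v) = degree(v),
#' ECi(v) = sum of the neighbors' EC(i-1). Iteration continues while the
#' number of distinct values strictly increases; the assignment in force
#' before the count stops increasing is returned.
#'
#' @param g a connected [molgraph()] (callers iterate over components).
#' @param trace keep the per-iteration value vectors (for inspecting the
#'   relaxation, e.g. via the command-line `debug-canon` tool).
#' @return list of class `ec_assignment`: `values` (numeric, per atom),
#'   `iteration` (number of relaxation steps kept), `num_classes`, and,
#'   with `trace = TRUE`, `history` (list of per-iteration values
#'   including the rejected final sweep).
#' @export
morgan_ec <- function(g, trace = FALSE) {
  n <- n_atoms(g)
  if (n == 0L) stop("morgan_ec needs at least one atom")
  a <- adjacency(g)$adj
  ec <- vapply(a, length, integer(1))
  ec <- as.numeric(ec)
  k <- length(unique(ec))
  iter <- 0L
  history <- list(ec)
  repeat {
    ec2 <- vapply(seq_len(n), function(v) sum(ec[a[[v]]]), numeric(1))
    k2 <- length(unique(ec2))
    history[[length(history) + 1L]] <- ec2
    if (k2 > k) { ec <- ec2; k <- k2; iter <- iter + 1L } else break
  }
  out <- list(values = ec, iteration = iter, num_classes = k)
  if (trace) out$history <- history
  structure(out, class = "ec_assignment")
}

# Iterative partition refinement used to resolve ties that the composite
# priority key leaves open. Initial colors come from (EC value, element);
# atoms in `anchors` (already-numbered atoms during a traversal) get
# unique colors from their canonical rank, which individualizes them and
# propagates their positions through the graph. Colors are ranks of
# lexicographically sorted signature strings, hence invariant under atom
# relabeling. Refinement stops when the class count stops growing.
refine_colors <- function(adj, bond_ord, ec, elements, anchors = integer(0),
                          anchor_rank = integer(0)) {
  n <- length(elements)
  init <- sprintf("%020.0f|%s", ec, elements)
  if (length(anchors) > 0L)
    init[anchors] <- sprintf("ANCHOR|%06d", anchor_rank)
  colors <- match(init, sort(unique(init), method = "radix"))
  k <- length(unique(colors))
  repeat {
    sig <- vapply(seq_len(n), function(v) {
      nb <- adj[[v]]
      if (length(nb) == 0L) return(sprintf("%d|", colors[v]))
      lab <- sprintf("%d:%d", bond_ord[cbind(v, nb)], colors[nb])
      sprintf("%d|%s", colors[v],
              paste(sort(lab, method = "radix"), collapse = ","))
    }, character(1))
    new <- match(sig, sort(unique(sig), method = "radix"))
    k2 <- length(unique(new))
    if (k2 > k) { colors <- new; k <- k2 } else break
  }
  colors
}

# Deterministic depth-first traversal from `root`. At each atom the next
# child is the unvisited neighbor with the best composite key:
# (final EC descending, element symbol ascending, order of the bond to the
# current atom descending). Residual ties are broken by anchored partition
# refinement over the whole graph, in which every already-numbered atom
# carries a unique color; tied candidates that survive that refinement are
# equivalent under an automorphism fixing the numbered region, so either
# choice yields the same emitted descriptor.
canon_traverse <- function(g, root, prep = NULL) {
  n <- n_atoms(g)
  if (is.null(prep)) prep <- canon_prep(g)
  adj <- prep$adj; bond_ord <- prep$order
  ec <- prep$ec; erank <- prep$erank
  rank <- integer(n); parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  nxt <- 0L
  visit_order <- integer(n)
  visit <- function(v) {
    nxt <<- nxt + 1L
    rank[v] <<- nxt
    visit_order[nxt] <<- v
    repeat {
      cand <- adj[[v]][rank[adj[[v]]] == 0L]
      if (length(cand) == 0L) return(invisible(NULL))
      if (length(cand) > 1L) {
        key <- order(-ec[cand], erank[cand], -bond_ord[v, cand])
        cand <- cand[key]
        top <- cand[ec[cand] == ec[cand[1]] &
                    erank[cand] == erank[cand[1]] &
                    bond_ord[v, cand] == bond_ord[v, cand[1]]]
        if (length(top) > 1L) {
          visited <- which(rank > 0L)
          colors <- refine_colors(adj, bond_ord, ec, g$elements,
                                  anchors = visited,
                                  anchor_rank = rank[visited])
          top <- top[colors[top] == min(colors[top])]
        }
        c1 <- top[1]
      } else c1 <- cand[1]
      children[[v]] <<- c(children[[v]], c1)
      parent[c1] <<- v
      visit(c1)
    }
  }
  visit(root)
  list(rank = rank, parent = parent, children = children,
       visit_order = visit_order)
}

canon_prep <- function(g) {
  a <- adjacency(g)
  ec <- morgan_ec(g)$values
  erank <- match(g$elements, sort(unique(g$elements), method = "radix"))
  list(adj = a$adj, order = a$order, ec = ec, erank = erank)
}

# Root candidates: maximal EC, then lexicographically smallest element,
# then smallest refined color. If several candidates survive, the full
# descriptor is emitted from each and the lexicographically smallest
# rendered text wins (candidates surviving refinement are almost always
# automorphic, in which case the strings coincide and the choice is
# immaterial).
canon_root <- function(g, prep) {
  n <- n_atoms(g)
  if (n == 1L) return(list(root = 1L, trav = canon_traverse(g, 1L, prep)))
  cand <- which(prep$ec == max(prep$ec))
  cand <- cand[prep$erank[cand] == min(prep$erank[cand])]
  if (length(cand) > 1L) {
    colors <- refine_colors(prep$adj, prep$order, prep$ec, g$elements)
    cand <- cand[colors[cand] == min(colors[cand])]
  }
  if (length(cand) == 1L)
    return(list(root = cand, trav = canon_traverse(g, cand, prep)))
  best <- NULL
  for (r in cand) {
    trav <- canon_traverse(g, r, prep)
    tok <- emit_tokens(g, trav, prep, flatten_bonds = FALSE)
    txt <- paste(tok, collapse = "")
    if (is.null(best) || txt < best$txt)
      best <- list(root = r, trav = trav, txt = txt)
  }
  list(root = best$root, trav = best$trav)
}

#' Canonical atom ordering of a connected molecular graph
#'
#' The root is the atom with the highest final Morgan EC value, ties
#' broken by element symbol (ascending) and then by partition refinement;
#' remaining atoms are numbered by a depth-first traversal expanding at
#' each step the neighbor with the best priority key (EC descending,
#' element ascending, connecting-bond order descending), residual ties
#' resolved by anchored partition refinement. The resulting ranks are
#' invariant under relabeling of the input atoms (up to automorphism,
#' which leaves the emitted descriptor unchanged).
#'
#' @param g a connected [molgraph()].
#' @return object of class `canonical_order`: `rank` (integer vector,
#'   root = 1), `parent` (NA for the root), `root`, and `ec` (the final
#'   Morgan EC values underlying the priority key).
#' @export
canonical_order <- function(g) {
  if (n_atoms(g) == 0L) stop("canonical_order needs a non-empty graph")
  if (max(component_membership(g)) != 1L)
    stop("canonical_order expects a connected graph; split with connected_components()")
  prep <- canon_prep(g)
  res <- canon_root(g, prep)
  structure(list(rank = res$trav$rank, parent = res$trav$parent,
                 root = res$root, ec = prep$ec,
                 children = res$trav$children),
            class = "canonical_order")
}

#' @export
print.canonical_order <- function(x, ...) {
  cat(sprintf("<canonical_order: %d atoms, root = atom %d>\n",
              length(x$rank), x$root))
  invisible(x)
}
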