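# Seeded generators: random labeled molecular graphs, atom-permutation
# fixtures, and toy activity-class benchmarks. They make the whole
# pipeline testable without a proprietary compound database. Every
# generator takes an explicit seed (no wall-clock default) and restores
# the caller's RNG state.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

DEFAULT_ELEMENT_WEIGHTS <- c(C = 0.70, N = 0.10, O = 0.15, S = 0.05)
DEFAULT_BOND_WEIGHTS <- c(`1` = 0.80, `2` = 0.15, `3` = 0.05)

#' Random connected labeled molecular graph
#'
#' Builds a uniform random recursive spanning tree over `n_atoms` atoms,
#' then adds `n_rings` extra non-duplicate edges (each closes one ring).
#' Elements and bond orders are sampled from the given weights. The
#' result is deterministic for a fixed seed and always satisfies the
#' molecular-graph invariants.
#'
#' @param n_atoms number of atoms (>= 1).
#' @param n_rings number of ring-closing extra edges (>= 0); must not
#'   exceed `n(n-1)/2 - (n-1)`.
#' @param seed integer RNG seed (required).
#' @param element_weights named probability vector over element symbols.
#' @param bond_order_weights named probability vector over orders 1..3.
#' @param name molecule name.
#' @return a [molgraph()].
#' @export
random_molgraph <- function(n_atoms, n_rings = 0L, seed,
                            element_weights = DEFAULT_ELEMENT_WEIGHTS,
                            bond_order_weights = DEFAULT_BOND_WEIGHTS,
                            name = "") {
  n_atoms <- as.integer(n_atoms); n_rings <- as.integer(n_rings)
  if (n_atoms < 1L) stop("n_atoms must be >= 1")
  max_rings <- n_atoms * (n_atoms - 1L) / 2L - (n_atoms - 1L)
  if (n_rings < 0L || n_rings > max_rings)
    stop("n_rings infeasible: at most ", max_rings, " for ", n_atoms, " atoms")
  with_local_seed(seed, {
    elements <- sample(names(element_weights), n_atoms, replace = TRUE,
                       prob = element_weights)
    orders <- as.integer(names(bond_order_weights))
    bi <- integer(0); bj <- integer(0)
    if (n_atoms > 1L) {
      parent <- vapply(2:n_atoms, function(i) sample.int(i - 1L, 1L),
                       integer(1))
      bi <- pmin(parent, 2:n_atoms); bj <- pmax(parent, 2:n_atoms)
    }
    if (n_rings > 0L) {
      have <- paste(bi, bj)
      pairs <- which(upper.tri(matrix(0, n_atoms, n_atoms)), arr.ind = TRUE)
      key <- paste(pairs[, 1], pairs[, 2])
      free <- which(!key %in% have)
      pick <- free[sample.int(length(free), n_rings)]
      bi <- c(bi, pairs[pick, 1]); bj <- c(bj, pairs[pick, 2])
    }
    bo <- sample(orders, length(bi), replace = TRUE,
                 prob = bond_order_weights)
    g <- molgraph(elements, data.frame(i = bi, j = bj, order = bo),
                  name = name)
    validate_molgraph(g)
    g
  })
}

#' Randomly relabel the atoms of a molecular graph
#'
#' Produces an isomorphic graph under a uniformly random permutation of
#' atom indices (bond rows are shuffled as well, so storage order carries
#' no signal). The permutation is attached as attribute `mapping`
#' (`mapping[old] = new`). The emitted canonical descriptor of the result
#' must equal the original's — this is the canonicality property under
#' test.
#'
#' @param g a [molgraph()].
#' @param seed integer RNG seed (required).
#' @return a relabeled `molgraph` with attribute `mapping`.
#' @export
permute_atoms <- function(g, seed) {
  n <- n_atoms(g)
  with_local_seed(seed, {
    perm <- if (n > 0L) sample.int(n) else integer(0)  # perm[old] = new
    elements <- character(n)
    elements[perm] <- g$elements
    b <- g$bonds
    nb <- data.frame(i = perm[b$i], j = perm[b$j], order = b$order)
    if (nrow(nb) > 1L) nb <- nb[sample.int(nrow(nb)), , drop = FALSE]
    out <- molgraph(elements, nb, name = g$name)
    attr(out, "mapping") <- perm
    out
  })
}

# One structure-preserving random edit: element substitution, atom
# addition, or bond rewire (delete a non-bridge bond, add a fresh edge).
# Edits never disconnect the graph.
mutate_molgraph <- function(g, element_weights = DEFAULT_ELEMENT_WEIGHTS,
                            bond_order_weights = DEFAULT_BOND_WEIGHTS) {
  ops <- c("element", "add_atom", "rewire")
  for (attempt in 1:20) {
    op <- sample(ops, 1L)
    n <- n_atoms(g)
    if (op == "element") {
      v <- sample.int(n, 1L)
      alt <- setdiff(names(element_weights), g$elements[v])
      if (length(alt) == 0L) next
      w <- element_weights[alt] / sum(element_weights[alt])
      g2 <- g; g2$elements[v] <- sample(alt, 1L, prob = w)
      return(g2)
    } else if (op == "add_atom") {
      anchor <- sample.int(n, 1L)
      elem <- sample(names(element_weights), 1L, prob = element_weights)
      ord <- as.integer(sample(names(bond_order_weights), 1L,
                               prob = bond_order_weights))
      return(molgraph(c(g$elements, elem),
                      rbind(g$bonds,
                            data.frame(i = anchor, j = n + 1L, order = ord)),
                      name = g$name))
    } else {
      if (nrow(g$bonds) < 2L || n < 3L) next
      k <- sample.int(nrow(g$bonds), 1L)
      g2 <- g; g2$bonds <- g$bonds[-k, , drop = FALSE]
      if (max(component_membership(g2)) != 1L) next  # bridge: would split
      have <- paste(g2$bonds$i, g2$bonds$j)
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      free <- which(!paste(pairs[, 1], pairs[, 2]) %in%
                      c(have, paste(g$bonds$i[k], g$bonds$j[k])))
      if (length(free) == 0L) next
      pick <- free[sample.int(length(free), 1L)]
      ord <- as.integer(sample(names(bond_order_weights), 1L,
                               prob = bond_order_weights))
      g2$bonds <- rbind(g2$bonds,
                        data.frame(i = pairs[pick, 1], j = pairs[pick, 2],
                                   order = ord))
      return(molgraph(g2$elements, g2$bonds, name = g2$name))
    }
  }
  g  # no feasible edit found; return unchanged
}

#' Generate a toy activity-class screening benchmark
#'
#' Emulates the structure of an activity-annotated screening database at
#' desk scale: each class grows from a random seed molecule, and every
#' active is that seed after `edits_per_active` random structure edits
#' (element substitution, atom addition, connectivity-preserving bond
#' rewire) — a small edit radius yields structurally homogeneous classes,
#' a large one heterogeneous classes. Decoys are independent random
#' graphs; reference (query) structures are drawn per class without
#' replacement.
#'
#' @param n_classes number of activity classes.
#' @param actives_per_class actives per class (>= `n_references`).
#' @param n_decoys number of inactive decoy molecules.
#' @param edits_per_active number of random edits applied to the class
#'   seed molecule per active (>= 1).
#' @param n_references reference structures per class (default 10, the
#'   usual screening protocol).
#' @param seed integer RNG seed (required).
#' @param n_atoms_range inclusive range of seed/decoy molecule sizes.
#' @param n_rings_range inclusive range of ring counts.
#' @param cutoff_fraction cutoff for the assembled [screening_run()].
#' @return list with elements `run` (a [screening_run()] whose db items
#'   are `molgraph`s), `graphs` (named list), and `labels`.
#' @export
make_benchmark <- function(n_classes = 5L, actives_per_class = 15L,
                           n_decoys = 80L, edits_per_active = 1L,
                           n_references = 10L, seed,
                           n_atoms_range = c(8L, 16L),
                           n_rings_range = c(0L, 2L),
                           cutoff_fraction = 0.05) {
  if (edits_per_active < 1L) stop("edits_per_active must be >= 1")
  if (actives_per_class < n_references)
    stop("actives_per_class must be >= n_references")
  with_local_seed(seed, {
    graphs <- list(); labels <- character(0); references <- list()
    for (cls in seq_len(n_classes)) {
      clsname <- sprintf("class%02d", cls)
      seed_g <- random_molgraph(
        sample(seq(n_atoms_range[1], n_atoms_range[2]), 1L),
        sample(seq(n_rings_range[1], n_rings_range[2]), 1L),
        seed = sample.int(.Machine$integer.max, 1L))
      for (a in seq_len(actives_per_class)) {
        gi <- seed_g
        for (e in seq_len(edits_per_active)) gi <- mutate_molgraph(gi)
        id <- sprintf("%s_a%02d", clsname, a)
        gi$name <- id
        graphs[[id]] <- gi
        labels[id] <- clsname
      }
      references[[clsname]] <-
        sample(names(labels)[labels == clsname], n_references)
    }
    for (d in seq_len(n_decoys)) {
      id <- sprintf("decoy%03d", d)
      gi <- random_molgraph(
        sample(seq(n_atoms_range[1], n_atoms_range[2]), 1L),
        sample(seq(n_rings_range[1], n_rings_range[2]), 1L),
        seed = sample.int(.Machine$integer.max, 1L), name = id)
      graphs[[id]] <- gi
      labels[id] <- "inactive"
    }
    run <- screening_run(graphs, labels, references,
                         cutoff_fraction = cutoff_fraction)
    list(run = run, graphs = graphs, labels = labels)
  })
}
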