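# Small reference molecules built in code.

make_ethanol <- function() {
  molgraph(c("C", "C", "O"),
           data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)),
           name = "ethanol")
}

make_cyclopropane <- function() {
  molgraph(c("C", "C", "C"),
           data.frame(i = c(1, 1, 2), j = c(2, 3, 3), order = 1L),
           name = "cyclopropane")
}

make_benzene <- function() {
  molgraph(rep("C", 6),
           data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)),
           name = "benzene")
}

make_star <- function(k, center = "C", leaf = "N") {
  molgraph(c(center, rep(leaf, k)),
           data.frame(i = 1L, j = seq_len(k) + 1L, order = 1L),
           name = "star")
}

aspirin_graph <- function() {
  parse_sdf(system.file("extdata", "aspirin.sdf", package = "gbmd"))[[1]]
}

# Union of two graphs as one disconnected molgraph.
graph_union <- function(g1, g2) {
  off <- length(g1$elements)
  molgraph(c(g1$elements, g2$elements),
           rbind(g1$bonds,
                 data.frame(i = g2$bonds$i + off, j = g2$bonds$j + off,
                            order = g2$bonds$order)))
}

atom_token_count <- function(tokens) sum(grepl("^[A-Z][a-z]?$", tokens))

# Deterministic size/ring pick that always respects the feasibility bound
# n_rings <= (n-1)(n-2)/2.
random_test_graph <- function(seed, nmin = 2, nmax = 20, rmax = 3, ...) {
  n <- nmin + (seed * 7L) %% (nmax - nmin + 1L)
  r <- min((seed * 3L) %% (rmax + 1L), (n - 1L) * (n - 2L) / 2L)
  random_molgraph(n, r, seed = seed, ...)
}

cyclomatic_number <- function(g) {
  ncomp <- length(connected_components(g))
  nrow(g$bonds) - length(g$elements) + ncomp
}
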