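test_that("spanning forest splits bonds into tree edges and breaking arcs", {
  f_eth <- build_spanning_forest(make_ethanol())
  expect_equal(nrow(f_eth$tree), 2L)
  expect_equal(nrow(f_eth$arcs), 0L)

  f_cyc <- build_spanning_forest(make_cyclopropane())
  expect_equal(nrow(f_cyc$tree), 2L)
  expect_equal(nrow(f_cyc$arcs), 1L)

  f_asp <- build_spanning_forest(aspirin_graph())
  expect_equal(nrow(f_asp$tree), 12L)
  expect_equal(nrow(f_asp$arcs), 1L)

  # cyclomatic law on random graphs, including disconnected unions
  for (s in 1:15) {
    g <- graph_union(random_test_graph(s, nmin = 2, nmax = 10, rmax = 2),
                     random_test_graph(s + 50, nmin = 2, nmax = 10, rmax = 2))
    f <- build_spanning_forest(g)
    ncomp <- length(connected_components(g))
    expect_equal(nrow(f$tree), length(g$elements) - ncomp)
    expect_equal(nrow(f$arcs), cyclomatic_number(g))
  }
})

test_that("Euler-tour emission reproduces the worked small molecules", {
  expect_equal(generate_gbmd(molgraph("C"))$text, "C")

  eth <- generate_gbmd(make_ethanol())
  expect_equal(eth$tokens, c("C", "-", "C", "-", "C", "-", "O", "-", "C"))
  expect_equal(atom_token_count(eth$tokens), 5L)  # 2n-1

  cyc <- generate_gbmd(make_cyclopropane())
  expect_equal(cyc$text, "/C-C-/C-C-C")
  expect_equal(sum(cyc$tokens == "/"), 2L)

  # acetylene: 2 atoms give 3 atom tokens with the triple-bond glyph
  ac <- molgraph(c("C", "C"), data.frame(i = 1, j = 2, order = 3))
  expect_equal(generate_gbmd(ac)$text, "C#C#C")

  expect_equal(generate_gbmd(molgraph(character(0)))$text, "")
})

test_that("disconnected structures join with periods, larger part first", {
  eth <- make_ethanol()
  twin <- graph_union(eth, eth)
  s <- generate_gbmd(eth)$text
  expect_equal(generate_gbmd(twin)$text, paste(s, s, sep = "."))

  mixed <- graph_union(molgraph("Na"), eth)
  expect_equal(generate_gbmd(mixed)$text, paste(s, "Na", sep = "."))
  expect_equal(sum(generate_gbmd(mixed)$tokens == "."), 1L)
})

test_that("token-count laws hold on random graphs", {
  for (s in 1:25) {
    g <- random_test_graph(s, nmin = 2, nmax = 20, rmax = 4)
    if (s %% 3 == 0)
      g <- graph_union(g, random_molgraph(1L + (s %% 8L), 0, seed = s + 70))
    toks <- generate_gbmd(g)$tokens
    comps <- connected_components(g)
    expect_equal(atom_token_count(toks),
                 sum(vapply(comps, function(cp) 2L * length(cp$elements) - 1L,
                            integer(1))))
    expect_equal(sum(toks == "/"), 2L * cyclomatic_number(g))
    expect_equal(sum(toks == "."), length(comps) - 1L)
  }
})

test_that("descriptor is sensitive to single-atom and single-bond edits", {
  for (s in 1:12) {
    g <- random_molgraph(sample(5:15, 1), sample(0:2, 1), seed = s)
    ref <- generate_gbmd(g)$text

    g_elem <- g
    v <- (s %% length(g$elements)) + 1L
    g_elem$elements[v] <- if (g$elements[v] == "C") "N" else "C"
    expect_false(identical(generate_gbmd(g_elem)$text, ref))

    # bond-order edits are guaranteed visible on spanning-tree bonds;
    # a breaking arc's order is never rendered (the closure is only a "/")
    tree <- build_spanning_forest(g)$tree
    treerow <- which(paste(g$bonds$i, g$bonds$j) %in% paste(tree$i, tree$j))
    k <- treerow[(s %% length(treerow)) + 1L]
    g_bond <- g
    g_bond$bonds$order[k] <- if (g$bonds$order[k] == 1L) 2L else 1L
    expect_false(identical(generate_gbmd(g_bond)$text, ref))
  }
})

test_that("a ring-closure bond's order can be silent in the rendered string", {
  # the grammar marks a breaking arc only with "/"; when the arc never
  # decides a traversal priority, flipping its order leaves the text as is
  g <- parse_edgelist(c("atom 0 C", "atom 1 C", "atom 2 C", "atom 3 N",
                        "atom 4 C", "atom 5 N",
                        "bond 0 1 1", "bond 0 2 1", "bond 1 3 1",
                        "bond 1 4 1", "bond 2 3 3", "bond 2 5 1"))
  f <- build_spanning_forest(g)
  row <- which(g$bonds$i == f$arcs$i[1] & g$bonds$j == f$arcs$j[1])
  g2 <- g
  g2$bonds$order[row] <- if (g$bonds$order[row] == 1L) 2L else 1L
  expect_identical(generate_gbmd(g2)$text, generate_gbmd(g)$text)
})

test_that("repeated emission is byte-identical", {
  g <- random_molgraph(18, 3, seed = 99)
  expect_identical(generate_gbmd(g)$text, generate_gbmd(g)$text)
  expect_identical(generate_gbmd(g, flatten_bonds = TRUE)$text,
                   generate_gbmd(g, flatten_bonds = TRUE)$text)
})

test_that("tokenizer splits symbols and inverts rendering", {
  expect_equal(tokenize_gbmd("C-Br-C"), c("C", "-", "Br", "-", "C"))
  expect_equal(tokenize_gbmd("/C-C"), c("/", "C", "-", "C"))
  expect_error(tokenize_gbmd("C?C"), "position 2")
  # en-dash in printed strings normalizes to the ASCII single-bond glyph
  expect_equal(tokenize_gbmd("C–C"), c("C", "-", "C"))

  for (s in 1:10) {
    g <- random_test_graph(s, nmin = 3, nmax = 15,
                           element_weights = c(C = 0.5, Br = 0.2, Cl = 0.2,
                                               N = 0.1))
    toks <- generate_gbmd(g)$tokens
    expect_identical(tokenize_gbmd(render_gbmd(toks)), toks)
  }
})

test_that("emit_component matches the assembled descriptor per component", {
  g <- graph_union(make_cyclopropane(), make_ethanol())
  forest <- build_spanning_forest(g)
  toks <- lapply(seq_along(forest$components), function(k)
    emit_component(g, forest, k))
  texts <- sort(vapply(toks, paste, character(1), collapse = ""))
  expect_equal(texts, sort(c("/C-C-/C-C-C", "C-C-C-O-C")))
})
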