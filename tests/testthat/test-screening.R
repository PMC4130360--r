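test_that("database ranking sorts by score with stable ties", {
  db <- list(m1 = 0.2, m2 = 0.9, m3 = 0.5)
  simfn <- function(q, item) item
  expect_equal(rank_database(NULL, db, simfn), c("m2", "m3", "m1"))

  ties <- list(a = 1, b = 1, c = 1)
  expect_equal(rank_database(NULL, ties, simfn), c("a", "b", "c"))

  expect_equal(rank_database(NULL, list(), simfn), character(0))

  # the query itself is excluded before ranking
  expect_equal(rank_database(NULL, db, simfn, query_id = "m2"),
               c("m3", "m1"))
})

test_that("recall honors the half-up cutoff count", {
  ranked <- sprintf("x%03d", 1:200)
  actives <- c("x001", "x002", sprintf("a%d", 1:8))  # 10 actives, 2 retrievable
  expect_equal(recall_at(ranked, actives, 0.01), 20)     # k = 2
  expect_equal(recall_at(ranked, c("x001", "x003"), 0.99), 100)
  expect_equal(recall_at(ranked, sprintf("a%d", 1:5), 0.05), 0)
  expect_error(recall_at(ranked, character(0), 0.01), "no actives")
  expect_error(recall_at(ranked, "x001", 0), "fraction")

  # half-up rounding of k: 150 * 0.01 = 1.5 rounds to k = 2
  r150 <- sprintf("y%03d", 1:150)
  expect_equal(recall_at(r150, c("y001", "y002"), 0.01), 100)

  # monotone non-decreasing in the cutoff fraction
  set.seed(3)
  act <- sample(ranked, 20)
  rec <- vapply(c(0.01, 0.05, 0.1, 0.5), function(f)
    recall_at(ranked, act, f), numeric(1))
  expect_true(all(diff(rec) >= 0))
})

test_that("class recall averages the reference searches", {
  # 101 molecules; cutoff 0.05 of the 100 searched gives k = 5
  ids <- c("r1", "r2", sprintf("a%d", 1:8), sprintf("d%02d", 1:91))
  labels <- setNames(c(rep("A", 10), rep("inactive", 91)), ids)
  score <- function(q, item) item   # db items are plain scores per query
  db_for <- function(top_actives) {
    # actives placed either just inside or far outside the top 5
    sc <- setNames(rep(0, length(ids)), ids)
    sc[sprintf("a%d", 1:8)] <- 0.1     # actives below the decoys...
    sc[sprintf("d%02d", 1:91)] <- 0.5  # ...so only boosted ones rank top-5
    sc[top_actives] <- 10
    as.list(sc)
  }
  # query r1 retrieves 3 of its 9 class mates in the top 5; r2 none
  run <- screening_run(db_for(c("a1", "a2", "a3")), labels,
                       list(A = c("r1", "r2")), cutoff_fraction = 0.05)
  r1 <- rank_database(NULL, run$db, score, query_id = "r1")
  expect_equal(recall_at(r1, setdiff(names(labels)[labels == "A"], "r1"),
                         0.05), 100 * 3 / 9)

  run1 <- screening_run(db_for(c("a1", "a2", "a3")), labels,
                        list(A = "r1"), cutoff_fraction = 0.05)
  expect_equal(class_recall(run1, "A", score), 100 * 3 / 9)

  # two references: mean of the individual recalls (here both searches
  # see the same scores, so r2 also finds the 3 boosted actives)
  expect_equal(class_recall(run, "A", score), 100 * 3 / 9)
})

test_that("screening_run validates its wiring", {
  db <- list(a = 1, b = 2)
  labels <- c(a = "A", b = "B")
  expect_error(screening_run(db, labels, list(A = "zz")), "not in db")
  expect_error(screening_run(db, labels, list(A = "b")), "disagree")
  expect_error(screening_run(db, c(a = "A"), list(A = "a")), "label")
  expect_error(screening_run(db, labels, list(A = "a"), cutoff_fraction = 2),
               "cutoff")
})

test_that("column means and bold-cell counts follow the table conventions", {
  m <- recall_matrix(matrix(c(10, 30, 20, 20), 2, 2,
                            dimnames = list(c("c1", "c2"), c("X", "Y"))))
  expect_equal(mean_row(m), c(X = 20, Y = 20))
  expect_equal(unname(mean_row(recall_matrix(
    matrix(c(5, 7), 1, 2, dimnames = list("c", c("X", "Y")))))), c(5, 7))
  expect_equal(unname(mean_row(recall_matrix(
    matrix(0, 3, 2, dimnames = list(1:3, c("X", "Y")))))[1]), 0)

  # ties bold every tied cell; a dominated column counts zero
  tie <- recall_matrix(matrix(c(5, 5), 1, 2,
                              dimnames = list("c", c("X", "Y"))))
  expect_equal(unname(bold_cells(tie, include_mean = FALSE)), c(1L, 1L))
  dom <- recall_matrix(matrix(c(9, 8, 1, 2), 2, 2,
                              dimnames = list(c("c1", "c2"), c("X", "Y"))))
  expect_equal(unname(bold_cells(dom, include_mean = FALSE)), c(2L, 0L))
  # with the mean row, the winning column collects one more
  expect_equal(unname(bold_cells(dom)), c(3L, 0L))
  # every row has at least one maximum
  expect_gte(sum(bold_cells(dom, include_mean = FALSE)), nrow(dom))
})

test_that("half-up rendering differs from banker's rounding where it must", {
  m <- recall_matrix(matrix(c(11.465, 11.475), 1, 2,
                            dimnames = list("c", c("X", "Y"))))
  expect_equal(unname(mean_row(m, digits = 2)), c(11.47, 11.48))
})

test_that("Kendall W spans perfect agreement to complete discordance", {
  agree <- recall_matrix(matrix(rep(c(40, 30, 20, 10), 3), 3, 4, byrow = TRUE,
                                dimnames = list(1:3, LETTERS[1:4])))
  k <- kendall_w(agree)
  expect_equal(k$W, 1)
  expect_equal(k$df, 3L)
  expect_equal(k$ranking, "A > B > C > D")

  discord <- recall_matrix(matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE,
                                  dimnames = list(1:2, c("A", "B"))))
  expect_equal(kendall_w(discord)$W, 0)

  expect_error(kendall_w(agree[1, , drop = FALSE]), "at least 2")
  expect_error(kendall_w(agree[, 1, drop = FALSE]), "at least 2")
})

test_that("Kendall W is rank-based and matches vegan's tie-corrected value", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(8 * 5, 0, 100), 8, 5,
                dimnames = list(1:8, LETTERS[1:5]))
    k1 <- kendall_w(recall_matrix(m))
    # strictly monotone per-judge transforms leave W unchanged
    m2 <- t(apply(m, 1, function(r) 0.9 * r + 5))
    dimnames(m2) <- dimnames(m)
    expect_equal(kendall_w(recall_matrix(m2))$W, k1$W)
    # vegan treats columns as judges, so hand it the transpose
    ref <- suppressWarnings(vegan::kendall.global(t(m)))
    expect_equal(k1$W, unname(ref$Concordance_analysis["W", 1]),
                 tolerance = 1e-10)
  }
})

test_that("recall matrices round-trip through CSV", {
  m <- mddr_recall_matrix("ds1", 1)
  expect_equal(dim(m), c(11L, 7L))
  expect_equal(colnames(m)[1], "GBMD")
  path <- tempfile(fileext = ".csv")
  write_recall_matrix(m, path)
  m2 <- read_recall_matrix(path)
  expect_equal(unclass(m2), unclass(m))
  expect_error(recall_matrix(matrix(c(1, NA), 1, 2)), "missing")
  expect_error(recall_matrix(matrix(c(1, 101), 1, 2)), "0, 100")
})
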