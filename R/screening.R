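# Virtual-screening protocol and result statistics: ranked retrieval,
# recall at a top-percentage cutoff, per-class averaging over reference
# structures, table statistics (column means, best-in-row counts) and the
# tie-corrected Kendall coefficient of concordance.

#' Rank a database against a query by similarity
#'
#' Scores every database entry against the query and sorts by score
#' descending; ties keep database input order (stable sort). When
#' `query_id` is given, that entry is removed from the database before
#' ranking — retrieving the query itself is uninformative and would
#' inflate recall.
#'
#' @param query query item (descriptor tokens, `gbmd`, fingerprint, ...).
#' @param db named list of database items (names are molecule ids).
#' @param simfn function `(query, item) -> numeric score`.
#' @param query_id optional id to exclude from `db`.
#' @return character vector of ids, best first (empty db gives empty).
#' @export
rank_database <- function(query, db, simfn, query_id = NULL) {
  if (length(db) == 0L) return(character(0))
  if (is.null(names(db)) || any(!nzchar(names(db))))
    stop("db must be a fully named list (names are molecule ids)")
  if (!is.null(query_id)) db <- db[names(db) != query_id]
  scores <- vapply(db, function(item) as.numeric(simfn(query, item)),
                   numeric(1))
  names(db)[order(-scores)]  # order() is stable: ties keep input order
}

#' Recall in the top fraction of a ranking
#'
#' The cutoff count is `k = round(fraction * N)` (half-up); recall is the
#' percentage of the active set found in the top k.
#'
#' @param ranked character vector of ids, best first.
#' @param active_ids ids of the actives sought.
#' @param fraction cutoff fraction in (0, 1), e.g. 0.01 or 0.05.
#' @return recall percentage in \[0, 100\].
#' @export
recall_at <- function(ranked, active_ids, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  active_ids <- unique(active_ids)
  if (length(active_ids) == 0L) stop("no actives: recall undefined")
  k <- floor(fraction * length(ranked) + 0.5)
  100 * length(intersect(head(ranked, k), active_ids)) / length(active_ids)
}

#' Assemble a screening run
#'
#' @param db named list of items searchable by a similarity function.
#' @param labels named character vector mapping every db id to its
#'   activity-class label (decoys may share an "inactive" label).
#' @param references named list: class -> character vector of reference
#'   (query) ids, each belonging to that class.
#' @param cutoff_fraction top-list fraction in (0, 1).
#' @return object of class `screening_run`.
#' @export
screening_run <- function(db, labels, references, cutoff_fraction = 0.01) {
  if (cutoff_fraction <= 0 || cutoff_fraction >= 1)
    stop("cutoff_fraction must be in (0,1)")
  if (is.null(names(db))) stop("db must be named by molecule id")
  if (!all(names(db) %in% names(labels)))
    stop("every db id needs a label")
  for (cls in names(references)) {
    refs <- references[[cls]]
    if (!all(refs %in% names(db))) stop("reference not in db: class ", cls)
    if (!all(labels[refs] == cls))
      stop("reference labels disagree with class ", cls)
  }
  structure(list(db = db, labels = labels, references = references,
                 cutoff_fraction = cutoff_fraction),
            class = "screening_run")
}

#' Mean recall of one activity class under one similarity function
#'
#' Each reference structure of the class is used as a query against the
#' database (query excluded); recall at the run's cutoff is averaged over
#' the references. The denominator of each search is the set of class
#' actives remaining in the searched database (class members minus the
#' query).
#'
#' @param run a [screening_run()].
#' @param class activity-class label.
#' @param simfn function `(query, item) -> numeric score`.
#' @return mean recall percentage.
#' @export
class_recall <- function(run, class, simfn) {
  refs <- run$references[[class]]
  if (is.null(refs) || length(refs) == 0L)
    stop("no references for class ", class)
  members <- names(run$labels)[run$labels == class]
  members <- intersect(members, names(run$db))
  recalls <- vapply(refs, function(ref) {
    ranked <- rank_database(run$db[[ref]], run$db, simfn, query_id = ref)
    recall_at(ranked, setdiff(members, ref), run$cutoff_fraction)
  }, numeric(1))
  mean(recalls)
}

#' Run a screening benchmark over several similarity functions
#'
#' Builds the activity-classes x descriptors recall matrix: one row per
#' class with references, one column per named similarity function.
#'
#' @param run a [screening_run()].
#' @param simfns named list of similarity functions; names become the
#'   descriptor column names.
#' @return a [recall_matrix()].
#' @export
run_screening <- function(run, simfns) {
  classes <- names(run$references)
  m <- vapply(simfns, function(f)
    vapply(classes, function(cls) class_recall(run, cls, f), numeric(1)),
    numeric(length(classes)))
  m <- matrix(m, nrow = length(classes),
              dimnames = list(classes, names(simfns)))
  recall_matrix(m)
}

#' Recall matrix (activity classes x descriptors)
#'
#' @param m numeric matrix of recall percentages with row names (activity
#'   classes) and column names (descriptor types); no missing cells.
#' @return the matrix with class `recall_matrix`.
#' @export
recall_matrix <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("recall matrix has missing cells")
  if (any(m < 0 | m > 100)) stop("recall values must lie in [0, 100]")
  class(m) <- c("recall_matrix", "matrix", "array")
  m
}

#' Read a recall matrix from CSV
#'
#' Expects a header row of descriptor names and a first column of
#' activity-class labels.
#'
#' @param path CSV file path.
#' @return a [recall_matrix()].
#' @export
read_recall_matrix <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  recall_matrix(m)
}

#' Write a recall matrix to CSV
#'
#' @param m a [recall_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recall_matrix <- function(m, path) {
  d <- data.frame(class = rownames(m), unclass(m), check.names = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Half-up rounding to `digits` decimals (base round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Column means of a recall matrix
#'
#' Unweighted mean over the activity classes for each descriptor, the
#' "Mean" row of a results table. Arithmetic is done at full precision;
#' rounding (half-up, 2 decimals) happens only at rendering.
#'
#' @param m a [recall_matrix()].
#' @param digits decimals for the rendered value, or `NA` for full
#'   precision.
#' @return named numeric vector of per-descriptor means.
#' @export
mean_row <- function(m, digits = NA) {
  mu <- colMeans(unclass(m))
  if (!is.na(digits)) mu <- round_half_up(mu, digits)
  mu
}

#' Best-in-row ("bold cell") counts per descriptor
#'
#' A cell is bold when it equals its row maximum (ties leave all tied
#' cells bold). The mean row is appended and scanned along with the
#' activity-class rows, matching the published tables' counting
#' convention; comparisons use the full-precision cell values.
#'
#' @param m a [recall_matrix()].
#' @param include_mean append the column-mean row before counting
#'   (default `TRUE`).
#' @return named integer vector of per-descriptor bold-cell counts.
#' @export
bold_cells <- function(m, include_mean = TRUE) {
  x <- unclass(m)
  if (include_mean) x <- rbind(x, Mean = colMeans(x))
  counts <- integer(ncol(x))
  for (r in seq_len(nrow(x)))
    counts <- counts + as.integer(x[r, ] == max(x[r, ]))
  setNames(counts, colnames(x))
}

#' Kendall coefficient of concordance over a recall matrix
#'
#' Activity classes act as judges, descriptor types as objects: each row
#' is converted to ranks (average ranks for ties, higher recall = better
#' rank) and agreement across rows is measured by the tie-corrected
#' Kendall W, with significance from the chi-square approximation
#' (chi2 = m (n - 1) W on n - 1 degrees of freedom for m judges and n
#' objects). The overall ranking string orders descriptors by mean rank;
#' descriptors with equal mean ranks are joined with `"="` and ordered
#' between themselves by mean recall.
#'
#' @param m a [recall_matrix()] with >= 2 rows and >= 2 columns.
#' @return object of class `kendall_result`: `W`, `chi2`, `df`, `p`,
#'   `ranking` (string such as `"A > B = C > D"`), and `mean_ranks`.
#' @export
kendall_w <- function(m) {
  x <- unclass(as.matrix(m))
  mj <- nrow(x); n <- ncol(x)
  if (mj < 2L || n < 2L)
    stop("kendall_w needs at least 2 judges and 2 objects")
  R <- t(apply(x, 1, function(row) rank(-row)))   # rank 1 = best
  S <- sum((colSums(R) - mj * (n + 1) / 2)^2)
  Tj <- sum(apply(R, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  W <- 12 * S / (mj^2 * (n^3 - n) - mj * Tj)
  chi2 <- mj * (n - 1) * W
  df <- n - 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  mean_ranks <- colMeans(R)
  mean_recall <- colMeans(x)
  ord <- order(mean_ranks, -mean_recall)
  seps <- ifelse(diff(mean_ranks[ord]) == 0, " = ", " > ")
  ranking <- paste0(colnames(x)[ord], c(seps, ""), collapse = "")
  structure(list(W = W, chi2 = chi2, df = df, p = p, ranking = ranking,
                 mean_ranks = mean_ranks),
            class = "kendall_result")
}

#' @export
print.kendall_result <- function(x, ...) {
  cat(sprintf("Kendall W = %.3f (chi2 = %.2f, df = %d, p = %.4g)\n",
              x$W, x$chi2, x$df, x$p))
  cat("Ranking:", x$ranking, "\n")
  invisible(x)
}

#' Published MDDR recall matrices
#'
#' The recall tables of the original MDDR virtual-screening study
#' (datasets DS1-DS3, top-1% and top-5% cutoffs, seven descriptor types)
#' shipped as plain-text CSVs. They are the inputs to the table
#' statistics — the underlying compound database is proprietary, but the
#' published per-class recalls are re-analyzable.
#'
#' @param dataset `"ds1"`, `"ds2"` or `"ds3"`.
#' @param cutoff 1 or 5 (top percentage).
#' @return a [recall_matrix()] with activity-index row names.
#' @export
mddr_recall_matrix <- function(dataset = c("ds1", "ds2", "ds3"), cutoff = 1) {
  dataset <- match.arg(dataset)
  stopifnot(cutoff %in% c(1, 5))
  f <- system.file("extdata",
                   sprintf("mddr_%s_top%dpct.csv", dataset, cutoff),
                   package = "gbmd", mustWork = TRUE)
  read_recall_matrix(f)
}
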