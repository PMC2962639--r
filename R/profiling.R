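#' @include adaptive.R
NULL

#' Composite score of the surviving alignments for one (query, profile) pair
#'
#' `(number of survivors) x (mean identity fraction) x (maximum coverage
#' fraction)`; identities and coverages enter as fractions in [0, 1], so the
#' score is bounded by the survivor count and is 0 exactly when there are no
#' survivors. Survivors from both seed terminals are pooled per profile
#' before scoring.
#'
#' @param survivors list of [FinalAlignment-class] objects (post-filter), or
#'   a [SearchResult-class].
#' @return non-negative numeric score.
#' @export
#' @examples
#' compositeScore(list())  # 0
compositeScore <- function(survivors) {
  if (is(survivors, "SearchResult")) survivors <- survivors@alignments
  if (length(survivors) == 0L) return(0)
  ids <- vapply(survivors, identityPct, numeric(1)) / 100
  cov <- vapply(survivors, coveragePct, numeric(1)) / 100
  length(survivors) * mean(ids) * max(cov)
}

#' Build the N x M alignment-profile matrix
#'
#' Entry (i, j) is the composite score of query i against profile j under
#' the chosen search strategy. Rows are alignment profiles: the vector
#' embedding of one query in the M-dimensional PSSM space.
#'
#' @param queries named character vector of query residue strings.
#' @param profiles list of [ScoringProfile-class] objects.
#' @param method `"adaptive"` (default) or `"exhaustive"`.
#' @inheritParams adaptiveSearch
#' @param ... further arguments passed to the search function.
#' @return numeric N x M matrix with query ids as row names and profile ids
#'   as column names.
#' @export
buildProfileMatrix <- function(queries, profiles,
                               method = c("adaptive", "exhaustive"),
                               p = 10, thresholds = filterThresholds(),
                               gap = gapParams(), matrix = NULL,
                               alpha = 0.05, terminals = c("N", "C"), ...) {
  method <- match.arg(method)
  stopifnot(length(queries) >= 1L, length(profiles) >= 1L)
  search <- if (method == "adaptive") adaptiveSearch else exhaustiveSearch
  qids <- names(queries)
  if (is.null(qids)) qids <- paste0("query", seq_along(queries))
  pids <- vapply(profiles, profileId, character(1))
  mat <- base::matrix(0, length(queries), length(profiles),
                      dimnames = list(qids, pids))
  for (i in seq_along(queries)) {
    for (j in seq_along(profiles)) {
      res <- search(queries[[i]], profiles[[j]], p = p,
                    thresholds = thresholds, gap = gap, matrix = matrix,
                    alpha = alpha, terminals = terminals,
                    queryId = qids[i], ...)
      mat[i, j] <- compositeScore(res)
    }
  }
  mat
}

#' Similarity between two alignment profiles
#'
#' @param a,b numeric vectors of equal length (rows of the profile matrix).
#' @param metric `"pearson"` (correlation, in [-1, 1]) or `"euclidean"`
#'   (distance, >= 0).
#' @return the similarity/distance; `NA` for Pearson when either vector is
#'   constant (undefined correlation, excluded from rankings).
#' @export
profileSimilarity <- function(a, b, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(length(a) == length(b))
  if (metric == "euclidean") return(sqrt(sum((a - b)^2)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' @describeIn profileSimilarity all-pairs similarity matrix over the rows of
#'   a profile matrix (diagonal set to `NA`).
#' @param mat numeric profile matrix (queries in rows).
#' @export
similarityMatrix <- function(mat, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  n <- nrow(mat)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i, j] <- profileSimilarity(mat[i, ], mat[j, ], metric)
  out
}

#' Top-k ROC curve for fold recognition
#'
#' For each query, the other queries are ranked by similarity (descending;
#' ties broken by query id, lexicographically); at each rank cutoff `k` the
#' top-k are the predicted positives and the query's own fold-group members
#' are the true positives. Sensitivity `TP/(TP+FN)` and false positive rate
#' `FP/(FP+TN)` are averaged over queries; queries whose group has a single
#' member contribute no sensitivity term, and candidates with undefined
#' (missing) similarity are excluded from the ranking.
#'
#' @param sim square similarity matrix from [similarityMatrix()] (higher =
#'   more similar; the diagonal is ignored).
#' @param labels named character/factor vector assigning each query id to a
#'   fold group.
#' @param kMax largest rank cutoff (default 40; truncated to N - 1).
#' @return data frame with one row per `k`: pooled `TP`, `FP`, `TN`, `FN`
#'   counts and per-query-averaged `sensitivity` and `fpr`, both
#'   nondecreasing in `k`.
#' @export
rocCurve <- function(sim, labels, kMax = 40L) {
  ids <- rownames(sim)
  stopifnot(!is.null(ids), all(ids %in% names(labels)))
  labels <- as.character(labels[ids])
  n <- length(ids)
  kMax <- min(as.integer(kMax), n - 1L)
  ranked <- lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    s <- sim[i, others]
    keep <- !is.na(s)
    others <- others[keep]; s <- s[keep]
    others[order(-s, ids[others])]
  })
  out <- lapply(seq_len(kMax), function(k) {
    TP <- FP <- TN <- FN <- 0L
    sens <- fpr <- numeric(0)
    for (i in seq_len(n)) {
      cand <- ranked[[i]]
      pos <- cand[labels[cand] == labels[i]]
      top <- head(cand, k)
      tp <- sum(labels[top] == labels[i]); fp <- length(top) - tp
      fn <- length(pos) - tp
      tn <- (length(cand) - length(pos)) - fp
      TP <- TP + tp; FP <- FP + fp; TN <- TN + tn; FN <- FN + fn
      if (length(pos) > 0L) sens <- c(sens, tp / length(pos))
      if (length(cand) - length(pos) > 0L)
        fpr <- c(fpr, fp / (length(cand) - length(pos)))
    }
    data.frame(k = k, TP = TP, FP = FP, TN = TN, FN = FN,
               sensitivity = mean(sens), fpr = mean(fpr))
  })
  do.call(rbind, out)
}

#' Average-linkage dendrogram of alignment profiles
#'
#' Hierarchical clustering (average linkage) of the profile-matrix rows under
#' Euclidean distance or Pearson distance (`1 - r`).
#'
#' @param mat numeric profile matrix (queries in rows, `N >= 2`).
#' @param metric `"pearson"` or `"euclidean"`.
#' @return an [ape::as.phylo()] tree with branch lengths.
#' @export
profileDendrogram <- function(mat, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(nrow(mat) >= 2L)
  if (metric == "euclidean") {
    d <- stats::dist(mat)
  } else {
    sds <- apply(mat, 1, stats::sd)
    if (any(sds == 0))
      stop("Pearson distance undefined for constant row(s): ",
           paste(rownames(mat)[sds == 0], collapse = ", "))
    d <- as.dist(1 - stats::cor(t(mat)))
  }
  ape::as.phylo(hclust(d, method = "average"))
}

#' @describeIn profileDendrogram write a tree in Newick format.
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
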