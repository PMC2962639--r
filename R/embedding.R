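#' @include align-core.R
NULL

#' Extract a terminal seed from a profile
#'
#' The seed is the N- or C-terminal `k = max(1, floor(p/100 * n))` residues of
#' the profile consensus; its self-score Score(S) is the sum of the seed
#' residues scored against the profile's own columns.
#'
#' @param profile a [ScoringProfile-class].
#' @param p seed fraction in percent (default 10; `0 < p <= 100`).
#' @param terminal `"N"` or `"C"`.
#' @param matrix optional [SubstitutionMatrix-class]; when given, Score(S) is
#'   computed under the same matrix scheme the search uses.
#' @return a [Seed-class].
#' @export
#' @examples
#' prof <- generateProfile(100, rngSeed = 1)
#' extractSeed(prof, p = 10, terminal = "N")  # k = 10
extractSeed <- function(profile, p = 10, terminal = c("N", "C"),
                        matrix = NULL) {
  terminal <- match.arg(terminal)
  stopifnot(p > 0, p <= 100)
  n <- profileLength(profile)
  if (n < 1L) stop("empty consensus")
  k <- max(1L, as.integer(floor(p * n / 100)))
  pos <- if (terminal == "N") seq_len(k) else seq(n - k + 1L, n)
  res <- substr(profileConsensus(profile),
                pos[1], pos[length(pos)])
  S <- scoringScheme(profile, matrix)
  codes <- encodeResidues(res)
  score <- sum(S[cbind(pos, codes + 1L)])
  new("Seed", residues = res, terminal = terminal,
      profileId = profileId(profile), score = as.numeric(score))
}

#' Build a chimera sequence
#'
#' Inserts the seed at 0-based position `q` of the query:
#' `C(q) = Y[0,q) | S | Y[q,m)`.
#'
#' @param query query residue string (a named length-1 vector supplies the
#'   query id).
#' @param seed a [Seed-class].
#' @param q 0-based insertion position, `0 <= q <= m`.
#' @param queryId query identifier (defaults to the name of `query`).
#' @return a [Chimera-class].
#' @export
buildChimera <- function(query, seed, q, queryId = NULL) {
  if (is.null(queryId))
    queryId <- if (!is.null(names(query))) names(query)[1] else "query"
  query <- toupper(unname(query[1]))
  m <- nchar(query)
  if (q < 0 || q > m) stop("insertion position q out of range [0, m]")
  res <- paste0(substr(query, 1L, q), seed@residues,
                substr(query, q + 1L, m))
  new("Chimera", queryId = queryId, residues = res, seed = seed,
      q = as.integer(q), m = as.integer(m))
}

#' @describeIn buildChimera recover the original query by stripping the seed
#'   span from a chimera.
#' @param chimera a [Chimera-class].
#' @export
stripSeed <- function(chimera) {
  k <- seedLength(chimera@seed)
  paste0(substr(chimera@residues, 1L, chimera@q),
         substr(chimera@residues, chimera@q + k + 1L,
                nchar(chimera@residues)))
}

#' Exhaustive seed-embedded search
#'
#' The reference strategy: for each requested terminal, a seed is inserted at
#' every query position `q` in `0..m-1`, each chimera is aligned by the
#' seeded, length-adjusted dynamic programming of [seededAlignment()], and
#' the survivors of [filterAlignments()] are returned. The adaptive search
#' output is always a subset of this oracle's output under identical
#' parameters.
#'
#' @inheritParams extractSeed
#' @param query query residue string (named vector supplies the id).
#' @param thresholds a [FilterThresholds-class].
#' @param gap a [GapParams-class].
#' @param alpha length-adjustment weight per alignment column (default 0.05).
#'   The final DP cell is chosen by the adjusted score `raw + alpha * length`;
#'   `alpha` must stay below the score decay rate of random extensions
#'   (about 0.2 per column under BLOSUM62 with gap penalties 11/1) or
#'   arbitrarily long random alignments become profitable.
#' @param terminals which seed terminals to run (default both).
#' @param queryId query identifier.
#' @return a [SearchResult-class]; `dpInvocations` equals
#'   `length(terminals) * m` by construction.
#' @export
exhaustiveSearch <- function(query, profile, p = 10,
                             thresholds = filterThresholds(),
                             gap = gapParams(), matrix = NULL, alpha = 0.05,
                             terminals = c("N", "C"), queryId = NULL) {
  if (is.null(queryId))
    queryId <- if (!is.null(names(query))) names(query)[1] else "query"
  query <- toupper(unname(query[1]))
  m <- nchar(query)
  candidates <- stats::setNames(
    rep(list(if (m > 0) 0:(m - 1L) else integer()), length(terminals)),
    terminals)
  run <- runSeededCandidates(query, queryId, profile, p, candidates,
                             thresholds, gap, matrix, alpha)
  new("SearchResult", queryId = queryId, profileId = profileId(profile),
      method = "exhaustive", alignments = run$alignments,
      dpInvocations = run$invocations, nPartials = NA_integer_)
}

# Shared driver: build a chimera and run the seeded DP at every candidate
# position, then filter, deduplicate on (terminal, q, spans) and sort by
# (terminal, q, target start).
runSeededCandidates <- function(query, queryId, profile, p, candidates,
                                thresholds, gap, matrix, alpha) {
  out <- list()
  invocations <- 0L
  for (terminal in names(candidates)) {
    qs <- candidates[[terminal]]
    if (length(qs) == 0L) next
    seed <- extractSeed(profile, p, terminal, matrix)
    for (q in qs) {
      ch <- buildChimera(query, seed, q, queryId)
      invocations <- invocations + 1L
      aln <- seededAlignment(ch, profile, gap, matrix, alpha)
      if (!is.null(aln)) out[[length(out) + 1L]] <- aln
    }
  }
  surv <- filterAlignments(out, thresholds)
  if (length(surv) > 1L) {
    key <- vapply(surv, function(a)
      paste(a@terminal, a@q, paste(targetSpan(a), collapse = ","),
            paste(querySpan(a), collapse = ",")), character(1))
    surv <- surv[!duplicated(key)]
    ord <- order(vapply(surv, function(a) a@terminal, character(1)),
                 vapply(surv, function(a) a@q, integer(1)),
                 vapply(surv, function(a) targetSpan(a)[1], integer(1)))
    surv <- surv[ord]
  }
  list(alignments = surv, invocations = invocations)
}
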