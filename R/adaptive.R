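#' @include embedding.R
NULL

#' Find non-overlapping partial alignments (Step 1)
#'
#' Word hits are extended into ungapped HSPs with hit consumption, each
#' surviving HSP is gap-extended from its GE starting pair, alignments
#' shorter than `minPartialFraction * n` columns are dropped, and the
#' remainder is reduced to a non-overlapping set by greedy selection in
#' decreasing score order: an alignment is rejected if its query span
#' overlaps an accepted one. Query spans partition the conserved regions of
#' the query; two partials may reuse the same target region (a repeated
#' domain aligns the target once per copy).
#'
#' @inheritParams exhaustiveSearch
#' @param wordSize,minWordScore,dropoff,minHspScore BLAST-like core
#'   parameters; see [findHits()] and [extendUngapped()].
#' @return a list of partial alignments, each a list with `targetIdx`,
#'   `queryIdx`, `score`, `targetSpan`, `querySpan`, `length`.
#' @export
findPartialAlignments <- function(profile, query,
                                  thresholds = filterThresholds(),
                                  gap = gapParams(), matrix = NULL,
                                  wordSize = 3L, minWordScore = 11L,
                                  dropoff = 7L, minHspScore = 25L) {
  query <- toupper(unname(query[1]))
  n <- profileLength(profile)
  if (nchar(query) < wordSize) return(list())
  hits <- findHits(profile, query, wordSize, minWordScore, matrix)
  if (nrow(hits) == 0L) return(list())
  hsps <- extendUngapped(profile, query, hits, wordSize, dropoff,
                         minHspScore, matrix)
  if (nrow(hsps) == 0L) return(list())
  alns <- lapply(seq_len(nrow(hsps)), function(r)
    extendGapped(profile, query, hsps[r, ], gap, matrix))
  len <- vapply(alns, function(a) length(a$targetIdx), integer(1))
  alns <- alns[len > thresholds@minPartialFraction * n]
  if (length(alns) == 0L) return(list())
  ord <- order(-vapply(alns, function(a) a$score, numeric(1)),
               vapply(alns, function(a) a$targetSpan[1], integer(1)),
               vapply(alns, function(a) a$querySpan[1], integer(1)))
  accepted <- list()
  for (a in alns[ord]) {
    clash <- any(vapply(accepted, function(b)
      a$querySpan[1] < b$querySpan[2] && a$querySpan[2] > b$querySpan[1],
      logical(1)))
    if (!clash) {
      a$length <- length(a$targetIdx)
      accepted[[length(accepted) + 1L]] <- a
    }
  }
  accepted
}

#' Maximum bridgeable gap G(S) of a seed (Step 2)
#'
#' The longest gap whose affine penalty (`GOP + G * GEP`) the seed's
#' self-score can pay for: `G(S) = max(0, floor((Score(S) - GOP) / GEP))`.
#'
#' @param seed a [Seed-class].
#' @param gap a [GapParams-class].
#' @return non-negative integer gap length.
#' @export
#' @examples
#' s <- new("Seed", residues = "AAA", terminal = "N", profileId = "p",
#'          score = 30)
#' maxGap(s, gapParams(gop = 11, gep = 1))  # 19
maxGap <- function(seed, gap = gapParams()) {
  max(0L, as.integer(floor((seedScore(seed) - gap@gop) / gap@gep)))
}

#' Select seed-insertion positions for one partial alignment (Step 2)
#'
#' For a partial alignment with query span `[ys, ye)` and target span
#' `[xs, xe)`: an N-terminal seed may be inserted at `q` in
#' `[max(0, ys - G(S) - k), ys + max(0, k - xs)]` — from the farthest
#' position whose gap to the partial the seed score can still pay for
#' (see [maxGap()]) up to the seamless position where the seed's target
#' block `[0, k)` hands over exactly to the partial (when the partial starts
#' inside that block, `xs < k`, the first `k - xs` partial query residues
#' are redundant with the seed and the seamless insertion lies that much
#' beyond `ys`). A C-terminal seed may be inserted at
#' `[ye - max(0, xe - (n - k)), min(m, ye + G(S))]`, mirrored. Positions are
#' original-query coordinates; an empty range is returned when no position
#' is feasible.
#'
#' @param partial one partial alignment from [findPartialAlignments()].
#' @param seed a [Seed-class] (its terminal decides which range is emitted).
#' @param gap a [GapParams-class].
#' @param m original query length.
#' @param n target profile length; when `NULL` the C-terminal seamless
#'   correction is omitted.
#' @return data frame with columns `terminal`, `q_start`, `q_end` (inclusive);
#'   zero rows when empty.
#' @export
selectSeedPositions <- function(partial, seed, gap, m, n = NULL) {
  G <- maxGap(seed, gap)
  k <- seedLength(seed)
  ys <- partial$querySpan[1]; ye <- partial$querySpan[2]
  if (seed@terminal == "N") {
    overlap <- max(0L, k - partial$targetSpan[1])
    qs <- max(0L, ys - G - k); qe <- ys + overlap
  } else {
    overlap <- if (is.null(n)) 0L else
      max(0L, partial$targetSpan[2] - (n - k))
    qs <- ye - overlap; qe <- min(m, ye + G)
  }
  if (qs > m || qs > qe)
    return(data.frame(terminal = character(), q_start = integer(),
                      q_end = integer()))
  data.frame(terminal = seed@terminal, q_start = as.integer(qs),
             q_end = as.integer(qe))
}

#' Seeded final alignment with length-adjusted DP (Step 3)
#'
#' The embedded seed aligns exactly to its terminal of the target
#' (N-terminal seed to target positions `[0, k)`, C-terminal to `[n-k, n)`);
#' affine-gap dynamic programming is anchored at the seed's inner end and
#' extends toward the region of interest (rightward for N seeds, leftward
#' for C). The recurrence maximizes the raw score; when the final cell is
#' chosen, each cell's comparison score is adjusted by the alignment length
#' `a` at that cell, `adjusted = raw + alpha * a`, so a longer alignment
#' with a lower raw score can beat a shorter, higher-scoring one. An
#' extension prefix whose cumulative raw score would exhaust the seed's
#' budget Score(S) is abandoned — a seed cannot bridge a gap it cannot pay
#' for, which is what makes the maximum gap G(S) of [maxGap()] the reach
#' limit of a seed. With `alpha = 0` the result is standard anchored
#' Smith-Waterman extension under that budget.
#'
#' @param chimera a [Chimera-class].
#' @inheritParams exhaustiveSearch
#' @return a [FinalAlignment-class], or `NULL` when the best adjusted
#'   extension score outside the seed is `<= 0`.
#' @export
seededAlignment <- function(chimera, profile, gap = gapParams(),
                            matrix = NULL, alpha = 0.05) {
  if (alpha < 0) stop("alpha must be non-negative")
  S <- scoringScheme(profile, matrix)
  cc <- encodeResidues(chimera@residues)
  seed <- chimera@seed
  k <- seedLength(seed); q <- chimera@q
  n <- profileLength(profile)
  if (k > n) stop("seed longer than the profile")
  if (seed@terminal == "N") {
    seedT <- 0:(k - 1L); anchorT <- k - 1L; anchorQ <- q + k - 1L; dir <- 1L
  } else {
    seedT <- (n - k):(n - 1L); anchorT <- n - k; anchorQ <- q; dir <- -1L
  }
  seedQ <- q:(q + k - 1L)
  bank <- seedScore(seed)
  ext <- cpp_extend_affine(S, cc, anchorT, anchorQ, dir, gap@gop, gap@gep,
                           alpha, bank, TRUE)
  if (ext$adjusted <= 0) return(NULL)
  path <- ext$path
  gapify <- function(v) ifelse(v < 0L, NA_integer_, as.integer(v))
  if (dir > 0) {
    targetIdx <- c(seedT, gapify(path[, "target"]))
    queryIdx <- c(seedQ, gapify(path[, "query"]))
  } else {
    targetIdx <- c(gapify(rev(path[, "target"])), seedT)
    queryIdx <- c(gapify(rev(path[, "query"])), seedQ)
  }
  Lext <- nrow(path)
  rawScore <- seedScore(seed) + ext$value
  adjScore <- rawScore + alpha * (k + Lext)
  # seed columns are the first (N) or last (C) k columns
  isSeed <- rep(FALSE, length(targetIdx))
  isSeed[if (dir > 0) seq_len(k) else seq(Lext + 1L, Lext + k)] <- TRUE
  nonSeedT <- targetIdx[!isSeed]; nonSeedQ <- queryIdx[!isSeed]
  denom <- sum(!isSeed)
  ident <- if (denom == 0L) 0 else {
    cons <- strsplit(profileConsensus(profile), "")[[1]]
    chres <- strsplit(chimera@residues, "")[[1]]
    matchCol <- !is.na(nonSeedT) & !is.na(nonSeedQ) &
      cons[nonSeedT + 1L] == chres[nonSeedQ + 1L]
    100 * sum(matchCol) / denom
  }
  ti <- targetIdx[!is.na(targetIdx)]
  coverage <- 100 * (max(ti) - min(ti) + 1L) / n
  qOrig <- nonSeedQ[!is.na(nonSeedQ)]
  qOrig <- if (dir > 0) qOrig - k else qOrig
  queryRange <- if (length(qOrig) == 0L) c(NA_integer_, NA_integer_)
                else c(min(qOrig), max(qOrig) + 1L)
  new("FinalAlignment", queryId = chimera@queryId,
      profileId = profileId(profile), terminal = seed@terminal,
      q = chimera@q, seedSpan = c(q, q + k),
      targetIdx = as.integer(targetIdx), queryIdx = as.integer(queryIdx),
      rawScore = rawScore, adjustedScore = adjScore,
      coveragePct = coverage, identityPct = ident,
      queryRange = as.integer(queryRange))
}

#' Filter final alignments by coverage and identity (Step 4)
#'
#' Keeps alignments whose percent coverage and seed-excluded percent identity
#' are both strictly greater than the thresholds. Seed-only alignments have
#' identity 0 and are dropped by any non-negative identity threshold.
#'
#' @param alignments list of [FinalAlignment-class] objects.
#' @param thresholds a [FilterThresholds-class].
#' @return the surviving sublist.
#' @export
filterAlignments <- function(alignments, thresholds = filterThresholds()) {
  keep <- vapply(alignments, function(a)
    a@coveragePct > thresholds@minCoverage &&
    a@identityPct > thresholds@minIdentity, logical(1))
  alignments[keep]
}

#' Adaptive seed-embedded search
#'
#' The four-step adaptive strategy: (1) unseeded non-overlapping partial
#' alignments locate the conserved regions; (2) for each partial alignment
#' the feasible seed-insertion positions are derived from the seed score and
#' the maximum bridgeable gap G(S); (3) a chimera is built and the seeded,
#' length-adjusted DP run only at those positions; (4) survivors are kept by
#' the coverage/identity filter. Output is deduplicated on
#' (terminal, q, target span, query span) and is always a subset of
#' [exhaustiveSearch()] under identical parameters.
#'
#' @inheritParams exhaustiveSearch
#' @inheritParams findPartialAlignments
#' @return a [SearchResult-class]; `dpInvocations` reports how many seeded
#'   DP runs were needed (at most `2 * m`, usually far fewer).
#' @export
#' @examples
#' prof <- generateProfile(40, rngSeed = 7)
#' pl <- plantHomolog(prof, plantSpec(identity = 0.8, flankLengths = c(15, 15),
#'                                    rngSeed = 8))
#' res <- adaptiveSearch(pl$sequence, prof)
#' dpInvocations(res)
adaptiveSearch <- function(query, profile, p = 10,
                           thresholds = filterThresholds(),
                           gap = gapParams(), matrix = NULL, alpha = 0.05,
                           terminals = c("N", "C"), queryId = NULL,
                           wordSize = 3L, minWordScore = 11L, dropoff = 7L,
                           minHspScore = 25L) {
  if (is.null(queryId))
    queryId <- if (!is.null(names(query))) names(query)[1] else "query"
  query <- toupper(unname(query[1]))
  m <- nchar(query)
  partials <- findPartialAlignments(profile, query, thresholds, gap, matrix,
                                    wordSize, minWordScore, dropoff,
                                    minHspScore)
  candidates <- list()
  for (terminal in terminals) {
    seed <- extractSeed(profile, p, terminal, matrix)
    qs <- integer()
    for (partial in partials) {
      rng <- selectSeedPositions(partial, seed, gap, m,
                                 n = profileLength(profile))
      if (nrow(rng))
        qs <- c(qs, seq(rng$q_start, rng$q_end))
    }
    qs <- sort(unique(qs[qs >= 0L & qs <= m - 1L]))
    candidates[[terminal]] <- qs
  }
  run <- runSeededCandidates(query, queryId, profile, p, candidates,
                             thresholds, gap, matrix, alpha)
  new("SearchResult", queryId = queryId, profileId = profileId(profile),
      method = "adaptive", alignments = run$alignments,
      dpInvocations = run$invocations,
      nPartials = length(partials))
}
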