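# Independent reference implementations kept deliberately separate from the
# package's compiled core: plain-R dynamic programming used as oracles.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# n x 21 scheme matrix (20 residues + X) for a profile, optionally under a
# substitution matrix
oracleScheme <- function(profile, matrix = NULL) {
  n <- profileLength(profile)
  cons <- strsplit(profileConsensus(profile), "")[[1]]
  if (is.null(matrix)) {
    cbind(profileScores(profile), X = rep(-1L, n))
  } else {
    m <- matrix@scores
    t(sapply(cons, function(r)
      c(m[r, AA20], X = if ("X" %in% colnames(m)) m[r, "X"] else -1L)))
  }
}

oracleCodes <- function(x) match(strsplit(toupper(x), "")[[1]], c(AA20, "X"))

# brute-force double loop over all (i, j) word placements
refFindHits <- function(S, qc, w, minWordScore) {
  n <- nrow(S); m <- length(qc)
  out <- NULL
  if (n >= w && m >= w) {
    for (i in 0:(n - w)) for (j in 0:(m - w)) {
      s <- sum(S[cbind(i + 1:w, qc[j + 1:w])])
      if (s > minWordScore)
        out <- rbind(out, c(i, j, s))
    }
  }
  if (is.null(out)) out <- matrix(integer(), 0, 3)
  colnames(out) <- c("target_start", "query_start", "score")
  out
}

# one-directional anchored affine extension by plain-R recurrence; returns the
# best adjusted value over cells ending in a match column (0 = empty).
# Semantics mirror the package contract (gap of length L costs GOP + L*GEP,
# each column worth +alpha, prefixes with bank + value <= 0 infeasible) but
# the code is written independently.
refExtendValue <- function(S, qc, ti0, qi0, dir, gop, gep, alpha = 0,
                           bank = Inf) {
  n <- nrow(S); m <- length(qc)
  U <- if (dir > 0) n - 1 - ti0 else ti0
  V <- if (dir > 0) m - 1 - qi0 else qi0
  NEG <- -Inf
  M <- matrix(NEG, U + 1, V + 1); GQ <- M; GT <- M
  M[1, 1] <- 0
  feas <- function(v) if (!is.finite(v) || (is.finite(bank) && bank + v <= 0)) NEG else v
  if (V >= 1) for (v in 1:V) GT[1, v + 1] <- feas(-(gop + gep) + alpha - (v - 1) * (gep - alpha))
  if (U >= 1) for (u in 1:U) GQ[u + 1, 1] <- feas(-(gop + gep) + alpha - (u - 1) * (gep - alpha))
  best <- 0
  if (U >= 1 && V >= 1) for (u in 1:U) for (v in 1:V) {
    sc <- S[ti0 + dir * u + 1, qc[qi0 + dir * v + 1]] + alpha
    M[u + 1, v + 1] <- feas(max(M[u, v], GQ[u, v], GT[u, v]) + sc)
    GQ[u + 1, v + 1] <- feas(max(M[u, v + 1] - gop - gep + alpha,
                                 GQ[u, v + 1] - gep + alpha))
    GT[u + 1, v + 1] <- feas(max(M[u + 1, v] - gop - gep + alpha,
                                 GT[u + 1, v] - gep + alpha))
    if (is.finite(M[u + 1, v + 1])) best <- max(best, M[u + 1, v + 1])
  }
  best
}

# best local alignment score restricted to paths through the anchor pair,
# aligned as a match column (the GE starting pair)
refAnchoredScore <- function(S, qc, anchorT, anchorQ, gop, gep) {
  unname(S[anchorT + 1, qc[anchorQ + 1]]) +
    refExtendValue(S, qc, anchorT, anchorQ, +1, gop, gep) +
    refExtendValue(S, qc, anchorT, anchorQ, -1, gop, gep)
}

# recompute an alignment's raw score from its columns under the scheme and
# affine gap costs (gap of length L costs GOP + L*GEP)
recomputeScore <- function(S, qc, targetIdx, queryIdx, gop, gep) {
  sc <- 0
  inGapT <- FALSE; inGapQ <- FALSE
  for (i in seq_along(targetIdx)) {
    t <- targetIdx[i]; q <- queryIdx[i]
    if (!is.na(t) && !is.na(q)) {
      sc <- sc + S[t + 1, qc[q + 1]]
      inGapT <- inGapQ <- FALSE
    } else if (is.na(q)) {          # gap in query, consumes target
      sc <- sc - gep - if (inGapQ) 0 else gop
      inGapQ <- TRUE; inGapT <- FALSE
    } else {                        # gap in target, consumes query
      sc <- sc - gep - if (inGapT) 0 else gop
      inGapT <- TRUE; inGapQ <- FALSE
    }
  }
  unname(sc)
}

# deterministic random related instance: profile + query with planted copy
randomInstance <- function(seed, n = 30, identity = 0.8, flanks = c(5, 5)) {
  prof <- generateProfile(n, rngSeed = seed)
  pl <- plantHomolog(prof, plantSpec(identity = identity,
                                     flankLengths = flanks,
                                     rngSeed = seed + 10000L))
  list(profile = prof, query = unname(pl$sequence), span = pl$span)
}

# a FinalAlignment stub carrying given coverage/identity (for filter and
# composite-score tests that do not need real columns)
alignmentStub <- function(coverage, identity, terminal = "N", q = 0L) {
  new("FinalAlignment", queryId = "q", profileId = "p", terminal = terminal,
      q = as.integer(q), seedSpan = c(0L, 1L), targetIdx = 0L,
      queryIdx = 0L, rawScore = 1, adjustedScore = 1,
      coveragePct = coverage, identityPct = identity,
      queryRange = c(NA_integer_, NA_integer_))
}

alignmentKey <- function(a)
  paste(a@terminal, a@q, paste(targetSpan(a), collapse = ","),
        paste(querySpan(a), collapse = ","))

# Verify the hit and HSP shift laws on one (profile, query) instance for the
# given seed terminals and insertion positions. Hits must shift exactly. For
# HSPs the law is checked on interference-free diagonals: every hit on the
# HSP's diagonal lies on the HSP's side of the insertion point, the chimera
# diagonal carries exactly the image hits, and the HSP keeps `margin`
# residues of clearance from the insertion point so its ungapped exploration
# cannot cross into seed-altered terrain.
checkShiftLaws <- function(profile, query, qStep = 3L, margin = 7L,
                           terminals = c("N", "C")) {
  w <- 3L
  m <- nchar(query)
  baseHits <- findHits(profile, query)
  baseH <- extendUngapped(profile, query, baseHits)
  baseDiag <- baseHits$target_start - baseHits$query_start
  hitBad <- hspBad <- 0L; hitChecked <- hspChecked <- 0L
  for (terminal in terminals) {
    seed <- extractSeed(profile, 10, terminal)
    k <- seedLength(seed)
    for (q in seq(0L, m - 1L, by = qStep)) {
      ch <- buildChimera(query, seed, q)
      chHits <- findHits(profile, ch@residues)
      chKeyHit <- paste(chHits$target_start, chHits$query_start)
      before <- baseHits$query_start + w - 1 < q
      after <- baseHits$query_start >= q
      hitChecked <- hitChecked + sum(before) + sum(after)
      hitBad <- hitBad +
        sum(!(paste(baseHits$target_start[before],
                    baseHits$query_start[before]) %in% chKeyHit)) +
        sum(!(paste(baseHits$target_start[after],
                    baseHits$query_start[after] + k) %in% chKeyHit))
      if (nrow(baseH) == 0) next
      chH <- extendUngapped(profile, ch@residues, chHits)
      chKeys <- paste(chH$target_start, chH$target_end, chH$query_start,
                      chH$query_end)
      chDiag <- chHits$target_start - chHits$query_start
      for (r in seq_len(nrow(baseH))) {
        h <- baseH[r, ]
        d <- h$target_start - h$query_start
        onDiag <- baseDiag == d
        if (h$query_end <= q - margin) {
          if (!all(before[onDiag])) next
          want <- paste(baseHits$target_start[onDiag],
                        baseHits$query_start[onDiag])
          have <- paste(chHits$target_start[chDiag == d],
                        chHits$query_start[chDiag == d])
          if (!setequal(want, have)) next
          hspChecked <- hspChecked + 1L
          if (!(paste(h$target_start, h$target_end, h$query_start,
                      h$query_end) %in% chKeys))
            hspBad <- hspBad + 1L
        } else if (h$query_start >= q + margin) {
          if (!all(after[onDiag])) next
          want <- paste(baseHits$target_start[onDiag],
                        baseHits$query_start[onDiag] + k)
          have <- paste(chHits$target_start[chDiag == d - k],
                        chHits$query_start[chDiag == d - k])
          if (!setequal(want, have)) next
          hspChecked <- hspChecked + 1L
          if (!(paste(h$target_start, h$target_end, h$query_start + k,
                      h$query_end + k) %in% chKeys))
            hspBad <- hspBad + 1L
        }
      }
    }
  }
  list(hitChecked = hitChecked, hitBad = hitBad,
       hspChecked = hspChecked, hspBad = hspBad)
}
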