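test_that("partial alignments cover conserved regions without query overlap", {
  prof <- generateProfile(40, rngSeed = 101)
  cons <- profileConsensus(prof)

  # identical query: a single partial covering the full diagonal
  p1 <- findPartialAlignments(prof, cons)
  expect_length(p1, 1L)
  expect_equal(p1[[1]]$targetSpan, c(0L, 40L))
  expect_equal(p1[[1]]$querySpan, c(0L, 40L))

  # two consensus copies separated by a random linker: one partial per copy
  linker <- unname(plantHomolog(generateProfile(30, rngSeed = 102),
                                plantSpec(1, c(0, 0), 103))$sequence)
  q2 <- paste0(cons, linker, cons)
  p2 <- findPartialAlignments(prof, q2)
  expect_length(p2, 2L)
  qspans <- t(vapply(p2, function(p) p$querySpan, integer(2)))
  expect_setequal(qspans[, 1], c(0L, 70L))
  # query spans never overlap pairwise
  o <- order(qspans[, 1])
  expect_true(all(qspans[o, 1][-1] >= qspans[o, 2][-length(p2)]))

  # an unreachable minimum length empties the result
  half <- substr(cons, 1, 20)
  none <- findPartialAlignments(prof, paste0(half, linker),
                                thresholds = filterThresholds(
                                  minPartialFraction = 1.0))
  expect_length(none, 0L)
})

test_that("the maximum bridgeable gap follows the seed-score arithmetic", {
  mk <- function(score) new("Seed", residues = "AAA", terminal = "N",
                            profileId = "p", score = score)
  expect_equal(maxGap(mk(30), gapParams(gop = 11, gep = 1)), 19L)
  expect_equal(maxGap(mk(11), gapParams(gop = 11, gep = 1)), 0L)
  expect_equal(maxGap(mk(5), gapParams(gop = 11, gep = 1)), 0L)
  expect_equal(maxGap(mk(31), gapParams(gop = 11, gep = 2)), 10L)
})

test_that("seed-position ranges derive from the partial spans, G(S) and k", {
  gap <- gapParams(gop = 11, gep = 1)
  partial <- list(querySpan = c(25L, 60L), targetSpan = c(10L, 45L))
  sN <- new("Seed", residues = "AAAAA", terminal = "N", profileId = "p",
            score = 21)                       # G = 10, k = 5
  rN <- selectSeedPositions(partial, sN, gap, m = 100L, n = 50L)
  expect_equal(rN$q_start, 10L)               # ys - G - k
  expect_equal(rN$q_end, 25L)                 # ys (xs >= k: no overlap)
  sC <- new("Seed", residues = "AAAAA", terminal = "C", profileId = "p",
            score = 21)
  rC <- selectSeedPositions(partial, sC, gap, m = 100L, n = 50L)
  expect_equal(rC$q_start, 60L)               # ye (xe <= n - k)
  expect_equal(rC$q_end, 70L)                 # min(m, ye + G)

  # a partial starting inside the seed target block extends the N range to
  # the seamless insertion ys + (k - xs); mirrored for C
  deep <- list(querySpan = c(25L, 60L), targetSpan = c(0L, 50L))
  expect_equal(selectSeedPositions(deep, sN, gap, m = 100L, n = 50L)$q_end,
               30L)                           # ys + (k - 0)
  expect_equal(selectSeedPositions(deep, sC, gap, m = 100L, n = 50L)$q_start,
               55L)                           # ye - (xe - (n - k))

  # clipping at the query boundaries
  r0 <- selectSeedPositions(list(querySpan = c(0L, 30L),
                                 targetSpan = c(20L, 50L)), sN, gap,
                            m = 100L, n = 50L)
  expect_equal(c(r0$q_start, r0$q_end), c(0L, 0L))
  rEnd <- selectSeedPositions(list(querySpan = c(70L, 98L),
                                   targetSpan = c(10L, 40L)), sC, gap,
                              m = 100L, n = 50L)
  expect_equal(c(rEnd$q_start, rEnd$q_end), c(98L, 100L))
})

test_that("the seeded DP reduces to anchored extension when alpha is 0", {
  gap <- gapParams()
  for (fseed in 111:116) {
    inst <- randomInstance(fseed, n = 30, identity = 0.8, flanks = c(5, 5))
    n <- profileLength(inst$profile)
    S <- oracleScheme(inst$profile)
    for (terminal in c("N", "C")) {
      seed <- extractSeed(inst$profile, 10, terminal)
      k <- seedLength(seed)
      q <- if (terminal == "N") inst$span[1] else inst$span[2]
      ch <- buildChimera(inst$query, seed, q)
      aln <- seededAlignment(ch, inst$profile, gap, alpha = 0)
      cc <- oracleCodes(ch@residues)
      anchorT <- if (terminal == "N") k - 1L else n - k
      anchorQ <- if (terminal == "N") q + k - 1L else q
      dir <- if (terminal == "N") 1 else -1
      ref <- refExtendValue(S, cc, anchorT, anchorQ, dir, gap@gop, gap@gep,
                            alpha = 0, bank = seedScore(seed))
      if (is.null(aln)) {
        expect_lte(ref, 0)
      } else {
        expect_equal(aln@rawScore, seedScore(seed) + ref)
        expect_equal(aln@adjustedScore, aln@rawScore)
        # reported raw score equals recomputation from the columns
        expect_equal(recomputeScore(S, cc, aln@targetIdx, aln@queryIdx,
                                    gap@gop, gap@gep), aln@rawScore)
      }
    }
  }
})

test_that("the length adjustment prefers long moderate extensions", {
  # one diagonal whose cumulative raw score peaks at 40 after 10 columns,
  # dips, and recovers to 36 after 30 columns; alpha = 0.25 makes the long
  # cell the best adjusted one (36 + 7.5 > 40 + 2.5)
  perCol <- c(rep(4L, 10), rep(-2L, 8), rep(1L, 12))
  seedRes <- "WWW"
  scores <- matrix(-20L, 33, 20)
  colnames(scores) <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  scores[1:3, "W"] <- 11L
  scores[4:33, "A"] <- perCol
  prof <- scoringProfile("crafted", paste0("WWW", strrep("A", 30)), scores)
  query <- strrep("A", 30)
  seed <- extractSeed(prof, p = 10, terminal = "N")   # k = 3, "WWW"
  expect_equal(seedScore(seed), 33)
  ch <- buildChimera(query, seed, 0)

  long <- seededAlignment(ch, prof, gapParams(), alpha = 0.25)
  expect_equal(length(long@targetIdx) - 3L, 30L)
  expect_equal(long@rawScore, 33 + 36)

  short <- seededAlignment(ch, prof, gapParams(), alpha = 0)
  expect_equal(length(short@targetIdx) - 3L, 10L)
  expect_equal(short@rawScore, 33 + 40)
})

test_that("the survivor filter gates strictly on coverage and identity", {
  thr <- filterThresholds(minCoverage = 60, minIdentity = 10)
  expect_length(filterAlignments(list(alignmentStub(59.9, 50)), thr), 0L)
  expect_length(filterAlignments(list(alignmentStub(60, 50)), thr), 0L)
  expect_length(filterAlignments(list(alignmentStub(60.1, 50)), thr), 1L)
  # seed-only alignments carry identity 0 and never survive
  expect_length(filterAlignments(list(alignmentStub(100, 0)), thr), 0L)
  expect_length(filterAlignments(list(alignmentStub(100, 100)),
                                 filterThresholds(100, 100)), 0L)
  expect_length(filterAlignments(list(alignmentStub(100, 100)),
                                 filterThresholds(99, 99)), 1L)
})

test_that("raising thresholds never increases the survivor count", {
  prof <- generateProfile(50, rngSeed = 121)
  pl <- plantHomolog(prof, plantSpec(identity = 0.5, flankLengths = c(25, 25),
                                     rngSeed = 122))
  res <- exhaustiveSearch(pl$sequence, prof,
                          thresholds = filterThresholds(0, 0))
  pool <- alignments(res)
  grid <- expand.grid(cov = c(0, 40, 60, 85), id = c(0, 10, 25, 50))
  counts <- matrix(NA_integer_, 4, 4)
  for (i in 1:4) for (j in 1:4)
    counts[i, j] <- length(filterAlignments(pool,
      filterThresholds(grid$cov[(j - 1) * 4 + i], grid$id[(j - 1) * 4 + i])))
  expect_true(all(diff(counts[, 1]) <= 0))       # coverage axis
  expect_true(all(diff(counts[1, ]) <= 0))       # identity axis
  for (i in 2:4) for (j in 2:4) {
    expect_lte(counts[i, j], counts[i - 1, j])
    expect_lte(counts[i, j], counts[i, j - 1])
  }
})

test_that("adaptive output is a subset of the exhaustive oracle", {
  for (fseed in 131:136) {
    prof <- generateProfile(50, rngSeed = fseed)
    pl <- plantHomolog(prof, plantSpec(identity = 0.3 + 0.06 * (fseed - 131),
                                       flankLengths = c(30, 30),
                                       rngSeed = fseed + 50))
    ad <- adaptiveSearch(pl$sequence, prof)
    ex <- exhaustiveSearch(pl$sequence, prof)
    ka <- vapply(alignments(ad), alignmentKey, character(1))
    ke <- vapply(alignments(ex), alignmentKey, character(1))
    expect_true(all(ka %in% ke))
    expect_lt(dpInvocations(ad), 2L * nchar(pl$sequence))
  }
})

test_that("planted domains at 70% identity are recovered over most of their span", {
  found <- 0L
  for (fseed in 141:150) {
    prof <- generateProfile(60, rngSeed = fseed)
    pl <- plantHomolog(prof, plantSpec(identity = 0.7, flankLengths = c(30, 30),
                                       rngSeed = fseed + 20))
    res <- adaptiveSearch(pl$sequence, prof)
    ok <- vapply(alignments(res), function(a) {
      r <- a@queryRange
      if (is.na(r[1])) return(FALSE)
      ov <- max(0, min(r[2], pl$span[2]) - max(r[1], pl$span[1]))
      ov >= 0.8 * (pl$span[2] - pl$span[1])
    }, logical(1))
    if (any(ok)) found <- found + 1L
  }
  expect_equal(found, 10L)
})
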