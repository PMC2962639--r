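test_that("seed extraction takes the stated terminal fraction and self-score", {
  prof <- generateProfile(100, rngSeed = 61)
  cons <- profileConsensus(prof)
  sN <- extractSeed(prof, p = 10, terminal = "N")
  expect_equal(seedLength(sN), 10L)
  expect_identical(sN@residues, substr(cons, 1, 10))
  sC <- extractSeed(prof, p = 10, terminal = "C")
  expect_identical(sC@residues, substr(cons, 91, 100))
  # Score(S) is the sum of the seed residues against their own columns
  S <- oracleScheme(prof)
  expect_equal(seedScore(sN), sum(S[cbind(1:10, oracleCodes(sN@residues))]))
  expect_equal(seedScore(sC), sum(S[cbind(91:100, oracleCodes(sC@residues))]))

  # 10% of a 10-residue profile is a single residue
  p10 <- generateProfile(10, rngSeed = 62)
  expect_equal(seedLength(extractSeed(p10, 10, "N")), 1L)
  expect_error(extractSeed(prof, p = 0), "p > 0")
})

test_that("chimera construction inserts, maps and reconstructs exactly", {
  prof <- generateProfile(50, rngSeed = 63)
  seed <- extractSeed(prof, 10, "N")
  query <- unname(plantHomolog(prof, plantSpec(1, c(25, 25), 64))$sequence)
  m <- nchar(query)
  expect_identical(buildChimera(query, seed, 0)@residues,
                   paste0(seed@residues, query))
  expect_identical(buildChimera(query, seed, m)@residues,
                   paste0(query, seed@residues))
  expect_error(buildChimera(query, seed, m + 1), "out of range")

  # stripping the seed recovers the query at every position
  for (q in 0:m)
    expect_identical(stripSeed(buildChimera(query, seed, q)), query)

  # a 100-residue query yields 100 distinct chimeras per seed
  q100 <- unname(plantHomolog(generateProfile(40, rngSeed = 65),
                              plantSpec(1, c(30, 30), 66))$sequence)
  chims <- vapply(0:99, function(q)
    buildChimera(q100, seed, q)@residues, character(1))
  expect_equal(length(unique(chims)), 100L)
})

test_that("hits shift by the seed length across the insertion point", {
  # hits strictly before the seed persist unchanged in the chimera; hits at
  # or after the insertion point reappear shifted by the seed length
  for (fseed in c(71, 72)) {
    inst <- randomInstance(fseed, n = 30, identity = 0.5, flanks = c(10, 10))
    laws <- checkShiftLaws(inst$profile, inst$query, qStep = 1L)
    expect_gt(laws$hitChecked, 100L)
    expect_identical(laws$hitBad, 0L)
  }
})

test_that("HSPs on interference-free diagonals shift by the seed length", {
  # An HSP's construction depends on the other hits sharing its diagonal
  # (hit consumption, extension bounds) and on the terrain its ungapped
  # exploration can reach. The shift law is asserted for HSPs whose diagonal
  # carries the same hit population on the HSP's side of the insertion point
  # in both sequences and whose span keeps clearance from the insertion
  # point (see checkShiftLaws in helper-oracles.R).
  checked <- 0L
  for (fseed in c(73, 74, 75, 76)) {
    inst <- randomInstance(fseed, n = 30, identity = 0.6, flanks = c(10, 10))
    laws <- checkShiftLaws(inst$profile, inst$query, qStep = 3L)
    expect_identical(laws$hspBad, 0L)
    checked <- checked + laws$hspChecked
  }
  expect_gt(checked, 30L)   # the exclusions leave a substantive sample
})

test_that("exhaustive search finds perfect planted copies and respects the region of interest", {
  prof <- generateProfile(30, rngSeed = 81)
  pl <- plantHomolog(prof, plantSpec(identity = 1, flankLengths = c(10, 10),
                                     rngSeed = 82))
  res <- exhaustiveSearch(pl$sequence, prof)
  expect_equal(dpInvocations(res), 2L * nchar(unname(pl$sequence)))
  covs <- vapply(alignments(res), coveragePct, numeric(1))
  ids <- vapply(alignments(res), identityPct, numeric(1))
  expect_true(any(covs == 100 & ids == 100))

  # region of interest: non-seed aligned query columns lie beyond the seed
  # for N-terminal seeds and before it for C-terminal seeds
  for (a in alignments(res)) {
    k <- a@seedSpan[2] - a@seedSpan[1]
    qi <- a@queryIdx[!is.na(a@queryIdx)]
    nonSeed <- qi[qi < a@seedSpan[1] | qi >= a@seedSpan[2]]
    if (a@terminal == "N") expect_true(all(nonSeed >= a@seedSpan[2]))
    else expect_true(all(nonSeed < a@seedSpan[1]))
  }
})

test_that("unrelated queries are sharply separated from related ones", {
  relComp <- unrelComp <- adInv <- numeric(0)
  adSurvZero <- 0L
  for (i in 1:20) {
    prof <- generateProfile(60, rngSeed = 9000 + i)
    pl <- plantHomolog(prof, plantSpec(identity = 0.5, flankLengths = c(30, 30),
                                       rngSeed = 9200 + i))
    decoy <- unname(plantHomolog(generateProfile(60, rngSeed = 9500 + i),
                                 plantSpec(1, c(30, 30),
                                           rngSeed = 9700 + i))$sequence)
    relComp <- c(relComp, compositeScore(exhaustiveSearch(pl$sequence, prof)))
    unrelComp <- c(unrelComp, compositeScore(exhaustiveSearch(decoy, prof)))
    ad <- adaptiveSearch(decoy, prof)
    adInv <- c(adInv, dpInvocations(ad))
    if (length(alignments(ad)) == 0L) adSurvZero <- adSurvZero + 1L
  }
  # the adaptive path almost never does seeded work on unrelated pairs and
  # almost never reports a survivor for them
  expect_equal(median(adInv), 0)
  expect_gte(adSurvZero, 17L)
  # exhaustive composite scores separate related from unrelated sharply
  expect_true(all(relComp > 0))
  expect_lt(mean(unrelComp), 0.1 * mean(relComp))
})
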