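test_that("pair scoring matches the bundled matrices and PSSM columns", {
  b62 <- substitutionMatrix("BLOSUM62")
  expect_identical(scorePair(b62, "W", "W"), 11L)
  # diagonal positivity for every canonical residue
  for (r in AA20) expect_gt(scorePair(b62, r, r), 0)

  # bundled table agrees with the Biostrings reference copy
  data(BLOSUM62, package = "Biostrings", envir = environment())
  expect_equal(unname(b62@scores[AA20, AA20]),
               unname(BLOSUM62[AA20, AA20]))

  # PSSM column lookup: all -4 except +6 at A
  col <- matrix(-4L, 1, 20); col[1] <- 6L
  prof <- scoringProfile("one", "A", col)
  expect_identical(scorePair(prof, 0, "A"), 6L)
  expect_identical(scorePair(prof, 0, "R"), -4L)
  expect_error(scorePair(prof, 1, "A"), "out of range")
})

test_that("word-hit search equals the brute-force double loop", {
  for (seed in c(11, 12, 13)) {
    inst <- randomInstance(seed, n = 40, identity = 0.6, flanks = c(8, 8))
    S <- oracleScheme(inst$profile)
    qc <- oracleCodes(inst$query)
    got <- findHits(inst$profile, inst$query)
    ref <- refFindHits(S, qc, 3L, 11L)
    expect_equal(as.matrix(got), ref, ignore_attr = TRUE)
    # every hit's word score strictly exceeds the threshold
    if (nrow(got)) expect_true(all(got$score > 11L))
  }
  # unreachable threshold and short queries give empty, error-free results
  prof <- generateProfile(20, rngSeed = 14)
  expect_equal(nrow(findHits(prof, profileConsensus(prof),
                             minWordScore = 10^6)), 0L)
  expect_equal(nrow(findHits(prof, "MK")), 0L)
})

test_that("ungapped extension spans perfect matches and splits at linkers", {
  # perfect 20-residue identity, one interior hit -> one full-span HSP
  prof <- generateProfile(20, rngSeed = 21)
  query <- profileConsensus(prof)
  hits <- findHits(prof, query)
  interior <- hits[hits$target_start == 8 & hits$query_start == 8, ]
  hsp <- extendUngapped(prof, query, interior)
  expect_equal(nrow(hsp), 1L)
  expect_equal(unlist(hsp[1, 1:4]), c(target_start = 0, target_end = 20,
                                      query_start = 0, query_end = 20))
  S <- oracleScheme(prof)
  expect_equal(hsp$score, sum(S[cbind(1:20, oracleCodes(query))]))

  # two motifs separated by a low-scoring linker -> two disjoint HSPs
  motif1 <- "WYFHMCKRDE"; motif2 <- "NQSTVGALIP"
  prof2 <- profileFromConsensus("two", paste0(motif1, motif2))
  query2 <- paste0(motif1, "GGGGGGGGGG", motif2)
  hsps <- extendUngapped(prof2, query2, findHits(prof2, query2))
  expect_equal(nrow(hsps), 2L)
  expect_setequal(hsps$target_start, c(0L, 10L))
  expect_setequal(hsps$query_start, c(0L, 20L))

  # unreachable minimum HSP score
  expect_equal(nrow(extendUngapped(prof, query, hits,
                                   minHspScore = 10^6)), 0L)
})

test_that("HSP spans on a shared diagonal never overlap", {
  for (seed in c(31, 32, 33, 34)) {
    inst <- randomInstance(seed, n = 50, identity = 0.5, flanks = c(20, 20))
    hsps <- extendUngapped(inst$profile, inst$query,
                           findHits(inst$profile, inst$query))
    if (nrow(hsps) < 2) next
    d <- hsps$target_start - hsps$query_start
    for (dg in unique(d)) {
      g <- hsps[d == dg, ]
      g <- g[order(g$target_start), ]
      if (nrow(g) > 1)
        expect_true(all(g$target_start[-1] >= g$target_end[-nrow(g)]))
    }
  }
})

test_that("gapped extension equals the anchored affine DP oracle", {
  gap <- gapParams()
  for (seed in 41:48) {
    inst <- randomInstance(seed, n = 35, identity = 0.7, flanks = c(6, 6))
    hsps <- extendUngapped(inst$profile, inst$query,
                           findHits(inst$profile, inst$query))
    if (nrow(hsps) == 0) next
    S <- oracleScheme(inst$profile)
    qc <- oracleCodes(inst$query)
    for (r in seq_len(nrow(hsps))) {
      aln <- extendGapped(inst$profile, inst$query, hsps[r, ], gap)
      anchor <- agblast:::geStartingPair(S, qc - 1L, hsps[r, ])
      expect_equal(aln$score,
                   refAnchoredScore(S, qc, anchor[["target"]],
                                    anchor[["query"]], gap@gop, gap@gep))
      # reported score equals recomputation from the columns
      expect_equal(recomputeScore(S, qc, aln$targetIdx, aln$queryIdx,
                                  gap@gop, gap@gep), aln$score)
    }
  }
})

test_that("gapped extension bridges a deletion and trims mismatch flanks", {
  seg1 <- "WYFHMCKRDENQSTV"; seg2 <- "GALIVPTSECWFYHK"
  # target carries one extra residue between two exact copies of the query
  prof <- profileFromConsensus("del", paste0(seg1, "D", seg2))
  query <- paste0(seg1, seg2)
  hsps <- extendUngapped(prof, query, findHits(prof, query))
  hsp1 <- hsps[hsps$target_start == 0 & hsps$query_start == 0, ]
  expect_equal(nrow(hsp1), 1L)
  aln <- extendGapped(prof, query, hsp1)
  b62 <- substitutionMatrix("BLOSUM62")
  selfScore <- function(s) sum(vapply(strsplit(s, "")[[1]],
                                      function(r) scorePair(b62, r, r),
                                      integer(1)))
  expect_equal(aln$score, selfScore(seg1) + selfScore(seg2) - 11 - 1)
  expect_equal(sum(is.na(aln$queryIdx)), 1L)   # a single gap column
  expect_equal(aln$targetSpan, c(0L, 31L))
  expect_equal(aln$querySpan, c(0L, 30L))

  # all-mismatch flanks: the alignment trims back to the HSP span
  core <- "WYFHMCKRDENQ"
  prof2 <- profileFromConsensus("flank", paste0("PPPPP", core, "PPPPP"))
  query2 <- paste0("GGGGG", core, "GGGGG")
  hsps2 <- extendUngapped(prof2, query2, findHits(prof2, query2))
  expect_equal(nrow(hsps2), 1L)
  aln2 <- extendGapped(prof2, query2, hsps2[1, ])
  expect_equal(aln2$targetSpan, c(5L, 17L))
  expect_equal(aln2$querySpan, c(5L, 17L))
})

test_that("all core alignment scores are integers", {
  inst <- randomInstance(51, n = 40, identity = 0.6)
  hits <- findHits(inst$profile, inst$query)
  expect_type(hits$score, "integer")
  hsps <- extendUngapped(inst$profile, inst$query, hits)
  expect_type(hsps$score, "integer")
  if (nrow(hsps)) {
    aln <- extendGapped(inst$profile, inst$query, hsps[1, ])
    expect_equal(aln$score, round(aln$score))
  }
})
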