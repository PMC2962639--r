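#' @include agblast-package.R
NULL

## ---------------------------------------------------------------------------
## ScoringProfile: a target X -- per-position 20-way score columns plus a
## consensus sequence. Rows are target positions (0-based externally).
## ---------------------------------------------------------------------------

#' ScoringProfile: a position-specific scoring matrix with consensus
#'
#' A target profile of length `n`: one row of 20 integer scores per consensus
#' position, in the canonical residue order `ARNDCQEGHILKMFPSTWYV`.
#'
#' @slot id character(1) profile identifier.
#' @slot consensus character(1) consensus sequence of length `n`.
#' @slot scores integer matrix, `n` rows by 20 columns.
#' @exportClass ScoringProfile
setClass("ScoringProfile",
  representation(id = "character", consensus = "character", scores = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- nchar(object@consensus)
    if (n < 1L) msg <- c(msg, "consensus must be non-empty")
    if (ncol(object@scores) != 20L)
      msg <- c(msg, "scores must have exactly 20 columns")
    if (nrow(object@scores) != n)
      msg <- c(msg, "consensus length must equal the number of score rows")
    if (!is.numeric(object@scores) || any(object@scores != round(object@scores)))
      msg <- c(msg, "scores must be integers")
    chars <- strsplit(object@consensus, "")[[1]]
    if (!all(chars %in% AA_ALPHABET))
      msg <- c(msg, "consensus contains characters outside the residue alphabet")
    if (length(msg)) msg else TRUE
  })

#' Construct a ScoringProfile
#'
#' @param id profile identifier.
#' @param consensus consensus sequence (string over the 20 residues plus X).
#' @param scores integer matrix with one 20-score row per consensus position,
#'   columns in `ARNDCQEGHILKMFPSTWYV` order (named columns are reordered).
#' @return a [ScoringProfile-class] object.
#' @export
#' @examples
#' scoringProfile("p", "AC", rbind(c(4, rep(-2, 19)), c(-2, 9, rep(-3, 18))))
scoringProfile <- function(id, consensus, scores) {
  scores <- as.matrix(scores)
  if (!is.null(colnames(scores)) && all(AA_ALPHABET20 %in% colnames(scores)))
    scores <- scores[, AA_ALPHABET20, drop = FALSE]
  storage.mode(scores) <- "integer"
  colnames(scores) <- AA_ALPHABET20
  rownames(scores) <- NULL
  new("ScoringProfile", id = id, consensus = toupper(consensus), scores = scores)
}

#' @describeIn scoringProfile profile length `n` (number of positions).
#' @param x a `ScoringProfile`.
#' @export
profileLength <- function(x) nchar(x@consensus)

#' @describeIn scoringProfile consensus sequence string.
#' @export
profileConsensus <- function(x) x@consensus

#' @describeIn scoringProfile the `n x 20` integer score matrix.
#' @export
profileScores <- function(x) x@scores

#' @describeIn scoringProfile profile identifier.
#' @export
profileId <- function(x) x@id

setMethod("show", "ScoringProfile", function(object) {
  cat("ScoringProfile", sQuote(object@id), "of length", profileLength(object), "\n")
  cat("  consensus:", substr(object@consensus, 1, 60),
      if (profileLength(object) > 60) "...\n" else "\n")
})

## ---------------------------------------------------------------------------
## SubstitutionMatrix
## ---------------------------------------------------------------------------

#' SubstitutionMatrix: a symmetric residue substitution score table
#'
#' @slot name character(1), e.g. `"BLOSUM62"`.
#' @slot scores square integer matrix with residue dimnames (the 20 canonical
#'   residues, optionally extended letters such as B, Z, X, *).
#' @exportClass SubstitutionMatrix
setClass("SubstitutionMatrix",
  representation(name = "character", scores = "matrix"),
  validity = function(object) {
    m <- object@scores
    msg <- character()
    if (is.null(dimnames(m)) || !identical(rownames(m), colnames(m)))
      msg <- c(msg, "scores must have identical row and column residue names")
    else {
      if (!all(AA_ALPHABET20 %in% rownames(m)))
        msg <- c(msg, "all 20 canonical residues must be present")
      if (!isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "matrix must be symmetric")
      else if (any(diag(m[AA_ALPHABET20, AA_ALPHABET20]) <= 0))
        msg <- c(msg, "diagonal entries for canonical residues must be positive")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SubstitutionMatrix", function(object) {
  cat("SubstitutionMatrix", sQuote(object@name), "over",
      nrow(object@scores), "letters\n")
})

## ---------------------------------------------------------------------------
## GapParams / FilterThresholds
## ---------------------------------------------------------------------------

#' Affine gap penalties
#'
#' A gap of length `L` costs `gop + L * gep`.
#'
#' @slot gop gap opening penalty (>= 0).
#' @slot gep gap extension penalty per residue (> 0).
#' @exportClass GapParams
setClass("GapParams", representation(gop = "numeric", gep = "numeric"),
  validity = function(object) {
    if (object@gop < 0) return("gap opening penalty must be >= 0")
    if (object@gep <= 0) return("gap extension penalty must be > 0")
    TRUE
  })

#' @param gop gap opening penalty (default 11).
#' @param gep gap extension penalty (default 1).
#' @rdname GapParams-class
#' @return a `GapParams` object.
#' @export
gapParams <- function(gop = 11, gep = 1) new("GapParams", gop = gop, gep = gep)

setMethod("show", "GapParams", function(object)
  cat("GapParams: open", object@gop, "extend", object@gep, "\n"))

#' Alignment significance thresholds
#'
#' Final alignments survive only if coverage and seed-excluded identity are
#' strictly greater than the thresholds; unseeded partial alignments shorter
#' than `minPartialFraction * n` (target length) are discarded.
#'
#' @slot minCoverage minimum percent coverage of the target (default 60).
#' @slot minIdentity minimum percent identity excluding seed columns
#'   (default 10).
#' @slot minPartialFraction minimum partial-alignment length as a fraction of
#'   the target length (default 0.10).
#' @exportClass FilterThresholds
setClass("FilterThresholds",
  representation(minCoverage = "numeric", minIdentity = "numeric",
                 minPartialFraction = "numeric"),
  validity = function(object) {
    p <- c(object@minCoverage, object@minIdentity)
    if (any(p < 0) || any(p > 100)) return("percentages must lie in [0, 100]")
    if (object@minPartialFraction < 0 || object@minPartialFraction > 1)
      return("minPartialFraction must lie in [0, 1]")
    TRUE
  })

#' @param minCoverage,minIdentity,minPartialFraction see slot documentation.
#' @rdname FilterThresholds-class
#' @return a `FilterThresholds` object.
#' @export
filterThresholds <- function(minCoverage = 60, minIdentity = 10,
                             minPartialFraction = 0.10) {
  new("FilterThresholds", minCoverage = minCoverage, minIdentity = minIdentity,
      minPartialFraction = minPartialFraction)
}

setMethod("show", "FilterThresholds", function(object)
  cat("FilterThresholds: coverage >", object@minCoverage,
      "%, identity >", object@minIdentity,
      "%, partial length >", object@minPartialFraction, "* n\n"))

## ---------------------------------------------------------------------------
## Seed / Chimera
## ---------------------------------------------------------------------------

#' Seed: a terminal fragment of a profile consensus
#'
#' The N-terminal seed is the first `k` consensus residues, the C-terminal
#' seed the last `k`, with `k = max(1, floor(p/100 * n))`. `score` is the
#' seed's self-score against its own profile columns, Score(S).
#'
#' @slot residues seed residues (length `k`).
#' @slot terminal `"N"` or `"C"`.
#' @slot profileId id of the source profile.
#' @slot score Score(S), integer self-score.
#' @exportClass Seed
setClass("Seed",
  representation(residues = "character", terminal = "character",
                 profileId = "character", score = "numeric"),
  validity = function(object) {
    if (!object@terminal %in% c("N", "C")) return("terminal must be 'N' or 'C'")
    if (nchar(object@residues) < 1L) return("seed must be non-empty")
    TRUE
  })

#' @describeIn extractSeed seed length `k`.
#' @param seed a `Seed`.
#' @export
seedLength <- function(seed) nchar(seed@residues)

#' @describeIn extractSeed the seed self-score Score(S).
#' @export
seedScore <- function(seed) seed@score

setMethod("show", "Seed", function(object)
  cat(sprintf("Seed (%s-terminal of %s): %s, Score(S) = %d\n", object@terminal,
              object@profileId, object@residues, as.integer(object@score))))

#' Chimera: a query with an embedded seed
#'
#' The chimera is `Y[0,q) | S | Y[q,m)` in 0-based coordinates: original query
#' residue `j` sits at chimera index `j` when `j < q` and at `j + k` when
#' `j >= q`; the seed occupies chimera indices `[q, q + k)`.
#'
#' @slot queryId query identifier.
#' @slot residues chimera residues, length `m + k`.
#' @slot seed the embedded [Seed-class].
#' @slot q 0-based insertion position, `0 <= q <= m`.
#' @slot m original query length.
#' @exportClass Chimera
setClass("Chimera",
  representation(queryId = "character", residues = "character",
                 seed = "Seed", q = "integer", m = "integer"),
  validity = function(object) {
    k <- seedLength(object@seed)
    if (object@q < 0L || object@q > object@m)
      return("q must lie in [0, m]")
    if (nchar(object@residues) != object@m + k)
      return("chimera length must be m + k")
    if (substr(object@residues, object@q + 1L, object@q + k) !=
        object@seed@residues)
      return("seed span does not match the seed residues")
    TRUE
  })

setMethod("show", "Chimera", function(object)
  cat(sprintf("Chimera of %s: %s-terminal seed of %s at q = %d (length %d)\n",
              object@queryId, object@seed@terminal, object@seed@profileId,
              object@q, nchar(object@residues))))

## ---------------------------------------------------------------------------
## FinalAlignment
## ---------------------------------------------------------------------------

#' FinalAlignment: a seeded alignment surviving (or subject to) filtering
#'
#' Alignment columns are stored as parallel index vectors (`NA` = gap);
#' query-side indices are chimera coordinates. `queryRange` is the half-open
#' span of aligned non-seed residues in original query coordinates
#' (`c(NA, NA)` when the alignment is seed-only).
#'
#' @slot queryId,profileId identifiers.
#' @slot terminal `"N"` or `"C"` seed terminal.
#' @slot q 0-based seed insertion position (original query coordinates).
#' @slot seedSpan half-open seed span in chimera coordinates.
#' @slot targetIdx,queryIdx 0-based aligned indices per column (`NA` = gap).
#' @slot rawScore,adjustedScore alignment scores before/after the length
#'   adjustment.
#' @slot coveragePct percent of the target length covered by the alignment.
#' @slot identityPct percent identical columns, seed columns excluded.
#' @slot queryRange half-open original-query span of the non-seed alignment.
#' @exportClass FinalAlignment
setClass("FinalAlignment",
  representation(queryId = "character", profileId = "character",
                 terminal = "character", q = "integer",
                 seedSpan = "integer", targetIdx = "integer",
                 queryIdx = "integer", rawScore = "numeric",
                 adjustedScore = "numeric", coveragePct = "numeric",
                 identityPct = "numeric", queryRange = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@targetIdx) != length(object@queryIdx))
      msg <- c(msg, "targetIdx and queryIdx must have equal length")
    if (any(is.na(object@targetIdx) & is.na(object@queryIdx)))
      msg <- c(msg, "no column may be a gap on both sides")
    ti <- object@targetIdx[!is.na(object@targetIdx)]
    qi <- object@queryIdx[!is.na(object@queryIdx)]
    if (is.unsorted(ti, strictly = TRUE) || is.unsorted(qi, strictly = TRUE))
      msg <- c(msg, "aligned indices must be strictly increasing")
    if (object@coveragePct < 0 || object@coveragePct > 100 ||
        object@identityPct < 0 || object@identityPct > 100)
      msg <- c(msg, "coverage and identity must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })

#' @describeIn alignmentTable half-open target span of a single alignment.
#' @param aln a `FinalAlignment`.
#' @export
targetSpan <- function(aln) {
  ti <- aln@targetIdx[!is.na(aln@targetIdx)]
  c(min(ti), max(ti) + 1L)
}

#' @describeIn alignmentTable half-open chimera-coordinate query span.
#' @export
querySpan <- function(aln) {
  qi <- aln@queryIdx[!is.na(aln@queryIdx)]
  c(min(qi), max(qi) + 1L)
}

#' @describeIn alignmentTable percent coverage accessor.
#' @export
coveragePct <- function(aln) aln@coveragePct

#' @describeIn alignmentTable percent seed-excluded identity accessor.
#' @export
identityPct <- function(aln) aln@identityPct

setMethod("show", "FinalAlignment", function(object) {
  ts <- targetSpan(object); qs <- querySpan(object)
  cat(sprintf(paste0("FinalAlignment %s vs %s (%s seed at q = %d): target ",
                     "[%d,%d) query [%d,%d), raw %g, adj %.2f, cov %.1f%%, ",
                     "id %.1f%%\n"),
              object@queryId, object@profileId, object@terminal, object@q,
              ts[1], ts[2], qs[1], qs[2], object@rawScore,
              object@adjustedScore, object@coveragePct, object@identityPct))
})

## ---------------------------------------------------------------------------
## SearchResult
## ---------------------------------------------------------------------------

#' SearchResult: the outcome of a seeded search for one (query, profile) pair
#'
#' @slot queryId,profileId identifiers.
#' @slot method `"adaptive"` or `"exhaustive"`.
#' @slot alignments list of surviving [FinalAlignment-class] objects, sorted
#'   by (terminal, q, target start).
#' @slot dpInvocations number of seeded dynamic-programming runs performed.
#' @slot nPartials number of unseeded partial alignments found (adaptive only;
#'   `NA` for exhaustive).
#' @exportClass SearchResult
setClass("SearchResult",
  representation(queryId = "character", profileId = "character",
                 method = "character", alignments = "list",
                 dpInvocations = "integer", nPartials = "integer"))

#' @describeIn adaptiveSearch list of surviving alignments in a result.
#' @param result a `SearchResult`.
#' @export
alignments <- function(result) result@alignments

#' @describeIn adaptiveSearch number of seeded DP invocations performed.
#' @export
dpInvocations <- function(result) result@dpInvocations

setMethod("show", "SearchResult", function(object)
  cat(sprintf("SearchResult (%s): %s vs %s, %d surviving alignment(s), %d seeded DP run(s)\n",
              object@method, object@queryId, object@profileId,
              length(object@alignments), object@dpInvocations)))

## ---------------------------------------------------------------------------
## PositionalTrack
## ---------------------------------------------------------------------------

#' PositionalTrack: a per-residue structural-signal curve
#'
#' @slot proteinId protein identifier.
#' @slot scores one value per residue.
#' @slot stage one of `"raw"`, `"normalized"`, `"smoothed"`, `"baselined"`.
#' @exportClass PositionalTrack
setClass("PositionalTrack",
  representation(proteinId = "character", scores = "numeric",
                 stage = "character"),
  validity = function(object) {
    if (!object@stage %in% c("raw", "normalized", "smoothed", "baselined"))
      return("unknown stage")
    if (object@stage == "normalized" &&
        abs(mean(object@scores)) > 1e-9)
      return("normalized track must have mean zero")
    TRUE
  })

#' @describeIn positionalTrack numeric scores of a track.
#' @param track a `PositionalTrack`.
#' @export
trackScores <- function(track) track@scores

#' @describeIn positionalTrack processing stage of a track.
#' @export
trackStage <- function(track) track@stage

setMethod("show", "PositionalTrack", function(object)
  cat(sprintf("PositionalTrack for %s (%s), %d residues, range [%.3f, %.3f]\n",
              object@proteinId, object@stage, length(object@scores),
              min(object@scores), max(object@scores))))
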