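#' @include AllClasses.R
NULL

#' Load a substitution matrix
#'
#' Reads a matrix in the standard NCBI text layout. `BLOSUM62` and `BLOSUM45`
#' are bundled with the package.
#'
#' @param name `"BLOSUM62"` or `"BLOSUM45"`, or the name for a custom file.
#' @param path optional path to an NCBI-layout matrix file; overrides the
#'   bundled tables.
#' @return a [SubstitutionMatrix-class].
#' @export
#' @examples
#' b62 <- substitutionMatrix("BLOSUM62")
#' scorePair(b62, "W", "W")  # 11
substitutionMatrix <- function(name = c("BLOSUM62", "BLOSUM45"), path = NULL) {
  if (is.null(path)) {
    name <- match.arg(name)
    path <- system.file("extdata", paste0(name, ".txt"), package = "agblast",
                        mustWork = TRUE)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  letters <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lines[-1]
  m <- matrix(0L, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (l in rows) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) != length(letters) + 1L)
      stop("malformed matrix row: ", l)
    m[tok[1], ] <- as.integer(tok[-1])
  }
  new("SubstitutionMatrix", name = name, scores = m)
}

# Build the internal scoring scheme: an n x 21 integer matrix of scores for
# each target position against the 20 residues plus X. With a substitution
# matrix, row i is the matrix row of consensus[i]; otherwise the profile's
# own PSSM columns are used (X scored from the matrix's X row if present,
# else -1, a BLAST-like conservative default).
scoringScheme <- function(profile, matrix = NULL, xScore = -1L) {
  n <- profileLength(profile)
  cons <- strsplit(profileConsensus(profile), "")[[1]]
  if (is.null(matrix)) {
    S <- cbind(profileScores(profile), X = rep(as.integer(xScore), n))
  } else {
    m <- matrix@scores
    xcol <- if ("X" %in% colnames(m)) m[AA_ALPHABET, "X"] else NULL
    S <- t(vapply(cons, function(r) {
      row <- m[r, AA_ALPHABET20]
      c(row, X = if (is.null(xcol)) as.integer(xScore) else m[r, "X"])
    }, integer(21L)))
    rownames(S) <- NULL
  }
  storage.mode(S) <- "integer"
  S
}

#' Score one target position against one query residue
#'
#' With a [ScoringProfile-class] the score is the PSSM column entry; with a
#' [SubstitutionMatrix-class] plus the profile consensus it equals
#' `matrix[consensus[pos], residue]`.
#'
#' @param x a `ScoringProfile` or `SubstitutionMatrix`.
#' @param pos 0-based target position (`ScoringProfile`), or the target
#'   residue (`SubstitutionMatrix`).
#' @param residue query residue (single letter).
#' @return integer score.
#' @export
scorePair <- function(x, pos, residue) {
  residue <- toupper(residue)
  if (is(x, "SubstitutionMatrix"))
    return(as.integer(x@scores[toupper(pos), residue]))
  if (!is.numeric(pos) || pos < 0 || pos >= profileLength(x))
    stop("position out of range")
  code <- encodeResidues(residue) + 1L
  S <- scoringScheme(x)
  as.integer(S[pos + 1L, code])
}

#' Find word hits between a profile and a query
#'
#' Exhaustively scans all (target, query) offset pairs for words of
#' `wordSize` consecutive residues whose summed per-position score exceeds
#' `minWordScore`.
#'
#' @param profile a [ScoringProfile-class].
#' @param query residue string.
#' @param wordSize word size `w` (default 3).
#' @param minWordScore minimum word score threshold (default 11); a hit
#'   requires a word score strictly greater than this.
#' @param matrix optional [SubstitutionMatrix-class] used instead of the
#'   PSSM columns.
#' @return data frame with 0-based `target_start`, `query_start`, `score`.
#' @export
findHits <- function(profile, query, wordSize = 3L, minWordScore = 11L,
                     matrix = NULL) {
  stopifnot(wordSize >= 1L)
  S <- scoringScheme(profile, matrix)
  qc <- encodeResidues(query)
  as.data.frame(cpp_find_hits(S, qc, as.integer(wordSize),
                              as.integer(minWordScore)))
}

#' Extend word hits into ungapped HSPs
#'
#' Each unconsumed hit is extended in both directions along its diagonal
#' until the running score drops more than `dropoff` below the running
#' maximum, then trimmed back to the maximum. Every constructed HSP consumes
#' the hits it covers, so later HSPs never overlap it on the same diagonal;
#' only HSPs scoring strictly above `minHspScore` are returned.
#'
#' @inheritParams findHits
#' @param hits data frame from [findHits()].
#' @param dropoff HSP drop-off score (default 7).
#' @param minHspScore minimum HSP score (default 25).
#' @return data frame with 0-based half-open `target_start`, `target_end`,
#'   `query_start`, `query_end` and `score`.
#' @export
extendUngapped <- function(profile, query, hits, wordSize = 3L, dropoff = 7L,
                           minHspScore = 25L, matrix = NULL) {
  S <- scoringScheme(profile, matrix)
  qc <- encodeResidues(query)
  h <- as.matrix(hits[, c("target_start", "query_start", "score")])
  storage.mode(h) <- "integer"
  as.data.frame(cpp_extend_ungapped(S, qc, h, as.integer(wordSize),
                                    as.integer(dropoff),
                                    as.integer(minHspScore)))
}

# Locate the GE starting pair of an HSP: the central residue pair of its
# maximal-scoring window of length min(11, HSP length); leftmost window on
# ties.
geStartingPair <- function(S, qc, hsp) {
  xs <- hsp[["target_start"]]; xe <- hsp[["target_end"]]
  d <- xs - hsp[["query_start"]]
  len <- xe - xs
  s <- vapply(xs:(xe - 1L), function(t) S[t + 1L, qc[t - d + 1L] + 1L],
              integer(1))
  L <- min(11L, len)
  sums <- vapply(seq_len(len - L + 1L),
                 function(w) sum(s[w:(w + L - 1L)]), numeric(1))
  w0 <- which.max(sums)                       # leftmost maximal window
  center <- (w0 - 1L) + (L - 1L) %/% 2L       # 0-based offset into the HSP
  c(target = xs + center, query = xs + center - d)
}

#' Gapped extension of an HSP into a local alignment
#'
#' Affine-gap extension in both directions from the GE starting pair (the
#' central pair of the HSP's maximal-scoring length-11 window, or of the
#' whole HSP when shorter). Each direction is trimmed at its score maximum,
#' so the result equals a full Smith-Waterman affine-gap alignment restricted
#' to paths through the GE starting pair.
#'
#' @inheritParams findHits
#' @param hsp one row of the data frame from [extendUngapped()] (a list or
#'   one-row data frame with `target_start`, `target_end`, `query_start`,
#'   `query_end`).
#' @param gap a [GapParams-class].
#' @return a list with `targetIdx`, `queryIdx` (0-based aligned indices,
#'   `NA` = gap), `score`, and the half-open `targetSpan` / `querySpan`.
#' @export
extendGapped <- function(profile, query, hsp, gap = gapParams(),
                         matrix = NULL) {
  S <- scoringScheme(profile, matrix)
  qc <- encodeResidues(query)
  anchor <- geStartingPair(S, qc, hsp)
  fw <- cpp_extend_affine(S, qc, anchor[["target"]], anchor[["query"]], 1L,
                          gap@gop, gap@gep, 0, 0, FALSE)
  bw <- cpp_extend_affine(S, qc, anchor[["target"]], anchor[["query"]], -1L,
                          gap@gop, gap@gep, 0, 0, FALSE)
  bpath <- bw$path; fpath <- fw$path
  gapify <- function(v) ifelse(v < 0L, NA_integer_, v)
  targetIdx <- c(gapify(rev(bpath[, "target"])), anchor[["target"]],
                 gapify(fpath[, "target"]))
  queryIdx <- c(gapify(rev(bpath[, "query"])), anchor[["query"]],
                gapify(fpath[, "query"]))
  score <- unname(S[anchor[["target"]] + 1L, qc[anchor[["query"]] + 1L] + 1L]) +
    fw$value + bw$value
  ti <- targetIdx[!is.na(targetIdx)]; qi <- queryIdx[!is.na(queryIdx)]
  list(targetIdx = as.integer(targetIdx), queryIdx = as.integer(queryIdx),
       score = score,
       targetSpan = c(min(ti), max(ti) + 1L),
       querySpan = c(min(qi), max(qi) + 1L))
}
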