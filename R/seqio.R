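#' @include AllClasses.R
NULL

#' Read protein sequences from a FASTA file
#'
#' Records are uppercased and validated against the 20-letter amino-acid
#' alphabet plus X. Wrapped sequence lines are concatenated.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of residue strings (names = record ids,
#'   the first whitespace-delimited token of each header).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, AA_ALPHABET)
    if (length(bad))
      stop(sprintf("record %d (%s): non-amino-acid character(s) %s",
                   i, ids[i], paste(bad, collapse = ", ")))
    if (nchar(seqs[[i]]) == 0L)
      stop(sprintf("record %d (%s): empty sequence", i, ids[i]))
  }
  if (anyDuplicated(ids)) {
    d <- which(duplicated(ids))[1]
    stop(sprintf("duplicate id %s at record %d", sQuote(ids[d]), d))
  }
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector of residue strings.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return the path, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a plain-text PSSM
#'
#' Two dialects are accepted and auto-detected:
#' \describe{
#'   \item{plain}{a header row of the 20 residue letters, then one row per
#'     position: `index  consensus-residue  20 integer scores`. Comment lines
#'     start with `#`. Indices are 0-based.}
#'   \item{PSI-BLAST ASCII}{the layout written by `psiblast -out_ascii_pssm`;
#'     only the first 20-column score block is used.}
#' }
#'
#' @param path path to the PSSM file.
#' @param id profile id; defaults to the file name without extension.
#' @return a [ScoringProfile-class].
#' @export
readPssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  if (any(grepl("position-specific scoring matrix", lines, ignore.case = TRUE)))
    .readPssmPsiblast(lines, id)
  else
    .readPssmPlain(lines, id)
}

.readPssmPlain <- function(lines, id) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("PSSM file has no data rows")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 20L || !setequal(header, AA_ALPHABET20))
    stop("plain PSSM header must list the 20 residue letters")
  ord <- match(AA_ALPHABET20, header)
  rows <- lines[-1]
  cons <- character(length(rows))
  scores <- matrix(0L, length(rows), 20L)
  for (r in seq_along(rows)) {
    tok <- strsplit(trimws(rows[r]), "\\s+")[[1]]
    if (length(tok) != 22L)
      stop(sprintf("PSSM row %d: expected 20 scores, found %d",
                   r, length(tok) - 2L))
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals) || any(vals != round(vals)))
      stop(sprintf("PSSM row %d: non-integer score", r))
    cons[r] <- toupper(tok[2])
    scores[r, ] <- as.integer(vals)[ord]
  }
  scoringProfile(id, paste(cons, collapse = ""), scores)
}

.readPssmPsiblast <- function(lines, id) {
  # header line carrying the residue letters twice (scores, then percentages)
  hidx <- which(vapply(lines, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    length(tok) >= 20L && all(tok[1:20] %in% AA_ALPHABET20)
  }, logical(1)))[1]
  if (is.na(hidx)) stop("could not locate PSI-BLAST PSSM header row")
  header <- strsplit(trimws(lines[hidx]), "\\s+")[[1]][1:20]
  ord <- match(AA_ALPHABET20, header)
  cons <- character(); scores <- NULL
  for (l in lines[-seq_len(hidx)]) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) < 22L || is.na(suppressWarnings(as.integer(tok[1])))) break
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals) || any(vals != round(vals)))
      stop(sprintf("PSI-BLAST PSSM row %d: non-integer score", length(cons) + 1L))
    cons <- c(cons, toupper(tok[2]))
    scores <- rbind(scores, as.integer(vals)[ord])
  }
  if (length(cons) == 0L) stop("PSI-BLAST PSSM has no data rows")
  scoringProfile(id, paste(cons, collapse = ""), scores)
}

#' Write a ScoringProfile as plain-text PSSM
#'
#' @param profile a [ScoringProfile-class].
#' @param path output path.
#' @param dialect `"plain"` (this package's dialect) or `"psiblast"`
#'   (PSI-BLAST ASCII layout; the percentage block is written as zeros).
#' @return the path, invisibly.
#' @export
writePssm <- function(profile, path, dialect = c("plain", "psiblast")) {
  dialect <- match.arg(dialect)
  n <- profileLength(profile)
  cons <- strsplit(profileConsensus(profile), "")[[1]]
  sc <- profileScores(profile)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "plain") {
    writeLines(c("# plain PSSM dialect; coordinates 0-based, half-open",
                 paste(AA_ALPHABET20, collapse = " ")), con)
    for (r in seq_len(n))
      writeLines(paste(r - 1L, cons[r], paste(sc[r, ], collapse = " ")), con)
  } else {
    writeLines(c("",
                 "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
                 paste0("            ", paste(sprintf("%3s", AA_ALPHABET20), collapse = ""),
                        " ", paste(sprintf("%3s", AA_ALPHABET20), collapse = ""))), con)
    for (r in seq_len(n))
      writeLines(paste0(sprintf("%5d %s  ", r, cons[r]),
                        paste(sprintf("%3d", sc[r, ]), collapse = " "), "  ",
                        paste(rep("  0", 20), collapse = " "),
                        "  0.00 0.00"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write / read an N x M profile matrix as TSV
#'
#' First row: column ids; first column: row ids. Values round-trip bit-exactly
#' for integers and to at least 12 significant digits for reals.
#'
#' @param mat numeric matrix with non-negative entries.
#' @param rowIds,colIds identifiers; default to the matrix dimnames.
#' @param path file path.
#' @return `writeProfileMatrix`: the path, invisibly.
#' @export
writeProfileMatrix <- function(mat, path, rowIds = rownames(mat),
                               colIds = colnames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(rowIds) || is.null(colIds) ||
      length(rowIds) == 0L || length(colIds) == 0L)
    stop("row and column id lists must be non-empty")
  if (length(rowIds) != nrow(mat) || length(colIds) != ncol(mat))
    stop("id lists do not match the matrix dimensions")
  dimnames(mat) <- list(rowIds, colIds)
  df <- data.frame(id = rowIds, format(mat, digits = 15, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileMatrix
#' @return `readProfileMatrix`: the numeric matrix with dimnames restored.
#' @export
readProfileMatrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  mat
}

#' Tabulate final alignments
#'
#' Flattens a list of [FinalAlignment-class] objects (or a
#' [SearchResult-class]) into a data frame, one row per alignment, including
#' the aligned-string triplet (target, match line, query). Coordinates are
#' 0-based, half-open; query spans are chimera coordinates.
#'
#' @param alignments a list of `FinalAlignment` objects or a `SearchResult`.
#' @param profile the [ScoringProfile-class] the alignments refer to
#'   (required for the aligned strings; omit for a coordinate-only table).
#' @param chimeras optional named list of [Chimera-class] residue strings used
#'   to render the query row of the triplet.
#' @return a data frame.
#' @export
alignmentTable <- function(alignments, profile = NULL, chimeras = NULL) {
  if (is(alignments, "SearchResult")) alignments <- alignments@alignments
  if (length(alignments) == 0L) {
    return(data.frame(query_id = character(), profile_id = character(),
                      terminal = character(), q = integer(),
                      target_start = integer(), target_end = integer(),
                      query_start = integer(), query_end = integer(),
                      raw_score = numeric(), adjusted_score = numeric(),
                      coverage_pct = numeric(), identity_pct = numeric(),
                      aligned_target = character(), aligned_match = character(),
                      aligned_query = character()))
  }
  rows <- lapply(alignments, function(a) {
    ts <- targetSpan(a); qs <- querySpan(a)
    trip <- c("", "", "")
    if (!is.null(profile)) {
      cons <- strsplit(profileConsensus(profile), "")[[1]]
      qres <- if (!is.null(chimeras)) {
        key <- paste0(a@terminal, a@q)
        strsplit(chimeras[[key]], "")[[1]]
      } else NULL
      tchr <- ifelse(is.na(a@targetIdx), "-", cons[a@targetIdx + 1L])
      qchr <- if (is.null(qres)) ifelse(is.na(a@queryIdx), "-", "?")
              else ifelse(is.na(a@queryIdx), "-", qres[a@queryIdx + 1L])
      mchr <- ifelse(!is.na(a@targetIdx) & !is.na(a@queryIdx) & tchr == qchr,
                     "|", " ")
      trip <- c(paste(tchr, collapse = ""), paste(mchr, collapse = ""),
                paste(qchr, collapse = ""))
    }
    data.frame(query_id = a@queryId, profile_id = a@profileId,
               terminal = a@terminal, q = a@q,
               target_start = ts[1], target_end = ts[2],
               query_start = qs[1], query_end = qs[2],
               raw_score = a@rawScore, adjusted_score = a@adjustedScore,
               coverage_pct = a@coveragePct, identity_pct = a@identityPct,
               aligned_target = trip[1], aligned_match = trip[2],
               aligned_query = trip[3])
  })
  do.call(rbind, rows)
}

#' @describeIn alignmentTable write the table as TSV (with a 0-based
#'   coordinate header comment).
#' @param path output path.
#' @export
writeAlignments <- function(alignments, path, profile = NULL, chimeras = NULL) {
  tab <- alignmentTable(alignments, profile, chimeras)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates 0-based, half-open [start, end)", con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
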