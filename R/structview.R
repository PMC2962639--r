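#' @include profiling.R
NULL

# merge 0-based half-open intervals into their union components
mergeIntervals <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { out <- rbind(out, c(ms, me)); ms <- starts[i]; me <- ends[i] }
  }
  rbind(out, c(ms, me))
}

#' Per-residue structural-signal track from overlapping alignments
#'
#' For every profile with at least one surviving alignment, the union of the
#' survivors' query spans (original coordinates) is taken as the alignment
#' boundary; each union region is realigned against the full profile
#' consensus by affine-gap Smith-Waterman under each substitution matrix.
#' Aligned protein residues score 2 when identical to the consensus and 1
#' when the substitution score is positive (conserved but not identical);
#' gap-aligned residues score 0. Per-matrix tracks are summed over profiles,
#' then averaged across the matrices (BLOSUM62 and BLOSUM45 by default).
#'
#' @param protein protein residue string (a named vector supplies the id).
#' @param results list of [SearchResult-class] objects (one per profile) for
#'   this protein, or a list of survivor lists.
#' @param profiles list of the corresponding [ScoringProfile-class] objects;
#'   matched to results by profile id.
#' @param matrices list of [SubstitutionMatrix-class] objects to average
#'   over (default BLOSUM62 and BLOSUM45).
#' @param gap a [GapParams-class] for the realignment.
#' @param proteinId protein identifier.
#' @return a [PositionalTrack-class] with stage `"raw"` (all zero when no
#'   profile has survivors).
#' @export
positionalTrack <- function(protein, results, profiles,
                            matrices = list(substitutionMatrix("BLOSUM62"),
                                            substitutionMatrix("BLOSUM45")),
                            gap = gapParams(), proteinId = NULL) {
  if (is.null(proteinId))
    proteinId <- if (!is.null(names(protein))) names(protein)[1] else "protein"
  protein <- toupper(unname(protein[1]))
  L <- nchar(protein)
  pids <- vapply(profiles, profileId, character(1))
  perMatrix <- lapply(matrices, function(mx) numeric(L))
  for (res in results) {
    survivors <- if (is(res, "SearchResult")) res@alignments else res
    if (length(survivors) == 0L) next
    pid <- if (is(res, "SearchResult")) res@profileId
           else survivors[[1]]@profileId
    profile <- profiles[[match(pid, pids)]]
    spans <- t(vapply(survivors, function(a) a@queryRange, integer(2)))
    spans <- spans[!is.na(spans[, 1]), , drop = FALSE]
    if (nrow(spans) == 0L) next
    merged <- mergeIntervals(spans[, 1], spans[, 2])
    cons <- strsplit(profileConsensus(profile), "")[[1]]
    for (r in seq_len(nrow(merged))) {
      s <- merged[r, 1]; e <- merged[r, 2]
      region <- substr(protein, s + 1L, e)
      rc <- encodeResidues(region)
      for (mi in seq_along(matrices)) {
        mx <- matrices[[mi]]
        S <- scoringScheme(profile, mx)
        sw <- cpp_smith_waterman(S, rc, gap@gop, gap@gep)
        path <- sw$path
        if (nrow(path) == 0L) next
        ok <- path[, "target"] >= 0L & path[, "query"] >= 0L
        tpos <- path[ok, "target"]; qpos <- path[ok, "query"]
        res_chr <- substring(region, qpos + 1L, qpos + 1L)
        con_chr <- cons[tpos + 1L]
        pts <- ifelse(res_chr == con_chr, 2,
                      ifelse(mx@scores[cbind(con_chr, res_chr)] > 0, 1, 0))
        idx <- s + qpos + 1L
        perMatrix[[mi]][idx] <- perMatrix[[mi]][idx] + pts
      }
    }
  }
  raw <- Reduce(`+`, perMatrix) / length(matrices)
  new("PositionalTrack", proteinId = proteinId, scores = raw, stage = "raw")
}

#' @describeIn smoothAndBaseline center a raw track to mean zero.
#' @export
normalizeTrack <- function(track) {
  stopifnot(is(track, "PositionalTrack"))
  new("PositionalTrack", proteinId = track@proteinId,
      scores = track@scores - mean(track@scores), stage = "normalized")
}

#' @describeIn smoothAndBaseline centered moving average of width `window`
#'   with edge truncation (the mean of the available neighbours near the
#'   ends); a linear-phase low-pass step.
#' @export
smoothTrack <- function(track, window = 8L) {
  stopifnot(is(track, "PositionalTrack"))
  if (track@stage != "normalized")
    stop("smoothTrack expects a normalized track; see normalizeTrack()")
  s <- track@scores
  L <- length(s)
  if (window < 1L || window > L) stop("window must lie in [1, track length]")
  halfL <- (window - 1L) %/% 2L
  halfR <- window %/% 2L
  sm <- vapply(seq_len(L), function(i)
    mean(s[max(1L, i - halfL):min(L, i + halfR)]), numeric(1))
  new("PositionalTrack", proteinId = track@proteinId, scores = sm,
      stage = "smoothed")
}

#' Smooth and baseline a normalized positional track
#'
#' Smoothing is a centered moving average of width `window`; discontinuous
#' baselining subtracts the piecewise-linear curve through every strict local
#' minimum of the smoothed track (endpoints included as anchors), so the
#' result is exactly 0 at each anchor.
#'
#' @param track a [PositionalTrack-class] with stage `"normalized"` (from
#'   [normalizeTrack()]).
#' @param window smoothing width in residues (default 8).
#' @return a `PositionalTrack` with stage `"baselined"`.
#' @export
smoothAndBaseline <- function(track, window = 8L) {
  sm <- smoothTrack(track, window)
  s <- sm@scores
  L <- length(s)
  interior <- if (L >= 3L)
    which(s[2:(L - 1L)] < s[1:(L - 2L)] & s[2:(L - 1L)] < s[3:L]) + 1L
  else integer()
  anchors <- sort(unique(c(1L, interior, L)))
  baseline <- if (length(anchors) == 1L) rep(s[anchors], L)
              else approx(anchors, s[anchors], xout = seq_len(L))$y
  new("PositionalTrack", proteinId = track@proteinId,
      scores = s - baseline, stage = "baselined")
}

#' Tabulate all stages of a positional track
#'
#' @param protein protein residue string.
#' @param rawTrack a raw [PositionalTrack-class] from [positionalTrack()].
#' @param window smoothing width (default 8).
#' @return data frame with 0-based `position`, `residue`, and `raw`,
#'   `normalized`, `smoothed`, `baselined` columns.
#' @export
trackTable <- function(protein, rawTrack, window = 8L) {
  protein <- toupper(unname(protein[1]))
  nt <- normalizeTrack(rawTrack)
  st <- smoothTrack(nt, window)
  bt <- smoothAndBaseline(nt, window)
  data.frame(position = seq_along(rawTrack@scores) - 1L,
             residue = strsplit(protein, "")[[1]],
             raw = rawTrack@scores, normalized = nt@scores,
             smoothed = st@scores, baselined = bt@scores)
}

#' @describeIn trackTable write the table as TSV (0-based positions).
#' @param path output path.
#' @export
writeTrack <- function(protein, rawTrack, path, window = 8L) {
  tab <- trackTable(protein, rawTrack, window)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions 0-based", con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
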