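#' @include structview.R
NULL

# cached BLOSUM62 for profile construction
.fixtureEnv <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.fixtureEnv$b62)) .fixtureEnv$b62 <- substitutionMatrix("BLOSUM62")
  .fixtureEnv$b62
}

#' Build a profile whose columns are substitution-matrix rows of a consensus
#'
#' Position `i` scores residue `r` as `matrix[consensus[i], r]`, so the
#' consensus self-score is the matrix diagonal sum and each column peaks at
#' its consensus residue.
#'
#' @param id profile identifier.
#' @param consensus consensus residue string.
#' @param matrix a [SubstitutionMatrix-class] (default BLOSUM62).
#' @return a [ScoringProfile-class].
#' @export
profileFromConsensus <- function(id, consensus, matrix = .blosum62()) {
  consensus <- toupper(consensus)
  cons <- strsplit(consensus, "")[[1]]
  scores <- matrix@scores[cons, AA_ALPHABET20, drop = FALSE]
  scoringProfile(id, consensus, scores)
}

#' Generate a random scoring profile
#'
#' Draws a uniform-random consensus over the 20 residues and derives the PSSM
#' columns from the BLOSUM62 rows of the consensus. Deterministic per seed.
#'
#' @param n profile length (`n >= 5`).
#' @param rngSeed integer seed.
#' @param id profile identifier.
#' @return a [ScoringProfile-class].
#' @export
generateProfile <- function(n, rngSeed, id = sprintf("prof%d", rngSeed)) {
  if (n < 5L) stop("profile length must be at least 5")
  withSeed(rngSeed, .rProfile(n, id))
}

.rProfile <- function(n, id) {
  consensus <- paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
  profileFromConsensus(id, consensus)
}

#' Specification of a planted homologous domain
#'
#' @param identity planted identity as a fraction in (0, 1]: each domain
#'   position is replaced, independently with probability `1 - identity`, by
#'   a residue drawn uniformly from the other 19.
#' @param flankLengths integer(2): lengths of the random N- and C-terminal
#'   flanks around the planted copy (default 30 and 30).
#' @param rngSeed integer seed.
#' @param indelRate per-position probability of an indel in the planted copy
#'   (half deletions, half single-residue insertions). Defaults to 0 so the
#'   ground-truth span stays exact.
#' @return a `PlantSpec` list.
#' @export
plantSpec <- function(identity, flankLengths = c(30L, 30L), rngSeed = 1L,
                      indelRate = 0) {
  stopifnot(identity > 0, identity <= 1, length(flankLengths) == 2L,
            all(flankLengths >= 0), indelRate >= 0, indelRate < 1)
  structure(list(identity = identity,
                 flankLengths = as.integer(flankLengths),
                 rngSeed = as.integer(rngSeed), indelRate = indelRate),
            class = "PlantSpec")
}

#' Plant a mutated copy of a profile consensus into a random query
#'
#' The query is `random flank | mutated consensus copy | random flank`. The
#' returned ground-truth span (0-based, half-open) locates the planted copy;
#' `realizedIdentity` records the fraction of copy positions left identical.
#'
#' @param profile a [ScoringProfile-class].
#' @param spec a [plantSpec()].
#' @param id query identifier.
#' @return list with `sequence` (named residue string), `span`,
#'   `realizedIdentity`.
#' @export
plantHomolog <- function(profile, spec,
                         id = paste0(profileId(profile), "_plant")) {
  stopifnot(inherits(spec, "PlantSpec"))
  withSeed(spec$rngSeed, .rPlant(profile, spec, id))
}

.rPlant <- function(profile, spec, id) {
  cons <- strsplit(profileConsensus(profile), "")[[1]]
  n <- length(cons)
  mutate <- runif(n) > spec$identity
  copy <- cons
  for (i in which(mutate))
    copy[i] <- sample(setdiff(AA_ALPHABET20, cons[i]), 1L)
  realized <- mean(copy == cons)
  if (spec$indelRate > 0) {
    keep <- runif(length(copy)) >= spec$indelRate / 2
    copy <- copy[keep]
    ins <- runif(length(copy)) < spec$indelRate / 2
    if (any(ins)) {
      out <- character(0)
      for (i in seq_along(copy)) {
        out <- c(out, copy[i])
        if (ins[i]) out <- c(out, sample(AA_ALPHABET20, 1L))
      }
      copy <- out
    }
  }
  f1 <- spec$flankLengths[1]; f2 <- spec$flankLengths[2]
  flank1 <- sample(AA_ALPHABET20, f1, replace = TRUE)
  flank2 <- sample(AA_ALPHABET20, f2, replace = TRUE)
  seqv <- paste(c(flank1, copy, flank2), collapse = "")
  list(sequence = stats::setNames(seqv, id),
       span = c(f1, f1 + length(copy)),
       realizedIdentity = realized)
}

#' Generate a planted-domain fold benchmark
#'
#' One hidden profile per fold group; each group member is an independent
#' planted-homolog draw from its group's profile. A desk-scale stand-in for
#' curated twilight-zone fold benchmarks: members of a group share a common
#' ancestor profile at the chosen identity, members of different groups are
#' unrelated.
#'
#' @param nGroups number of fold groups (>= 1).
#' @param membersPerGroup queries per group (>= 1).
#' @param identity planted identity fraction.
#' @param rngSeed integer seed; output is byte-identical per seed.
#' @param profileLength length of each group profile (default 60).
#' @param flankLengths flank lengths around each planted copy (default 30).
#' @return list with `queries` (named residue strings), `labels` (named group
#'   vector), `profiles` (list of [ScoringProfile-class]), and `truth` (data
#'   frame of planted spans and realized identities).
#' @export
generateBenchmark <- function(nGroups, membersPerGroup, identity, rngSeed,
                              profileLength = 60L, flankLengths = c(30L, 30L)) {
  stopifnot(nGroups >= 1L, membersPerGroup >= 1L)
  withSeed(rngSeed, {
    profiles <- list()
    queries <- character(0)
    labels <- character(0)
    truth <- NULL
    for (g in seq_len(nGroups)) {
      gid <- sprintf("group%02d", g)
      prof <- .rProfile(profileLength, gid)
      profiles[[g]] <- prof
      for (mbr in seq_len(membersPerGroup)) {
        qid <- sprintf("%s_m%02d", gid, mbr)
        spec <- structure(list(identity = identity,
                               flankLengths = as.integer(flankLengths),
                               rngSeed = NA_integer_, indelRate = 0),
                          class = "PlantSpec")
        pl <- .rPlant(prof, spec, qid)
        queries[qid] <- unname(pl$sequence)
        labels[qid] <- gid
        truth <- rbind(truth, data.frame(query_id = qid, group = gid,
                                         span_start = pl$span[1],
                                         span_end = pl$span[2],
                                         realized_identity = pl$realizedIdentity))
      }
    }
    list(queries = queries, labels = labels, profiles = profiles,
         truth = truth)
  })
}

#' Read / write fold-group label tables
#'
#' Two-column TSV: `query_id`, `group`.
#'
#' @param labels named character vector (names = query ids).
#' @param path file path.
#' @return `writeLabels`: the path invisibly; `readLabels`: the named vector.
#' @export
writeLabels <- function(labels, path) {
  write.table(data.frame(query_id = names(labels), group = unname(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character")
  stats::setNames(df$group, df$query_id)
}
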