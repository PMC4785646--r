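# Exact placement of small RNA reads on mature tRNAs, fragment typing
# (5'-tRF / 5'-half / i-tRF / 3'-half / 3'-tRF) and genomic ambiguity
# labeling. Matching is exact by design: a single mismatch is enough to
# change which genomic loci a short read can derive from, so approximate
# placements are not offered.

#' Load and dereplicate small RNA reads
#'
#' Reads FASTA or FASTQ (auto-detected from the first record character),
#' merges identical sequences and sums their multiplicities.
#'
#' @param path FASTA or FASTQ file.
#' @return data.frame: `seq`, `count`, `length`, ordered by descending
#'   count then lexicographically by sequence.
#' @export
loadAndDereplicate <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path)
  lines <- readLines(path, n = 50L)
  nonEmpty <- lines[nzchar(trimws(lines))]
  if (length(nonEmpty) == 0L) {
    warning("empty reads file: ", path)
    return(data.frame(seq = character(0), count = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  lead <- substring(nonEmpty[1], 1L, 1L)
  fmt <- switch(lead, ">" = "fasta", "@" = "fastq",
                stop("cannot detect reads dialect (first record starts with '",
                     lead, "', expected '>' or '@')"))
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(x) == 0L) {
    warning("no reads in ", path)
    return(data.frame(seq = character(0), count = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(as.character(x))
  df <- data.frame(seq = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$length <- nchar(df$seq)
  df <- df[order(-df$count, df$seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Partition reads by a minimum-length filter
#'
#' Short reads occur at many genomic locations by chance alone, so reads
#' below the minimum length are excluded from fragment calling and
#' reported separately rather than dropped.
#'
#' @param reads data.frame with columns `seq`, `count`, `length` (as
#'   from [loadAndDereplicate()]).
#' @param minLen minimum read length in nucleotides (default 16).
#' @return list with data.frames `pass` and `tooShort`.
#' @export
lengthFilter <- function(reads, minLen = 16L) {
  minLen <- as.integer(minLen)
  if (length(minLen) != 1L || is.na(minLen) || minLen < 1L)
    stop("minLen must be a single integer >= 1")
  short <- reads$length < minLen
  list(pass = reads[!short, , drop = FALSE],
       tooShort = reads[short, , drop = FALSE])
}

#' Exact placements of one read on the mature tRNAs
#'
#' Finds every exact-substring occurrence of the read on every mature
#' sequence, forward orientation only (mature sequences are already
#' transcript-oriented). Overlapping occurrences are all reported.
#'
#' @param readSeq read sequence (no `N`; reads containing `N` are
#'   unplaceable and should be reported as such by the caller).
#' @param matures a [MatureTRNASet-class] or named sequences.
#' @return data.frame: `trna`, `start`, `end` (1-based inclusive mature
#'   coordinates); zero rows when the read places nowhere.
#' @export
placeOnMatures <- function(readSeq, matures) {
  seqs <- .asMatureSeqs(matures)
  empty <- data.frame(trna = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (grepl("[^ACGT]", readSeq)) return(empty)
  subject <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::vmatchPattern(readSeq, subject)
  cnt <- S4Vectors::elementNROWS(m)
  if (sum(cnt) == 0L) return(empty)
  ids <- rep.int(seq_along(cnt), cnt)
  ir <- unlist(m, use.names = FALSE)
  data.frame(trna = names(seqs)[ids],
             start = IRanges::start(ir), end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

#' Fragment type of a placement
#'
#' Classifies a mature-coordinate placement by its endpoints: fragments
#' starting at mature position 1 are 5' fragments, fragments reaching
#' the final (CCA-inclusive) mature position are 3' fragments, anything
#' else is internal (i-tRF). A 5' (3') fragment whose 3' (5') end falls
#' within `halvesWindow` nucleotides of the anticodon is called a half.
#'
#' @param start,end 1-based inclusive mature coordinates.
#' @param matureLen length of the mature sequence (including CCA).
#' @param acStart 1-based mature position of the first anticodon base.
#' @param halvesWindow half-boundary tolerance around the anticodon in
#'   nucleotides (default 2): the anticodon window is
#'   `[acStart - halvesWindow, acStart + 2 + halvesWindow]`.
#' @param threePrimeSlack how far short of the final mature position a
#'   3' fragment may stop and still be called 3' (default 0: it must
#'   reach the CCA-inclusive end).
#' @return one of `"FIVE_TRF"`, `"FIVE_HALF"`, `"I_TRF"`,
#'   `"THREE_HALF"`, `"THREE_TRF"`.
#' @export
callFragmentType <- function(start, end, matureLen, acStart,
                             halvesWindow = 2L, threePrimeSlack = 0L) {
  stopifnot(start >= 1L, end <= matureLen, start <= end)
  inWindow <- function(p) !is.na(acStart) &&
    p >= acStart - halvesWindow && p <= acStart + 2L + halvesWindow
  if (start == 1L) {
    if (inWindow(end)) "FIVE_HALF" else "FIVE_TRF"
  } else if (end >= matureLen - threePrimeSlack) {
    if (inWindow(start)) "THREE_HALF" else "THREE_TRF"
  } else {
    "I_TRF"
  }
}

#' Genomic-ambiguity label for a read
#'
#' A read is `EXCLUSIVE` when every exact genomic copy of it (on either
#' strand) lies fully inside tRNA space — including the case of zero
#' genomic copies, which arises for reads spanning a splice junction or
#' the non-templated CCA. Any exact copy outside tRNA space makes the
#' read `AMBIGUOUS`. The genome is required: labeling against tRNA
#' space alone is precisely the practice this package exists to avoid.
#'
#' @param readSeq read sequence over `{A,C,G,T}`.
#' @param genome named `DNAStringSet` (mandatory).
#' @param space tRNA-space `GRanges`.
#' @return list with `label` (`"EXCLUSIVE"`/`"AMBIGUOUS"`) and
#'   `outsideCount`.
#' @export
labelAmbiguity <- function(readSeq, genome, space) {
  if (missing(genome) || is.null(genome))
    stop("a genome is required: ambiguity cannot be assessed from tRNA space alone")
  occ <- countSequenceOccurrences(genome, readSeq, space)
  list(label = if (occ[["outside"]] == 0L) "EXCLUSIVE" else "AMBIGUOUS",
       outsideCount = occ[["outside"]])
}

#' Classify a set of small RNA reads against mature tRNAs and the genome
#'
#' End-to-end classifier: length filter, exact placement on mature
#' tRNAs, fragment typing per placement, and a genome-wide ambiguity
#' label per read. Reads placed on more than one mature tRNA keep every
#' placement and are flagged `multi`.
#'
#' @param reads data.frame from [loadAndDereplicate()] (columns `seq`,
#'   `count`, `length`).
#' @param matures a [MatureTRNASet-class] (or the result of
#'   [readMatureFasta()]: a list with `seqs` and `anticodonStart`).
#' @param genome named `DNAStringSet`.
#' @param space tRNA-space `GRanges`.
#' @param minLen minimum read length (default 16).
#' @param halvesWindow anticodon window half-width for half calls
#'   (default 2).
#' @param threePrimeSlack slack for 3' calls (default 0).
#' @return list with `calls` (data.frame: `seq`, `count`, `length`,
#'   `filtered`, `nPlacements`, `trna`, `start`, `end`, `fragmentType`,
#'   `multi`, `ambiguity`, `outsideCount`; one row per placement, one
#'   row for unplaced or filtered reads) and `stats` (named counts).
#' @export
classifyReads <- function(reads, matures, genome, space,
                          minLen = 16L, halvesWindow = 2L,
                          threePrimeSlack = 0L) {
  if (is.list(matures) && !isS4(matures) &&
      all(c("seqs", "anticodonStart") %in% names(matures))) {
    seqs <- matures$seqs
    acStarts <- matures$anticodonStart
  } else {
    seqs <- .asMatureSeqs(matures)
    acStarts <- if (is(matures, "MatureTRNASet")) anticodonStart(matures)
                else stats::setNames(rep(NA_integer_, length(seqs)), names(seqs))
  }
  genome <- .asGenome(genome)
  part <- lengthFilter(reads, minLen)
  matureLens <- nchar(seqs)

  callRow <- function(readRow, filtered, placements = NULL,
                      ambiguity = NA_character_, outsideCount = NA_integer_) {
    if (is.null(placements) || nrow(placements) == 0L) {
      return(data.frame(seq = readRow$seq, count = readRow$count,
                        length = readRow$length, filtered = filtered,
                        nPlacements = 0L, trna = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        fragmentType = NA_character_, multi = FALSE,
                        ambiguity = ambiguity, outsideCount = outsideCount,
                        stringsAsFactors = FALSE))
    }
    nP <- nrow(placements)
    types <- vapply(seq_len(nP), function(j) {
      nm <- placements$trna[j]
      callFragmentType(placements$start[j], placements$end[j],
                       matureLens[[nm]], acStarts[[nm]],
                       halvesWindow, threePrimeSlack)
    }, character(1))
    data.frame(seq = readRow$seq, count = readRow$count,
               length = readRow$length, filtered = filtered,
               nPlacements = nP, trna = placements$trna,
               start = placements$start, end = placements$end,
               fragmentType = types, multi = nP > 1L,
               ambiguity = ambiguity, outsideCount = outsideCount,
               stringsAsFactors = FALSE)
  }

  rows <- vector("list", nrow(part$pass) + nrow(part$tooShort))
  ri <- 0L
  for (i in seq_len(nrow(part$pass))) {
    rd <- part$pass[i, , drop = FALSE]
    if (grepl("[^ACGT]", rd$seq)) {
      ri <- ri + 1L
      rows[[ri]] <- callRow(rd, "PASS")       # unplaceable: contains N
      next
    }
    pl <- placeOnMatures(rd$seq, seqs)
    if (nrow(pl) == 0L) {
      ri <- ri + 1L
      rows[[ri]] <- callRow(rd, "PASS")
      next
    }
    amb <- labelAmbiguity(rd$seq, genome, space)
    ri <- ri + 1L
    rows[[ri]] <- callRow(rd, "PASS", pl, amb$label, amb$outsideCount)
  }
  for (i in seq_len(nrow(part$tooShort))) {
    ri <- ri + 1L
    rows[[ri]] <- callRow(part$tooShort[i, , drop = FALSE], "TOO_SHORT")
  }
  calls <- do.call(rbind, rows[seq_len(ri)])
  if (is.null(calls))
    calls <- callRow(data.frame(seq = character(0), count = integer(0),
                                length = integer(0)), character(0))[0, ]
  rownames(calls) <- NULL
  placedSeqs <- unique(calls$seq[calls$nPlacements > 0L])
  stats <- c(nInput = nrow(reads),
             nPass = nrow(part$pass),
             nTooShort = nrow(part$tooShort),
             nPlaced = length(placedSeqs),
             nUnplaced = nrow(part$pass) - length(placedSeqs),
             nExclusive = length(unique(calls$seq[
               !is.na(calls$ambiguity) & calls$ambiguity == "EXCLUSIVE"])),
             nAmbiguous = length(unique(calls$seq[
               !is.na(calls$ambiguity) & calls$ambiguity == "AMBIGUOUS"])))
  list(calls = calls, stats = stats)
}

#' Per-tRNA fragment profiles
#'
#' One profile per mature tRNA, one row per distinct fragment sequence.
#' Counts are never summed across distinct sequences — two fragments
#' differing by a single nucleotide keep separate rows — and no
#' "dominant" fragment is designated: distinct fragments from the same
#' template have been shown to behave independently, so collapsing them
#' destroys signal. Reads placed on several tRNAs appear in every
#' matching profile, flagged `multi`.
#'
#' @param calls calls data.frame from [classifyReads()].
#' @return named list of data.frames (`fragmentSeq`, `start`, `end`,
#'   `fragmentType`, `count`, `ambiguity`, `outsideCount`, `multi`),
#'   rows sorted by mature start then descending count.
#' @export
buildProfiles <- function(calls) {
  placed <- calls[!is.na(calls$trna) & calls$filtered == "PASS", , drop = FALSE]
  if (nrow(placed) == 0L) return(stats::setNames(list(), character(0)))
  out <- lapply(split(placed, placed$trna), function(df) {
    p <- data.frame(fragmentSeq = df$seq, start = df$start, end = df$end,
                    fragmentType = df$fragmentType, count = df$count,
                    ambiguity = df$ambiguity,
                    outsideCount = df$outsideCount,
                    multi = df$multi, stringsAsFactors = FALSE)
    p <- p[order(p$start, -p$count, p$fragmentSeq), , drop = FALSE]
    rownames(p) <- NULL
    p
  })
  out[order(names(out))]
}

#' Write classifier calls as a provenance-stamped TSV
#'
#' @param calls calls data.frame from [classifyReads()].
#' @param path output TSV.
#' @param provenance extra header lines (each prefixed with `#`).
#' @return `path`, invisibly.
#' @export
writeCallsTsv <- function(calls, path, provenance = character()) {
  .writeProvenancedTsv(calls, path, provenance)
}

#' Write per-tRNA fragment profiles as TSVs
#'
#' @param profiles list from [buildProfiles()].
#' @param dir output directory (created if absent); one
#'   `profile_<tRNA>.tsv` per tRNA.
#' @param provenance extra header lines.
#' @return character vector of written paths, invisibly.
#' @export
writeProfiles <- function(profiles, dir, provenance = character()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(profiles), function(nm) {
    p <- file.path(dir, paste0("profile_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv"))
    .writeProvenancedTsv(profiles[[nm]], p, c(paste0("tRNA: ", nm), provenance))
    p
  }, character(1))
  invisible(paths)
}
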