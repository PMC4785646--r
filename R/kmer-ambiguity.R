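# Exact k-mer exclusivity profiling: which k-mers of the mature tRNA
# transcriptome occur, as exact copies, only inside tRNA space and which
# also occur elsewhere on the genome. Occurrences are counted on both
# strands (a window matches a k-mer when it equals the k-mer or its
# reverse complement) and an occurrence is "inside" only when its
# interval is fully contained in tRNA space.

#' Enumerate the distinct k-mers of a set of mature tRNAs
#'
#' Takes every length-`k` window of every mature sequence — including
#' windows that span a splice junction or run into the non-templated
#' CCA — deduplicates them, and records every source window. Windows
#' containing `N` are excluded (matching is exact over `{A,C,G,T}`).
#'
#' @param matures a [MatureTRNASet-class], named `DNAStringSet`, or
#'   named character vector of mature sequences.
#' @param k k-mer length (>= 1).
#' @return an [ExclusivityTable-class] with zeroed counts and filled
#'   sources.
#' @export
enumerateMatureKmers <- function(matures, k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be a single integer >= 1")
  seqs <- .asMatureSeqs(matures)
  if (length(seqs) == 0L) stop("matures must be non-empty")
  src <- lapply(names(seqs), function(nm) {
    w <- .kmerWindows(seqs[[nm]], k)
    if (length(w) == 0L) return(NULL)
    keep <- !grepl("[^ACGT]", w)
    if (!any(keep)) return(NULL)
    data.frame(kmer = w[keep], trna = nm, start = which(keep),
               stringsAsFactors = FALSE)
  })
  sources <- do.call(rbind, src)
  if (is.null(sources) || nrow(sources) == 0L) {
    warning("k = ", k, " exceeds every mature sequence length; empty table")
    sources <- data.frame(kmer = character(0), trna = character(0),
                          start = integer(0), stringsAsFactors = FALSE)
    return(new("ExclusivityTable", k = k, kmers = character(0),
               inside = integer(0), outside = integer(0),
               nSources = integer(0), sources = sources, scanned = FALSE))
  }
  uk <- sort(unique(sources$kmer))
  nSrc <- as.integer(table(factor(sources$kmer, levels = uk)))
  new("ExclusivityTable", k = k, kmers = uk,
      inside = integer(length(uk)), outside = integer(length(uk)),
      nSources = nSrc, sources = sources, scanned = FALSE)
}

# Scan one ExclusivityTable against the genome; returns the table with
# counts filled. Matching uses Biostrings preprocessed dictionaries
# (Aho-Corasick style multi-pattern search).
.scanOneTable <- function(genome, table, space) {
  keys <- table@kmers
  if (length(keys) == 0L) return(table)
  keySet <- Biostrings::DNAStringSet(keys)
  rcSet <- Biostrings::reverseComplement(keySet)
  palindromic <- as.character(rcSet) == keys
  pdF <- Biostrings::PDict(keySet)
  pdR <- Biostrings::PDict(rcSet)
  inside <- integer(length(keys))
  outside <- integer(length(keys))
  spaceDf <- .spaceToDf(space)
  for (chrom in names(genome)) {
    chr <- genome[[chrom]]
    if (length(chr) < table@k) next
    collect <- function(mindex, drop = logical(length(keys))) {
      cnt <- S4Vectors::elementNROWS(mindex)
      ids <- rep.int(seq_along(cnt), cnt)
      ir <- unlist(mindex, use.names = FALSE)
      if (any(drop)) {
        keep <- !drop[ids]
        ids <- ids[keep]
        ir <- ir[keep]
      }
      list(ids = ids, ir = ir)
    }
    fwd <- collect(Biostrings::matchPDict(pdF, chr))
    # reverse-complement hits: drop palindromic keys (their rc matches
    # coincide with the forward matches and must count once)
    rev <- collect(Biostrings::matchPDict(pdR, chr), drop = palindromic)
    ids <- c(fwd$ids, rev$ids)
    if (length(ids) == 0L) next
    ir <- c(fwd$ir, rev$ir)
    sp <- spaceDf[spaceDf$chrom == chrom, , drop = FALSE]
    isInside <- if (nrow(sp)) {
      IRanges::overlapsAny(ir, IRanges::IRanges(sp$start, sp$end),
                           type = "within")
    } else rep(FALSE, length(ids))
    inside <- inside + tabulate(ids[isInside], nbins = length(keys))
    outside <- outside + tabulate(ids[!isInside], nbins = length(keys))
  }
  table@inside <- inside
  table@outside <- outside
  table@scanned <- TRUE
  table
}

#' Count exact genomic occurrences of mature-tRNA k-mers
#'
#' Scans every chromosome for exact occurrences of the table's k-mers,
#' on both strands, and classifies each occurrence as inside tRNA space
#' (interval fully contained) or outside. A palindromic k-mer matching
#' one genomic window both forward and as its own reverse complement
#' counts once.
#'
#' @param genome named `DNAStringSet`.
#' @param tables one [ExclusivityTable-class] or a list of them (e.g.
#'   one per k).
#' @param space tRNA-space `GRanges` from [buildTrnaSpace()]; may be
#'   empty (`NULL` or zero-length), in which case every occurrence is
#'   outside.
#' @return the table(s) with `inside`/`outside` counts filled, in the
#'   same shape as `tables` was given.
#' @export
scanGenome <- function(genome, tables, space = NULL) {
  genome <- .asGenome(genome)
  single <- is(tables, "ExclusivityTable")
  if (single) tables <- list(tables)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    warning("empty genome; all counts remain zero")
  out <- lapply(tables, function(tb) {
    stopifnot(is(tb, "ExclusivityTable"))
    .scanOneTable(genome, tb, space)
  })
  if (single) out[[1]] else out
}

#' Summarize an exclusivity table
#'
#' Counts k-mers whose exact genomic occurrences are confined to tRNA
#' space (`outside == 0`; this includes k-mers with no genomic
#' occurrence at all, such as junction- or CCA-spanning k-mers) versus
#' k-mers that also occur outside. Percentages are rounded half-up to
#' one decimal.
#'
#' @param table a scanned [ExclusivityTable-class].
#' @return one-row data.frame: `k`, `nDistinct`, `nExclusive`,
#'   `nNonexclusive`, `pctExclusive`, `pctNonexclusive`.
#' @export
summarizeAmbiguity <- function(table) {
  stopifnot(is(table, "ExclusivityTable"))
  n <- length(table@kmers)
  if (n == 0L) stop("cannot summarize an empty exclusivity table")
  nEx <- sum(table@outside == 0L)
  nNon <- n - nEx
  data.frame(k = table@k, nDistinct = n, nExclusive = nEx,
             nNonexclusive = nNon,
             pctExclusive = .roundHalfUp(100 * nEx / n, 1L),
             pctNonexclusive = .roundHalfUp(100 * nNon / n, 1L))
}

#' Count exact genomic occurrences of one query sequence
#'
#' Both-strand, containment-classified counting for a single
#' arbitrary-length query: a genomic window counts when it equals the
#' query or its reverse complement, and is "inside" only when fully
#' contained in tRNA space.
#'
#' @param genome named `DNAStringSet`.
#' @param query DNA string over `{A,C,G,T}`.
#' @param space tRNA-space `GRanges` (may be `NULL`/empty).
#' @return named integer vector `c(inside = , outside = )`.
#' @export
countSequenceOccurrences <- function(genome, query, space = NULL) {
  genome <- .asGenome(genome)
  query <- toupper(as.character(query))
  if (nchar(query) < 1L) stop("query must be non-empty")
  if (grepl("[^ACGT]", query))
    stop("query must be over the alphabet {A,C,G,T}")
  q <- Biostrings::DNAString(query)
  rcq <- Biostrings::reverseComplement(q)
  palindromic <- as.character(rcq) == query
  spaceDf <- .spaceToDf(space)
  inside <- 0L; outside <- 0L
  for (chrom in names(genome)) {
    chr <- genome[[chrom]]
    if (length(chr) < nchar(query)) next
    ir <- IRanges::ranges(Biostrings::matchPattern(q, chr))
    if (!palindromic)
      ir <- c(ir, IRanges::ranges(Biostrings::matchPattern(rcq, chr)))
    if (length(ir) == 0L) next
    sp <- spaceDf[spaceDf$chrom == chrom, , drop = FALSE]
    isInside <- if (nrow(sp)) {
      IRanges::overlapsAny(ir, IRanges::IRanges(sp$start, sp$end),
                           type = "within")
    } else rep(FALSE, length(ir))
    inside <- inside + sum(isInside)
    outside <- outside + sum(!isInside)
  }
  c(inside = inside, outside = outside)
}

#' Genomic copies of the CCA-ending terminal k-mers of mature tRNAs
#'
#' For each mature tRNA, takes its 3'-terminal k-mer (which ends in the
#' non-templated CCA) and counts its exact copies outside tRNA space.
#' The grand total sums over tRNAs, not over distinct k-mers: two tRNAs
#' sharing a terminal k-mer each contribute its outside count.
#'
#' @param matures a [MatureTRNASet-class] or named sequences.
#' @param genome named `DNAStringSet`.
#' @param space tRNA-space `GRanges`.
#' @param k terminal k-mer length (default 16).
#' @return list with `nTrnasWithOutsideCopies`, `grandTotalOutside` and
#'   `perTrna` (data.frame: `trna`, `kmer`, `outside`).
#' @export
ccaTerminalReport <- function(matures, genome, space, k = 16L) {
  k <- as.integer(k)
  seqs <- .asMatureSeqs(matures)
  genome <- .asGenome(genome)
  rows <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    L <- nchar(s)
    if (L < k) {
      warning("mature tRNA ", nm, " shorter than k = ", k, "; skipped")
      return(NULL)
    }
    term <- substring(s, L - k + 1L, L)
    if (grepl("[^ACGT]", term)) {
      warning("terminal k-mer of ", nm, " contains N; skipped")
      return(NULL)
    }
    occ <- countSequenceOccurrences(genome, term, space)
    data.frame(trna = nm, kmer = term, outside = unname(occ["outside"]),
               stringsAsFactors = FALSE)
  })
  perTrna <- do.call(rbind, rows)
  if (is.null(perTrna))
    perTrna <- data.frame(trna = character(0), kmer = character(0),
                          outside = integer(0), stringsAsFactors = FALSE)
  list(nTrnasWithOutsideCopies = sum(perTrna$outside >= 1L),
       grandTotalOutside = sum(perTrna$outside),
       perTrna = perTrna)
}

# Canonical form: the lexicographic minimum of a k-mer and its reverse
# complement, so that a k-mer and its reverse complement count once.
.canonicalKmers <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  pmin(kmers, .revcomp(kmers))
}

#' Exact k-mer cross-talk between mature tRNAs and a foreign sequence set
#'
#' Counts the distinct k-mers shared between the mature tRNA set and a
#' foreign set of sequences (typically tRNA-lookalike loci), where
#' sharing counts matches in forward orientation or as reverse
#' complement, and a k-mer and its reverse complement are one k-mer.
#'
#' @param matures a [MatureTRNASet-class] or named sequences.
#' @param foreignSeqs named character vector (or `DNAStringSet`) of
#'   foreign sequences; must be non-empty.
#' @param k k-mer length (default 16).
#' @return list with `nTrnasSharing`, `nSharedKmers` and `perTrna`
#'   (named integer vector of shared-k-mer counts per mature tRNA).
#' @export
crosstalkReport <- function(matures, foreignSeqs, k = 16L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be >= 1")
  seqs <- .asMatureSeqs(matures)
  if (is(foreignSeqs, "DNAStringSet")) foreignSeqs <- as.character(foreignSeqs)
  if (length(foreignSeqs) == 0L) stop("foreign sequence set must be non-empty")
  foreignKmers <- unique(.canonicalKmers(unlist(lapply(foreignSeqs, function(s) {
    w <- .kmerWindows(toupper(s), k)
    w[!grepl("[^ACGT]", w)]
  }), use.names = FALSE)))
  perTrna <- vapply(seqs, function(s) {
    w <- .kmerWindows(s, k)
    w <- unique(.canonicalKmers(w[!grepl("[^ACGT]", w)]))
    sum(w %in% foreignKmers)
  }, integer(1))
  sharedAll <- unique(unlist(lapply(seqs, function(s) {
    w <- .kmerWindows(s, k)
    w <- unique(.canonicalKmers(w[!grepl("[^ACGT]", w)]))
    w[w %in% foreignKmers]
  }), use.names = FALSE))
  list(nTrnasSharing = sum(perTrna >= 1L),
       nSharedKmers = length(sharedAll),
       perTrna = perTrna)
}

#' Read a RepeatMasker `.out` annotation file
#'
#' Parses the standard whitespace-delimited RepeatMasker output (header
#' lines skipped). Coordinates are 1-based inclusive as printed by
#' RepeatMasker; the class/family column is split on `/` and the part
#' before the slash retained as the repeat class.
#'
#' @param path path to a `.out` file.
#' @return data.frame: `chrom`, `start`, `end`, `strand`, `repeatName`,
#'   `repeatClass`, `length`.
#' @export
readRepeatMaskerOut <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker file not found: ", path)
  lines <- readLines(path)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1]]
    # header lines start with column labels, not a numeric SW score
    if (is.na(suppressWarnings(as.numeric(tok[1])))) next
    if (length(tok) < 11L)
      stop("malformed RepeatMasker line ", i, ": expected >= 11 fields")
    start <- suppressWarnings(as.integer(tok[6]))
    end <- suppressWarnings(as.integer(tok[7]))
    if (is.na(start) || is.na(end) || start > end)
      stop("malformed RepeatMasker line ", i, ": bad coordinates")
    rows[[i]] <- data.frame(
      chrom = tok[5], start = start, end = end,
      strand = if (tok[9] %in% c("C", "-")) "-" else "+",
      repeatName = tok[10],
      repeatClass = sub("/.*$", "", tok[11]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      repeatName = character(0), repeatClass = character(0),
                      stringsAsFactors = FALSE)
  out$length <- out$end - out$start + 1L
  out
}

#' Short tRNA-class repeat segments outside tRNA space
#'
#' Filters RepeatMasker features to those of class `"tRNA"` with length
#' at most `maxLen` whose interval is not fully contained in tRNA space
#' — the short, incomplete tRNA copies that make reads of ambiguous
#' genomic origin look tRNA-derived.
#'
#' @param features data.frame from [readRepeatMaskerOut()].
#' @param space tRNA-space `GRanges`.
#' @param maxLen maximum segment length in nucleotides (default 50).
#' @param bedPath optional path; survivors written as BED3 when given.
#' @return list with `count` and `features` (the surviving rows).
#' @export
filterShortTrnaRepeats <- function(features, space, maxLen = 50L, bedPath = NULL) {
  keep <- features$repeatClass == "tRNA" & features$length <= maxLen
  feat <- features[keep, , drop = FALSE]
  if (nrow(feat)) {
    gr <- GenomicRanges::GRanges(feat$chrom,
                                 IRanges::IRanges(feat$start, feat$end))
    containedInSpace <- if (!is.null(space) && length(space)) {
      IRanges::overlapsAny(gr, space, type = "within", ignore.strand = TRUE)
    } else rep(FALSE, length(gr))
    feat <- feat[!containedInSpace, , drop = FALSE]
  }
  if (!is.null(bedPath)) {
    if (nrow(feat)) {
      writeBed3(GenomicRanges::GRanges(feat$chrom,
                                       IRanges::IRanges(feat$start, feat$end)),
                bedPath)
    } else {
      writeLines(character(0), bedPath)
    }
  }
  list(count = nrow(feat), features = feat)
}
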