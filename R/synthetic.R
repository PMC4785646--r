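# Synthetic genomes with planted tRNA genes and decoy features, plus the
# naive brute-force scan every exact-matching operation is tested
# against. The generator emulates the four mechanisms that make
# candidate tRFs genomically ambiguous: truncated tRNA copies outside
# tRNA space, intron-containing genes whose mature sequence crosses an
# exon-exon junction, CCA-ending decoy sites, and tRNA-lookalike loci.

#' Specification of a synthetic genome fixture
#'
#' Defaults describe the package's reference study conditions: a 100 kb
#' genome at human-like GC content carrying 6 tRNA genes (2 of them
#' intron-containing), 10 truncated partial copies, 3 mutated
#' lookalikes and 3 verbatim CCA-ending decoy sites.
#'
#' @param genomeLength genome length in nucleotides.
#' @param nTrnas number of planted tRNA genes (72 nt mature body).
#' @param nIntronicTrnas how many of those carry a 10-20 nt intron.
#' @param nPartialCopies truncated tRNA segments planted outside tRNA
#'   space (lengths 20 to `maxPartialLen`).
#' @param maxPartialLen maximum partial-copy length (default 50 nt).
#' @param nLookalikes tRNA-body copies with 2-10 point substitutions.
#' @param nCcaDecoys verbatim copies of a tRNA's CCA-ending terminal
#'   16-mer planted outside tRNA space.
#' @param gcContent background GC fraction (default 0.41, human-like).
#' @param seed RNG seed making the fixture deterministic.
#' @return a validated list of class `syntheticGenomeSpec`.
#' @export
syntheticGenomeSpec <- function(genomeLength = 100000L, nTrnas = 6L,
                                nIntronicTrnas = 2L, nPartialCopies = 10L,
                                maxPartialLen = 50L, nLookalikes = 3L,
                                nCcaDecoys = 3L, gcContent = 0.41,
                                seed = 42L) {
  spec <- list(genomeLength = as.integer(genomeLength),
               nTrnas = as.integer(nTrnas),
               nIntronicTrnas = as.integer(nIntronicTrnas),
               nPartialCopies = as.integer(nPartialCopies),
               maxPartialLen = as.integer(maxPartialLen),
               nLookalikes = as.integer(nLookalikes),
               nCcaDecoys = as.integer(nCcaDecoys),
               gcContent = as.numeric(gcContent),
               seed = as.integer(seed))
  stopifnot(spec$genomeLength > 0L, spec$nTrnas >= 0L,
            spec$nIntronicTrnas >= 0L, spec$nIntronicTrnas <= spec$nTrnas,
            spec$nPartialCopies >= 0L, spec$nLookalikes >= 0L,
            spec$nCcaDecoys >= 0L,
            spec$gcContent > 0, spec$gcContent < 1)
  if ((spec$nPartialCopies + spec$nLookalikes + spec$nCcaDecoys) > 0L &&
      spec$nTrnas == 0L)
    stop("decoy features need at least one source tRNA")
  class(spec) <- c("syntheticGenomeSpec", "list")
  spec
}

.randSeq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Pure base-R reverse complement (kept independent of Biostrings so the
# oracle path shares no code with the scanning implementation).
.revcompBase <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic genome with planted tRNA and decoy features
#'
#' Builds an i.i.d. background genome and plants, without overlap:
#' tRNA genes (on random strands; intronic ones carry the intron
#' immediately 3' of the anticodon), truncated partial copies of those
#' genes, lookalikes (tRNA bodies with 2-10 substitutions) and verbatim
#' CCA-ending decoy 16-mers. All decoy features are planted in mature
#' orientation on the forward strand. The emitted annotation, lookalike
#' BED, RepeatMasker-style `.out` (listing the partial copies with
#' class `tRNA`) and ground truth are deterministic for a given seed.
#' Planted sequences are verified against the assembled genome before
#' returning.
#'
#' @param spec a [syntheticGenomeSpec()].
#' @param outDir optional directory; when given, `genome.fa`,
#'   `trna_annotation.bed`, `lookalikes.bed`, `repeatmasker.out` and
#'   `truth_features.tsv` are written there.
#' @return list with `genome` (`DNAStringSet`), `truth`
#'   ([SyntheticTruth-class]), `trnas` (data.frame of planted gene
#'   details incl. mature sequences), `annotationLines`,
#'   `lookalikeLines`, `rmOutLines`, and `files` (named paths or
#'   `NULL`).
#' @export
generateGenome <- function(spec, outDir = NULL) {
  stopifnot(inherits(spec, "syntheticGenomeSpec"))
  .withSeed(spec$seed, {
    chrom <- "chrS"
    bg <- strsplit(.randSeq(spec$genomeLength, spec$gcContent), "")[[1]]

    occupied <- IRanges::IRanges()
    margin <- 5L
    place <- function(len) {
      for (try in seq_len(2000L)) {
        s <- sample.int(spec$genomeLength - len + 1L, 1L)
        cand <- IRanges::IRanges(max(1L, s - margin),
                                 min(spec$genomeLength, s + len - 1L + margin))
        if (length(occupied) == 0L ||
            !any(IRanges::overlapsAny(cand, occupied))) {
          occupied <<- c(occupied, cand)
          return(s)
        }
      }
      stop("could not place a ", len,
           "-nt feature without overlap; increase genomeLength")
    }
    plant <- function(start, seq) {
      chars <- strsplit(seq, "")[[1]]
      bg[start:(start + length(chars) - 1L)] <<- chars
    }

    feats <- list()
    addFeat <- function(id, kind, start, end, strand, source, seq) {
      feats[[length(feats) + 1L]] <<- data.frame(
        id = id, kind = kind, chrom = chrom, start = start, end = end,
        strand = strand, source = source, seq = seq,
        stringsAsFactors = FALSE)
    }

    # --- tRNA genes -----------------------------------------------------
    bodyLen <- 72L
    trnaRows <- list()
    annotationLines <- character(0)
    for (i in seq_len(spec$nTrnas)) {
      id <- sprintf("tRNA-SYN%02d", i)
      body <- .randSeq(bodyLen, spec$gcContent)
      intronic <- i <= spec$nIntronicTrnas
      intronLen <- if (intronic) sample(10:20, 1L) else 0L
      intron <- if (intronic) .randSeq(intronLen, spec$gcContent) else ""
      # intron sits immediately 3' of mature position 37 (just past the
      # anticodon at mature positions 34-36)
      gene <- if (intronic)
        paste0(substring(body, 1L, 37L), intron, substring(body, 38L, bodyLen))
      else body
      geneLen <- nchar(gene)
      strand <- sample(c("+", "-"), 1L)
      genomicSeq <- if (strand == "-") .revcompBase(gene) else gene
      s <- place(geneLen)
      plant(s, genomicSeq)
      e <- s + geneLen - 1L
      addFeat(id, "TRNA", s, e, strand, NA_character_, genomicSeq)

      s0 <- s - 1L                                  # 0-based BED start
      ac0 <- if (strand == "+") s0 + 33L else s0 + geneLen - 36L
      if (intronic) {
        sizes <- if (strand == "+") c(37L, 35L) else c(35L, 37L)
        offs <- c(0L, sizes[1] + intronLen)
      } else {
        sizes <- geneLen
        offs <- 0L
      }
      annotationLines <- c(annotationLines, paste(
        chrom, s0, s0 + geneLen, id, 0L, strand, s0, s0 + geneLen, "0",
        length(sizes),
        paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(offs, collapse = ","), ","),
        "Xxx", "NNN", ac0, sep = "\t"))
      trnaRows[[i]] <- data.frame(
        id = id, strand = strand, start = s, end = e,
        body = body, geneSeq = gene, intronLen = intronLen,
        matureSeq = paste0(body, "CCA"),
        anticodonMatureStart = 34L,
        stringsAsFactors = FALSE)
    }
    trnas <- if (length(trnaRows)) do.call(rbind, trnaRows) else
      data.frame(id = character(0), strand = character(0),
                 start = integer(0), end = integer(0), body = character(0),
                 geneSeq = character(0), intronLen = integer(0),
                 matureSeq = character(0),
                 anticodonMatureStart = integer(0), stringsAsFactors = FALSE)

    # --- partial (truncated) copies, outside tRNA space -----------------
    rmOutLines <- c(
      "   SW  perc perc perc  query     position in query     matching  repeat        position in repeat",
      "score  div. del. ins.  sequence  begin  end   (left)   repeat    class/family  begin  end (left)  ID",
      "")
    for (i in seq_len(spec$nPartialCopies)) {
      src <- trnas[sample.int(nrow(trnas), 1L), ]
      len <- sample(20:spec$maxPartialLen, 1L)
      # truncate the genomic gene sequence (transcript orientation,
      # introns included): junction-spanning mature sequence never gains
      # an outside copy this way, matching genuine truncated gene relics
      off <- sample.int(nchar(src$geneSeq) - len + 1L, 1L)
      seg <- substring(src$geneSeq, off, off + len - 1L)
      s <- place(len)
      plant(s, seg)
      id <- sprintf("partial%02d", i)
      addFeat(id, "PARTIAL", s, s + len - 1L, "+", src$id, seg)
      rmOutLines <- c(rmOutLines, sprintf(
        "  463  10.1  0.0  0.0  %s  %d  %d  (%d)  +  %s  tRNA  1  %d  (0)  %d",
        chrom, s, s + len - 1L, spec$genomeLength - (s + len - 1L),
        src$id, len, i))
    }

    # --- tRNA-lookalikes (mutated bodies) -------------------------------
    lookalikeLines <- character(0)
    for (i in seq_len(spec$nLookalikes)) {
      src <- trnas[sample.int(nrow(trnas), 1L), ]
      chars <- strsplit(src$body, "")[[1]]
      nMut <- sample(2:10, 1L)
      pos <- sample.int(bodyLen, nMut)
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      seq <- paste(chars, collapse = "")
      s <- place(bodyLen)
      plant(s, seq)
      id <- sprintf("lookalike%02d", i)
      addFeat(id, "LOOKALIKE", s, s + bodyLen - 1L, "+", src$id, seq)
      lookalikeLines <- c(lookalikeLines,
                          paste(chrom, s - 1L, s + bodyLen - 1L, id,
                                sep = "\t"))
    }

    # --- CCA-ending decoy sites -----------------------------------------
    for (i in seq_len(spec$nCcaDecoys)) {
      src <- trnas[sample.int(nrow(trnas), 1L), ]
      term <- substring(src$matureSeq, nchar(src$matureSeq) - 15L)
      s <- place(16L)
      plant(s, term)
      id <- sprintf("ccadecoy%02d", i)
      addFeat(id, "CCA_DECOY", s, s + 15L, "+", src$id, term)
    }

    genomeStr <- paste(bg, collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(genomeStr, chrom))
    features <- if (length(feats)) do.call(rbind, feats) else
      data.frame(id = character(0), kind = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 source = character(0), seq = character(0),
                 stringsAsFactors = FALSE)

    # self-check: every planted sequence must be recoverable from the
    # assembled genome at its recorded interval
    for (i in seq_len(nrow(features))) {
      got <- substring(genomeStr, features$start[i], features$end[i])
      if (!identical(got, features$seq[i]))
        stop("internal error: planted feature ", features$id[i],
             " does not match the assembled genome")
    }

    truth <- new("SyntheticTruth", features = features,
                 reads = data.frame(), spec = unclass(spec))
    files <- NULL
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      files <- c(genome = file.path(outDir, "genome.fa"),
                 annotation = file.path(outDir, "trna_annotation.bed"),
                 lookalikes = file.path(outDir, "lookalikes.bed"),
                 lookalikeFasta = file.path(outDir, "lookalikes.fa"),
                 rmOut = file.path(outDir, "repeatmasker.out"),
                 truth = file.path(outDir, "truth_features.tsv"))
      Biostrings::writeXStringSet(genome, files[["genome"]])
      writeLines(annotationLines, files[["annotation"]])
      writeLines(lookalikeLines, files[["lookalikes"]])
      la <- features[features$kind == "LOOKALIKE", , drop = FALSE]
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(stats::setNames(la$seq, la$id)),
        files[["lookalikeFasta"]])
      writeLines(rmOutLines, files[["rmOut"]])
      utils::write.table(features, files[["truth"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(genome = genome, truth = truth, trnas = trnas,
         annotationLines = annotationLines,
         lookalikeLines = lookalikeLines,
         rmOutLines = rmOutLines, files = files)
  })
}

#' Simulate small RNA reads with ground-truth ambiguity labels
#'
#' Samples reads from the mature tRNAs (windows may span the exon-exon
#' junction and the non-templated CCA) and from the planted decoy
#' features. Each read's expected ambiguity is recomputed from the full
#' genome by the naive brute-force scan at generation time — never
#' assumed from the construction — so the truth holds even if an
#' accidental background copy of a read exists.
#'
#' @param gen result of [generateGenome()].
#' @param nReads number of reads to draw.
#' @param lengthRange integer pair, read length range (default 16-30).
#' @param seed RNG seed.
#' @param kindWeights sampling weights for origin kinds
#'   (`TRNA`, `PARTIAL`, `LOOKALIKE`, `CCA_DECOY`).
#' @return list with `reads` (data.frame: `id`, `seq`, `count`,
#'   `origin`, `kind`, `expectedOutside`, `expectedAmbiguity`,
#'   `expectedType`) and `truth` (the updated [SyntheticTruth-class]).
#' @export
generateReads <- function(gen, nReads = 1000L, lengthRange = c(16L, 30L),
                          seed = 1L,
                          kindWeights = c(TRNA = 0.6, PARTIAL = 0.2,
                                          LOOKALIKE = 0.1, CCA_DECOY = 0.1)) {
  stopifnot(nReads >= 0L, length(lengthRange) == 2L,
            lengthRange[1] >= 1L, lengthRange[1] <= lengthRange[2])
  trnas <- gen$trnas
  feats <- truthFeatures(gen$truth)
  if (nrow(trnas) == 0L) stop("fixture has no tRNAs to read from")
  matureLens <- nchar(trnas$matureSeq)
  if (lengthRange[1] > min(matureLens))
    stop("minimum read length exceeds the shortest mature tRNA length")
  space <- GenomicRanges::reduce(GenomicRanges::GRanges(
    feats$chrom[feats$kind == "TRNA"],
    IRanges::IRanges(feats$start[feats$kind == "TRNA"],
                     feats$end[feats$kind == "TRNA"])))
  cache <- new.env(parent = emptyenv())
  genomeChar <- stats::setNames(as.character(gen$genome), names(gen$genome))

  decoyKinds <- intersect(names(kindWeights),
                          unique(feats$kind[feats$kind != "TRNA"]))
  kinds <- c("TRNA", decoyKinds)
  w <- kindWeights[kinds]
  # fragment typing convention re-derived inline (independent of the
  # classifier): defaults halvesWindow = 2, threePrimeSlack = 0
  typeOf <- function(start, end, L, ac) {
    inWin <- end >= ac - 2L & end <= ac + 4L
    inWinS <- start >= ac - 2L & start <= ac + 4L
    if (start == 1L) { if (inWin) "FIVE_HALF" else "FIVE_TRF" }
    else if (end == L) { if (inWinS) "THREE_HALF" else "THREE_TRF" }
    else "I_TRF"
  }

  rows <- .withSeed(seed, {
    lapply(seq_len(nReads), function(i) {
      kind <- sample(kinds, 1L, prob = w)
      len <- sample(lengthRange[1]:lengthRange[2], 1L)
      if (kind == "TRNA") {
        j <- sample.int(nrow(trnas), 1L)
        L <- matureLens[j]
        len <- min(len, L)
        s <- sample.int(L - len + 1L, 1L)
        seq <- substring(trnas$matureSeq[j], s, s + len - 1L)
        origin <- trnas$id[j]
        expType <- typeOf(s, s + len - 1L, L,
                          trnas$anticodonMatureStart[j])
      } else {
        cand <- feats[feats$kind == kind, , drop = FALSE]
        j <- sample.int(nrow(cand), 1L)
        flen <- cand$end[j] - cand$start[j] + 1L
        len <- min(len, flen)
        if (len < lengthRange[1]) len <- flen   # short decoys read whole
        off <- sample.int(flen - len + 1L, 1L)
        seq <- substring(cand$seq[j], off, off + len - 1L)
        origin <- cand$id[j]
        expType <- NA_character_
      }
      occ <- bruteForceCounts(genomeChar, seq, space, cache = cache)
      data.frame(id = sprintf("read%05d", i), seq = seq,
                 count = sample(1:5, 1L), origin = origin, kind = kind,
                 expectedOutside = unname(occ["outside"]),
                 expectedAmbiguity = if (occ[["outside"]] == 0L)
                   "EXCLUSIVE" else "AMBIGUOUS",
                 expectedType = expType, stringsAsFactors = FALSE)
    })
  })
  reads <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), seq = character(0), count = integer(0),
               origin = character(0), kind = character(0),
               expectedOutside = integer(0), expectedAmbiguity = character(0),
               expectedType = character(0), stringsAsFactors = FALSE)
  truth <- gen$truth
  truth@reads <- reads
  list(reads = reads, truth = truth)
}

#' Write simulated reads as FASTQ
#'
#' Each read is emitted `count` times so that dereplication recovers the
#' multiplicities.
#'
#' @param reads reads data.frame from [generateReads()].
#' @param path output FASTQ.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    for (r in seq_len(reads$count[i])) {
      writeLines(c(paste0("@", reads$id[i], ".", r),
                   reads$seq[i], "+",
                   strrep("I", nchar(reads$seq[i]))), con)
    }
  }
  invisible(path)
}

# Genome windows of width k per chromosome, optionally memoised.
.genomeWindows <- function(genomeChar, chrom, k, cache = NULL) {
  key <- paste0(chrom, ".", k)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  s <- genomeChar[[chrom]]
  n <- nchar(s) - k + 1L
  w <- if (n >= 1L) substring(s, seq_len(n), seq_len(n) + k - 1L) else character(0)
  if (!is.null(cache)) cache[[key]] <- w
  w
}

#' Naive brute-force exact occurrence scan (reference oracle)
#'
#' Pure base-R reference implementation: slides a window over every
#' chromosome and compares it character-for-character to the query and
#' its reverse complement. A palindromic query matching one window both
#' ways is recorded once (as a forward hit). Other exact-matching
#' operations in the package are tested against this function; it
#' deliberately shares no code with them.
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @param query non-empty DNA string.
#' @param cache optional environment memoising genome windows across
#'   calls (see [makeWindowCache()]).
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`.
#' @export
bruteForceOccurrences <- function(genome, query, cache = NULL) {
  if (is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  stopifnot(is.character(genome), !is.null(names(genome)))
  query <- toupper(query)
  k <- nchar(query)
  if (k < 1L) stop("query must be non-empty")
  rcq <- .revcompBase(query)
  out <- list()
  for (chrom in names(genome)) {
    w <- .genomeWindows(genome, chrom, k, cache)
    if (length(w) == 0L) next
    fw <- which(w == query)
    rv <- if (rcq != query) which(w == rcq) else integer(0)
    if (length(fw))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = fw, end = fw + k - 1L, strand = "+",
        stringsAsFactors = FALSE)
    if (length(rv))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = rv, end = rv + k - 1L, strand = "-",
        stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Brute-force inside/outside occurrence counts
#'
#' Classifies the occurrences found by [bruteForceOccurrences()] against
#' an interval set using plain arithmetic (an occurrence is inside only
#' when fully contained in one interval).
#'
#' @inheritParams bruteForceOccurrences
#' @param space tRNA-space `GRanges` or a data.frame with `chrom`,
#'   `start`, `end` (1-based inclusive); may be `NULL`.
#' @return named integer vector `c(inside = , outside = )`.
#' @export
bruteForceCounts <- function(genome, query, space = NULL, cache = NULL) {
  occ <- bruteForceOccurrences(genome, query, cache = cache)
  sp <- if (is.null(space)) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  } else if (is.data.frame(space)) space else .spaceToDf(space)
  inside <- 0L
  for (i in seq_len(nrow(occ))) {
    contained <- any(sp$chrom == occ$chrom[i] &
                     sp$start <= occ$start[i] &
                     sp$end >= occ$end[i])
    if (contained) inside <- inside + 1L
  }
  c(inside = inside, outside = nrow(occ) - inside)
}

#' Window cache for repeated brute-force scans of one genome
#'
#' @return an environment to pass as `cache` to
#'   [bruteForceOccurrences()]/[bruteForceCounts()].
#' @export
makeWindowCache <- function() new.env(parent = emptyenv())
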