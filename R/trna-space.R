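# Construction of "tRNA space": the genomic loci harbouring tRNA genes,
# their spliced and CCA-appended mature sequences, and the merged
# interval set occurrences are classified against.

#' Read a genome FASTA file
#'
#' Loads a (multi-record) FASTA file into a named
#' [Biostrings::DNAStringSet]. Sequences are uppercased; duplicate record
#' names are rejected because downstream coordinate maps key on the
#' chromosome identifier.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`, one entry per record.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  firstLines <- readLines(path, n = 50L)
  nonEmpty <- which(nzchar(trimws(firstLines)))
  if (length(nonEmpty) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(firstLines[nonEmpty[1]], ">"))
    stop("malformed FASTA (line ", nonEmpty[1], " does not start a record): ",
         path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence name(s) in FASTA: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x
}

#' Read a tRNA gene annotation (BED12 + 3 extra columns)
#'
#' Parses a tab-separated BED12 file with three auxiliary columns:
#' column 13 the amino acid, column 14 the anticodon, column 15 the
#' 0-based genomic start of the anticodon. BED blocks encode exons;
#' introns are the gaps between consecutive blocks. Input coordinates
#' are 0-based half-open (BED convention) and are converted to the
#' 1-based closed coordinates used throughout the package.
#'
#' @param path path to the annotation file.
#' @param mitoChrom chromosome name identifying the mitochondrial
#'   genome; loci on it are flagged `compartment = "mitochondrial"`.
#' @return a [GenomicRanges::GRanges] with one range per locus and
#'   metadata columns `name`, `aminoAcid`, `anticodon`,
#'   `anticodonRange` ([IRanges::IRanges], genomic, 1-based),
#'   `introns` ([IRanges::IRangesList], genomic, 1-based) and
#'   `compartment`.
#' @export
readTrnaAnnotation <- function(path, mitoChrom = "chrM") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 15L)
    stop("annotation must have 15 tab-separated columns (BED12 + 3), got ",
         ncol(raw))
  n <- nrow(raw)
  chrom <- as.character(raw[[1]])
  start0 <- as.integer(raw[[2]])
  end0 <- as.integer(raw[[3]])
  name <- as.character(raw[[4]])
  strand <- as.character(raw[[6]])
  if (any(start0 >= end0)) stop("locus start must be < end")
  if (!all(strand %in% c("+", "-")))
    stop("strand column must be '+' or '-'")

  introns <- vector("list", n)
  acRanges <- IRanges::IRanges()
  for (i in seq_len(n)) {
    nb <- as.integer(raw[[10]][i])
    sizes <- as.integer(strsplit(sub(",$", "", as.character(raw[[11]][i])), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", as.character(raw[[12]][i])), ",")[[1]])
    if (length(sizes) != nb || length(offs) != nb)
      stop("block count disagrees with block lists for locus ", name[i])
    exonStart <- start0[i] + offs + 1L        # 1-based
    exonEnd <- exonStart + sizes - 1L
    if (any(exonStart < start0[i] + 1L) || any(exonEnd > end0[i]))
      stop("blocks outside locus interval for ", name[i])
    if (is.unsorted(exonStart, strictly = TRUE))
      stop("blocks must be sorted for ", name[i])
    if (nb > 1L && any(exonStart[-1] <= exonEnd[-nb]))
      stop("blocks must not overlap for ", name[i])
    if (exonStart[1] != start0[i] + 1L || exonEnd[nb] != end0[i])
      stop("first/last block must reach the locus boundaries for ", name[i])
    introns[[i]] <- if (nb > 1L)
      IRanges::IRanges(start = exonEnd[-nb] + 1L, end = exonStart[-1] - 1L)
    else IRanges::IRanges()

    ac0 <- as.integer(raw[[15]][i])
    acIr <- IRanges::IRanges(start = ac0 + 1L, width = 3L)
    if (IRanges::start(acIr) < start0[i] + 1L || IRanges::end(acIr) > end0[i])
      stop("anticodon block outside locus interval for ", name[i])
    if (length(introns[[i]]) &&
        any(IRanges::overlapsAny(acIr, introns[[i]])))
      stop("anticodon block lies inside an intron for ", name[i])
    acRanges <- c(acRanges, acIr)
  }

  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$aminoAcid <- as.character(raw[[13]])
  S4Vectors::mcols(gr)$anticodon <- as.character(raw[[14]])
  S4Vectors::mcols(gr)$anticodonRange <- acRanges
  S4Vectors::mcols(gr)$introns <- IRanges::IRangesList(introns)
  S4Vectors::mcols(gr)$compartment <-
    ifelse(chrom == mitoChrom, "mitochondrial", "nuclear")
  names(gr) <- name
  gr
}

#' Extract a locus sequence in transcript orientation
#'
#' Returns the genomic subsequence of a tRNA locus, reverse-complemented
#' for minus-strand loci so that the result always reads 5' to 3' in
#' transcript orientation.
#'
#' @param genome named `DNAStringSet` (see [readGenomeFasta()]).
#' @param locus a length-1 `GRanges` as produced by
#'   [readTrnaAnnotation()].
#' @return a [Biostrings::DNAString].
#' @export
extractLocusSequence <- function(genome, locus) {
  genome <- .asGenome(genome)
  stopifnot(length(locus) == 1L)
  chrom <- as.character(GenomicRanges::seqnames(locus))
  if (!chrom %in% names(genome))
    stop("unknown chromosome: ", chrom)
  chr <- genome[[chrom]]
  s <- GenomicRanges::start(locus); e <- GenomicRanges::end(locus)
  if (s < 1L || e > length(chr))
    stop("locus interval out of chromosome bounds: ", chrom, ":", s, "-", e)
  seq <- Biostrings::subseq(chr, s, e)
  if (as.character(GenomicRanges::strand(locus)) == "-")
    seq <- Biostrings::reverseComplement(seq)
  seq
}

# Build one mature tRNA entry (internal worker). Returns the pieces a
# MatureTRNASet is assembled from.
.buildOneMature <- function(locus, locusSeq) {
  chrom <- as.character(GenomicRanges::seqnames(locus))
  strand <- as.character(GenomicRanges::strand(locus))
  s <- GenomicRanges::start(locus); e <- GenomicRanges::end(locus)
  chars <- strsplit(as.character(locusSeq), "")[[1]]
  if (length(chars) != e - s + 1L)
    stop("locus sequence length disagrees with locus span")
  # genomic position of each transcript-oriented base
  gposAll <- if (strand == "+") s:e else e:s
  introns <- S4Vectors::mcols(locus)$introns[[1]]
  intronPos <- if (length(introns))
    unlist(lapply(seq_along(introns), function(i)
      IRanges::start(introns)[i]:IRanges::end(introns)[i]))
  else integer(0)
  keep <- !(gposAll %in% intronPos)
  if (!any(keep)) stop("intron removal left an empty mature sequence")
  matureChars <- chars[keep]
  gpos <- gposAll[keep]
  seq <- paste0(paste(matureChars, collapse = ""), "CCA")
  acIr <- S4Vectors::mcols(locus)$anticodonRange
  acFirstGenomic <- if (strand == "+") IRanges::start(acIr) else IRanges::end(acIr)
  acStart <- match(acFirstGenomic, gpos)
  list(
    seq = seq,
    map = list(chrom = chrom, strand = strand,
               gpos = c(gpos, NA_integer_, NA_integer_, NA_integer_)),
    anticodonStart = as.integer(acStart),
    hasN = any(!matureChars %in% c("A", "C", "G", "T"))
  )
}

#' Build the mature tRNA sequence for one locus
#'
#' Removes intron blocks from the transcript-oriented locus sequence and
#' appends the non-templated `CCA`, producing the mature sequence along
#' with its mature-to-genome coordinate map.
#'
#' @param locus a length-1 annotated locus `GRanges`.
#' @param locusSeq transcript-oriented locus sequence from
#'   [extractLocusSequence()].
#' @return a length-1 [MatureTRNASet-class].
#' @export
buildMatureTrna <- function(locus, locusSeq) {
  m <- .buildOneMature(locus, locusSeq)
  new("MatureTRNASet",
      seqs = stats::setNames(Biostrings::DNAStringSet(m$seq),
                             S4Vectors::mcols(locus)$name),
      coordMaps = list(m$map),
      anticodonStart = m$anticodonStart,
      hasN = m$hasN)
}

#' Build mature tRNAs for a whole annotation
#'
#' Convenience wrapper running [extractLocusSequence()] and
#' [buildMatureTrna()] over every locus; no locus is silently dropped.
#'
#' @param genome named `DNAStringSet`.
#' @param loci annotated loci `GRanges` from [readTrnaAnnotation()].
#' @return a [MatureTRNASet-class] with one entry per locus.
#' @export
buildMatureTrnas <- function(genome, loci) {
  genome <- .asGenome(genome)
  parts <- lapply(seq_along(loci), function(i) {
    locus <- loci[i]
    .buildOneMature(locus, extractLocusSequence(genome, locus))
  })
  new("MatureTRNASet",
      seqs = stats::setNames(
        Biostrings::DNAStringSet(vapply(parts, `[[`, "", "seq")),
        S4Vectors::mcols(loci)$name),
      coordMaps = lapply(parts, `[[`, "map"),
      anticodonStart = vapply(parts, `[[`, integer(1), "anticodonStart"),
      hasN = vapply(parts, `[[`, logical(1), "hasN"))
}

#' Merge tRNA loci into the tRNA-space interval set
#'
#' Collapses the annotated loci into a sorted, strand-ignorant, merged
#' set of genomic intervals — the region exact occurrences are
#' classified against. The operation is idempotent and independent of
#' input order.
#'
#' @param loci `GRanges` of tRNA loci (strand ignored).
#' @return an unstranded, reduced, sorted `GRanges`; its total span in
#'   nucleotides is `sum(width(.))`.
#' @export
buildTrnaSpace <- function(loci) {
  if (length(loci) == 0L) stop("at least one locus is required")
  gr <- GenomicRanges::granges(loci)
  GenomicRanges::strand(gr) <- "*"
  GenomicRanges::sort(GenomicRanges::reduce(gr))
}

#' Write mature tRNAs as FASTA
#'
#' Record ids are the locus names; the description carries the 1-based
#' mature anticodon start (`ac=<pos>`) so that fragment typing can be
#' reconstructed from the FASTA alone.
#'
#' @param matures a [MatureTRNASet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMatureFasta <- function(matures, path) {
  seqs <- matureSeqs(matures)
  names(seqs) <- paste0(names(matures), " ac=", anticodonStart(matures))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a mature tRNA FASTA written by [writeMatureFasta()]
#'
#' Restores sequences and anticodon positions (coordinate maps are not
#' serialized to FASTA and are unavailable on the result).
#'
#' @param path FASTA file.
#' @return list with `seqs` (named character) and `anticodonStart`
#'   (named integer, `NA` where no `ac=` tag was present).
#' @export
readMatureFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  full <- names(x)
  ids <- sub("\\s.*$", "", full)
  ac <- suppressWarnings(as.integer(sub("^.*\\bac=(\\d+).*$", "\\1", full)))
  ac[!grepl("\\bac=\\d+", full)] <- NA_integer_
  list(seqs = stats::setNames(as.character(x), ids),
       anticodonStart = stats::setNames(ac, ids))
}

#' Write an interval set as BED3
#'
#' Converts from the package's 1-based closed coordinates to BED's
#' 0-based half-open convention.
#'
#' @param gr a `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBed3 <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 file into a GRanges
#'
#' @param path BED file (first three columns used).
#' @return an unstranded `GRanges`.
#' @export
readBed3 <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  GenomicRanges::GRanges(
    seqnames = as.character(df[[1]]),
    ranges = IRanges::IRanges(start = as.integer(df[[2]]) + 1L,
                              end = as.integer(df[[3]])))
}
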