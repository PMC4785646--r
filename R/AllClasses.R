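#' @import methods
#' @importFrom S4Vectors isConstant
NULL

#' Set of mature tRNA sequences with genomic coordinate maps
#'
#' A `MatureTRNASet` holds spliced, strand-resolved mature tRNA sequences
#' with the non-templated `CCA` trinucleotide appended, together with a
#' per-base map back to genomic coordinates. The last three bases of every
#' sequence are the enzymatically added CCA and carry no genomic
#' coordinate (`NA` in the map); every other base maps to exactly one
#' genomic position in transcript orientation.
#'
#' @slot seqs [Biostrings::DNAStringSet] of mature sequences, named by
#'   source locus; every sequence ends in `CCA`.
#' @slot coordMaps list, one entry per sequence: a list with elements
#'   `chrom` (character), `strand` (`"+"`/`"-"`) and `gpos` (integer
#'   vector of 1-based genomic positions, `NA` for the terminal CCA).
#' @slot anticodonStart integer vector, 1-based mature position of the
#'   first anticodon base, per sequence.
#' @slot hasN logical vector flagging loci whose genomic sequence
#'   contained ambiguous bases (`N`); such loci are kept but their
#'   N-containing k-mers are excluded from enumeration.
#'
#' @seealso [buildMatureTrnas()], [matureSeqs()], [anticodonStart()]
#' @export
setClass("MatureTRNASet",
  slots = c(
    seqs = "DNAStringSet",
    coordMaps = "list",
    anticodonStart = "integer",
    hasN = "logical"
  )
)

setValidity("MatureTRNASet", function(object) {
  n <- length(object@seqs)
  msgs <- character(0)
  if (length(object@coordMaps) != n || length(object@anticodonStart) != n ||
      length(object@hasN) != n)
    msgs <- c(msgs, "slot lengths disagree")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msgs <- c(msgs, "sequences must have unique names")
  seqs <- as.character(object@seqs)
  if (n && !all(substring(seqs, nchar(seqs) - 2L) == "CCA"))
    msgs <- c(msgs, "every mature sequence must end in CCA")
  for (i in seq_len(n)) {
    cm <- object@coordMaps[[i]]
    L <- nchar(seqs[i])
    if (length(cm$gpos) != L) {
      msgs <- c(msgs, sprintf("coord map %d length != sequence length", i))
      next
    }
    naPos <- which(is.na(cm$gpos))
    if (!identical(naPos, (L - 2L):L))
      msgs <- c(msgs, sprintf("exactly the last 3 positions of map %d must be non-templated", i))
    g <- cm$gpos[!is.na(cm$gpos)]
    d <- diff(g)
    ok <- if (identical(cm$strand, "+")) all(d > 0) else all(d < 0)
    if (!ok)
      msgs <- c(msgs, sprintf("coord map %d not monotone in transcript orientation", i))
    a <- object@anticodonStart[i]
    if (!is.na(a) && (a < 1L || a + 2L > L))
      msgs <- c(msgs, sprintf("anticodon position of entry %d out of range", i))
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-k-mer genomic exclusivity table
#'
#' Records, for every distinct k-mer of a set of mature tRNA sequences,
#' how many exact genomic occurrences fall fully inside the annotated
#' tRNA loci ("tRNA space") versus outside, counting both the forward
#' match and the reverse-complement match of each k-mer (a palindromic
#' k-mer at one genomic window counts once). A k-mer that only exists in
#' mature sequence via a splice junction or the non-templated CCA can
#' legitimately have zero genomic occurrences in total.
#'
#' @slot k integer k-mer length.
#' @slot kmers character vector of distinct k-mers (alphabet `ACGT`).
#' @slot inside,outside integer occurrence counts per k-mer.
#' @slot nSources integer; number of (mature tRNA, offset) source windows
#'   per k-mer.
#' @slot sources data.frame with columns `kmer`, `trna`, `start`
#'   (1-based mature position) listing every source window.
#' @slot scanned logical; `TRUE` once a genome scan filled the counts.
#'
#' @seealso [enumerateMatureKmers()], [scanGenome()], [summarizeAmbiguity()]
#' @export
setClass("ExclusivityTable",
  slots = c(
    k = "integer",
    kmers = "character",
    inside = "integer",
    outside = "integer",
    nSources = "integer",
    sources = "data.frame",
    scanned = "logical"
  )
)

setValidity("ExclusivityTable", function(object) {
  msgs <- character(0)
  if (length(object@k) != 1L || object@k < 1L)
    msgs <- c(msgs, "k must be a single integer >= 1")
  n <- length(object@kmers)
  if (n) {
    if (!all(nchar(object@kmers) == object@k))
      msgs <- c(msgs, "all k-mers must have length k")
    if (any(grepl("[^ACGT]", object@kmers)))
      msgs <- c(msgs, "k-mers restricted to alphabet {A,C,G,T}")
    if (anyDuplicated(object@kmers))
      msgs <- c(msgs, "k-mers must be distinct")
  }
  if (length(object@inside) != n || length(object@outside) != n ||
      length(object@nSources) != n)
    msgs <- c(msgs, "count vectors must parallel the k-mer vector")
  if (n && any(object@nSources < 1L))
    msgs <- c(msgs, "every k-mer needs at least one source window")
  if (n && (any(object@inside < 0L) || any(object@outside < 0L)))
    msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth for a synthetic fixture
#'
#' Produced by [generateGenome()] and extended by [generateReads()].
#' `features` records every planted genomic feature (true tRNA genes,
#' truncated partial copies, mutated lookalikes, verbatim CCA-ending
#' decoy sites) with 1-based inclusive coordinates and the planted
#' sequence; `reads` records every simulated read with its origin
#' feature and the ambiguity label expected under exact matching, as
#' recomputed from the emitted genome by the naive brute-force scan at
#' generation time.
#'
#' @slot features data.frame: `id`, `kind` (`TRNA`, `PARTIAL`,
#'   `LOOKALIKE`, `CCA_DECOY`), `chrom`, `start`, `end`, `strand`,
#'   `source`, `seq` (forward-strand genomic sequence).
#' @slot reads data.frame (possibly empty): `id`, `seq`, `count`,
#'   `origin`, `kind`, `expectedOutside`, `expectedAmbiguity`,
#'   `expectedType`.
#' @slot spec list; the [syntheticGenomeSpec()] the fixture was built from.
#'
#' @export
setClass("SyntheticTruth",
  slots = c(features = "data.frame", reads = "data.frame", spec = "list")
)

setValidity("SyntheticTruth", function(object) {
  need <- c("id", "kind", "chrom", "start", "end", "strand", "source", "seq")
  if (!all(need %in% names(object@features)))
    return("features is missing required columns")
  if (nrow(object@features) && any(object@features$start > object@features$end))
    return("feature start must not exceed end")
  TRUE
})
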