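# Accessors and show methods for the package's S4 containers.

#' @rdname MatureTRNASet-class
#' @export
setMethod("matureSeqs", "MatureTRNASet", function(x) x@seqs)

#' @rdname MatureTRNASet-class
#' @export
setMethod("anticodonStart", "MatureTRNASet", function(x) {
  stats::setNames(x@anticodonStart, names(x@seqs))
})

#' @rdname MatureTRNASet-class
#' @export
setMethod("coordMap", "MatureTRNASet", function(x, name) {
  i <- match(name, names(x@seqs))
  if (is.na(i)) stop("no mature tRNA named '", name, "'")
  x@coordMaps[[i]]
})

#' @rdname MatureTRNASet-class
#' @export
setMethod("length", "MatureTRNASet", function(x) length(x@seqs))

#' @rdname MatureTRNASet-class
#' @export
setMethod("names", "MatureTRNASet", function(x) names(x@seqs))

#' @rdname MatureTRNASet-class
#' @param object a `MatureTRNASet`.
#' @export
setMethod("show", "MatureTRNASet", function(object) {
  n <- length(object)
  cat("MatureTRNASet with", n, "mature tRNA sequence(s)\n")
  if (n) {
    w <- Biostrings::width(object@seqs)
    cat("  lengths (incl. CCA):", min(w), "-", max(w), "nt\n")
    cat("  loci flagged with N:", sum(object@hasN), "\n")
  }
})

#' Subset a MatureTRNASet
#'
#' @param x a `MatureTRNASet`.
#' @param i index or names.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MatureTRNASet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  new("MatureTRNASet",
      seqs = x@seqs[i],
      coordMaps = x@coordMaps[i],
      anticodonStart = x@anticodonStart[i],
      hasN = x@hasN[i])
})

#' @rdname ExclusivityTable-class
#' @export
setMethod("kmers", "ExclusivityTable", function(x) x@kmers)

#' @rdname ExclusivityTable-class
#' @export
setMethod("insideCounts", "ExclusivityTable", function(x) {
  stats::setNames(x@inside, x@kmers)
})

#' @rdname ExclusivityTable-class
#' @export
setMethod("outsideCounts", "ExclusivityTable", function(x) {
  stats::setNames(x@outside, x@kmers)
})

#' @rdname ExclusivityTable-class
#' @export
setMethod("kmerSources", "ExclusivityTable", function(x) x@sources)

#' @rdname ExclusivityTable-class
#' @export
setMethod("length", "ExclusivityTable", function(x) length(x@kmers))

#' @rdname ExclusivityTable-class
#' @param object an `ExclusivityTable`.
#' @export
setMethod("show", "ExclusivityTable", function(object) {
  cat("ExclusivityTable (k = ", object@k, ") with ", length(object@kmers),
      " distinct k-mer(s); counts ",
      if (object@scanned) "filled" else "not yet scanned", "\n", sep = "")
  if (object@scanned && length(object@kmers)) {
    cat("  exclusive (no outside copies):", sum(object@outside == 0L), "\n")
  }
})

#' Tabular view of an ExclusivityTable
#'
#' @param x an `ExclusivityTable`.
#' @param row.names,optional,... passed on conventionally; unused.
#' @return data.frame with columns `kmer`, `k`, `inside`, `outside`,
#'   `nSources`, `exclusive`.
#' @export
as.data.frame.ExclusivityTable <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(kmer = x@kmers, k = x@k,
             inside = x@inside, outside = x@outside,
             nSources = x@nSources,
             exclusive = ifelse(x@outside == 0L, "Y", "N"),
             stringsAsFactors = FALSE)
}

#' @rdname SyntheticTruth-class
#' @export
setMethod("truthFeatures", "SyntheticTruth", function(x) x@features)

#' @rdname SyntheticTruth-class
#' @export
setMethod("truthReads", "SyntheticTruth", function(x) x@reads)

#' @rdname SyntheticTruth-class
#' @param object a `SyntheticTruth`.
#' @export
setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@features), "planted feature(s),",
      nrow(object@reads), "simulated read(s)\n")
  if (nrow(object@features))
    print(table(object@features$kind))
})
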