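#' @rdname MatureTRNASet-class
#' @param x a `MatureTRNASet` or `ExclusivityTable`.
#' @export
setGeneric("matureSeqs", function(x) standardGeneric("matureSeqs"))

#' @rdname MatureTRNASet-class
#' @export
setGeneric("anticodonStart", function(x) standardGeneric("anticodonStart"))

#' @rdname MatureTRNASet-class
#' @param name locus name of one mature tRNA.
#' @export
setGeneric("coordMap", function(x, name) standardGeneric("coordMap"))

#' @rdname ExclusivityTable-class
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))

#' @rdname ExclusivityTable-class
#' @export
setGeneric("insideCounts", function(x) standardGeneric("insideCounts"))

#' @rdname ExclusivityTable-class
#' @export
setGeneric("outsideCounts", function(x) standardGeneric("outsideCounts"))

#' @rdname ExclusivityTable-class
#' @export
setGeneric("kmerSources", function(x) standardGeneric("kmerSources"))

#' @rdname SyntheticTruth-class
#' @param x a `SyntheticTruth`.
#' @export
setGeneric("truthFeatures", function(x) standardGeneric("truthFeatures"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthReads", function(x) standardGeneric("truthReads"))
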