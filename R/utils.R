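# Internal helpers shared across modules.

# Reverse complement of a character vector of DNA strings.
.revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Round half away from zero (commercial rounding), as used for the
# percentage columns of the exclusivity summary. base::round() rounds
# half to even, which would turn 12.25 into 12.2 rather than 12.3.
.roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb user sessions.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  code
}

# Coerce a genome argument to a named DNAStringSet. Accepts a
# DNAStringSet or a named character vector.
.asGenome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(genome)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a DNAStringSet or a named character vector")
}

# Coerce mature tRNAs to a named character vector of sequences.
.asMatureSeqs <- function(matures) {
  if (is(matures, "MatureTRNASet")) {
    s <- as.character(matureSeqs(matures))
    names(s) <- names(matures)
    return(s)
  }
  if (is(matures, "DNAStringSet")) {
    s <- as.character(matures)
    if (is.null(names(s))) stop("mature sequences must be named")
    return(s)
  }
  if (is.character(matures)) {
    if (is.null(names(matures))) stop("mature sequences must be named")
    return(matures)
  }
  stop("matures must be a MatureTRNASet, DNAStringSet or named character vector")
}

# All length-k windows of a string as a character vector (5'->3' order).
.kmerWindows <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

# tRNA space (GRanges) -> plain data.frame, used by the base-R oracle path.
.spaceToDf <- function(space) {
  if (is.null(space) || length(space) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(space)),
             start = GenomicRanges::start(space),
             end = GenomicRanges::end(space),
             stringsAsFactors = FALSE)
}

# Write a data.frame as TSV with '#'-prefixed provenance lines on top.
.writeProvenancedTsv <- function(df, path, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- tryCatch(as.character(utils::packageVersion("tRFspace")),
                      error = function(e) "dev")
  writeLines(c(
    paste0("# tRFspace ", version),
    paste0("# created: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    if (length(extra)) paste0("# ", extra)
  ), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV written by .writeProvenancedTsv (comment lines skipped).
.readProvenancedTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
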