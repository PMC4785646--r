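# Small in-code fixtures shared across test files.

writeTempFasta <- function(seqs, ext = ".fa") {
  path <- tempfile(fileext = ext)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

writeTempFastq <- function(seqs) {
  path <- tempfile(fileext = ".fq")
  con <- file(path, "w")
  for (i in seq_along(seqs)) {
    writeLines(c(paste0("@r", i), seqs[i], "+", strrep("I", nchar(seqs[i]))),
               con)
  }
  close(con)
  path
}

# One BED12+3 annotation line. Coordinates are 0-based half-open (BED);
# blockSizes/blockStarts relative to start0.
annotationLine <- function(chrom, start0, end0, name, strand,
                           blockSizes, blockStarts, ac0,
                           aa = "Xxx", anticodon = "NNN") {
  paste(chrom, start0, end0, name, 0L, strand, start0, end0, "0",
        length(blockSizes),
        paste0(paste(blockSizes, collapse = ","), ","),
        paste0(paste(blockStarts, collapse = ","), ","),
        aa, anticodon, ac0, sep = "\t")
}

writeTempAnnotation <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# Independent base-R reverse complement for use inside tests.
rcBase <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# The default-condition synthetic fixture, built once per test run.
defaultFixture <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      dir <- tempfile("fixture")
      gen <- generateGenome(syntheticGenomeSpec(seed = 42L), outDir = dir)
      loci <- readTrnaAnnotation(gen$files[["annotation"]])
      genome <- readGenomeFasta(gen$files[["genome"]])
      matures <- buildMatureTrnas(genome, loci)
      space <- buildTrnaSpace(loci)
      cached <<- list(gen = gen, loci = loci, genome = genome,
                      matures = matures, space = space, dir = dir)
    }
    cached
  }
})
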