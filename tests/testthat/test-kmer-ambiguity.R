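# k-mer enumeration, genome scanning, exclusivity summaries and the
# CCA/lookalike/RepeatMasker side analyses.

emptySpace <- GenomicRanges::GRanges()

test_that("k-mer enumeration covers windows, dedups and records sources", {
  tb <- enumerateMatureKmers(c(m1 = "ACGTACG"), 4L)
  expect_setequal(kmers(tb), c("ACGT", "CGTA", "GTAC", "TACG"))

  tb2 <- enumerateMatureKmers(c(m1 = "AAAAA"), 3L)
  expect_identical(kmers(tb2), "AAA")
  expect_identical(nrow(kmerSources(tb2)), 3L)

  # identical matures double the sources but not the distinct keys
  tb3 <- enumerateMatureKmers(c(m1 = "ACGTACG", m2 = "ACGTACG"), 4L)
  expect_identical(length(tb3), length(tb))
  expect_identical(nrow(kmerSources(tb3)), 2L * nrow(kmerSources(tb)))

  # windows containing N are skipped
  tb4 <- enumerateMatureKmers(c(m1 = "ACGNACGT"), 4L)
  expect_setequal(kmers(tb4), "ACGT")

  expect_warning(enumerateMatureKmers(c(m1 = "ACG"), 10L), "exceeds")
  expect_error(enumerateMatureKmers(c(m1 = "ACG"), 0L), "k must")
})

test_that("genome scan counts both strands with palindromes counted once", {
  # palindromic key matching forward and as its own reverse complement
  g <- c(chrA = "TTACGTTT")
  tb <- scanGenome(g, enumerateMatureKmers(c(m = "ACGT"), 4L), emptySpace)
  expect_identical(unname(outsideCounts(tb)["ACGT"]), 1L)
  expect_identical(unname(insideCounts(tb)["ACGT"]), 0L)

  # containment in tRNA space (space [2,6) 0-based = 3..6 1-based)
  sp <- GenomicRanges::GRanges("chrB", IRanges::IRanges(3, 6))
  tb2 <- scanGenome(c(chrB = "TTAAACTT"),
                    enumerateMatureKmers(c(m = "AAAC"), 4L), sp)
  expect_identical(unname(insideCounts(tb2)["AAAC"]), 1L)
  expect_identical(unname(outsideCounts(tb2)["AAAC"]), 0L)

  # hit purely via reverse complement
  tb3 <- scanGenome(c(chrC = "GTTT"),
                    enumerateMatureKmers(c(m = "AAAC"), 4L), emptySpace)
  expect_identical(unname(outsideCounts(tb3)["AAAC"]), 1L)

  expect_warning(scanGenome(c(chrD = ""),
                            enumerateMatureKmers(c(m = "AAAC"), 4L),
                            emptySpace), "empty genome")
})

test_that("scan counts equal the brute-force oracle on a random genome", {
  set.seed(101)
  g <- c(chr1 = randomDna(50000))
  # 20 16-mers drawn from the genome (guaranteed present) as "matures"
  starts <- sample.int(50000 - 15L, 20L)
  keys <- substring(g, starts, starts + 15L)
  names(keys) <- paste0("m", seq_along(keys))
  sp <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1000, 30000), c(5000, 31000)))
  tb <- scanGenome(g, enumerateMatureKmers(keys, 16L), sp)
  cache <- makeWindowCache()
  for (km in kmers(tb)) {
    expected <- bruteForceCounts(g, km, sp, cache = cache)
    expect_identical(unname(insideCounts(tb)[km]), unname(expected["inside"]))
    expect_identical(unname(outsideCounts(tb)[km]), unname(expected["outside"]))
  }
})

test_that("ambiguity summary counts exclusives and rounds half-up", {
  mkTable <- function(n, nExclusive, k = 5L) {
    all5 <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                        stringsAsFactors = FALSE)
    km <- do.call(paste0, all5)[seq_len(n)]
    new("ExclusivityTable", k = k, kmers = km,
        inside = rep(1L, n),
        outside = c(rep(0L, nExclusive), rep(2L, n - nExclusive)),
        nSources = rep(1L, n),
        sources = data.frame(kmer = km, trna = "m", start = seq_len(n),
                             stringsAsFactors = FALSE),
        scanned = TRUE)
  }
  s <- summarizeAmbiguity(mkTable(4L, 1L))
  expect_identical(s$nDistinct, 4L)
  expect_identical(s$nExclusive, 1L)
  expect_identical(s$nNonexclusive, 3L)
  expect_equal(s$pctExclusive, 25.0)
  expect_equal(s$pctNonexclusive, 75.0)

  expect_equal(summarizeAmbiguity(mkTable(4L, 4L))$pctExclusive, 100.0)

  # 49/400 = 12.25 %: half-up gives 12.3 (banker's rounding would give 12.2)
  expect_equal(summarizeAmbiguity(mkTable(400L, 49L))$pctExclusive, 12.3)

  expect_error(summarizeAmbiguity(
    suppressWarnings(enumerateMatureKmers(c(m = "ACG"), 10L))), "empty")
})

test_that("single-query occurrence counting matches its contract", {
  expect_identical(
    countSequenceOccurrences(c(chr = "AAGGAAGG"), "AAGG", emptySpace),
    c(inside = 0L, outside = 2L))
  expect_error(countSequenceOccurrences(c(chr = "AAGG"), "AANG"), "alphabet")

  # query equal to a planted tRNA locus, space = that locus
  fx <- defaultFixture()
  feats <- truthFeatures(fx$gen$truth)
  tr <- feats[feats$kind == "TRNA", ][1, ]
  occ <- countSequenceOccurrences(fx$genome, tr$seq, fx$space)
  expect_gte(occ[["inside"]], 1L)
})

test_that("query counting agrees with the brute-force oracle across cases", {
  set.seed(77)
  cache <- makeWindowCache()
  g <- c(c1 = randomDna(8000), c2 = randomDna(4000))
  sp <- GenomicRanges::GRanges(c("c1", "c2"),
                               IRanges::IRanges(c(100, 1), c(2000, 500)))
  for (i in 1:25) {
    k <- sample(4:18, 1)
    q <- if (i %% 2 == 0) randomDna(k) else {
      chrom <- sample(names(g), 1)
      s <- sample.int(nchar(g[[chrom]]) - k + 1L, 1L)
      w <- substring(g[[chrom]], s, s + k - 1L)
      if (i %% 3 == 0) rcBase(w) else w
    }
    expect_identical(countSequenceOccurrences(g, q, sp),
                     bruteForceCounts(g, q, sp, cache = cache),
                     info = paste("query", q))
  }
})

test_that("CCA-terminal report counts outside copies per tRNA", {
  # one decoy site equal to a planted tRNA's terminal 16-mer
  set.seed(11)
  body <- randomDna(30)
  mature <- paste0(body, "CCA")
  term <- substring(mature, nchar(mature) - 15L)
  locusSeq <- body                       # genomic gene (no CCA)
  g <- c(chr = paste0("TTTT", locusSeq, "TTTTTT", term, "TT"))
  sp <- GenomicRanges::GRanges("chr", IRanges::IRanges(5L, 4L + nchar(body)))
  rep1 <- ccaTerminalReport(c(t1 = mature), g, sp, k = 16L)
  expect_identical(rep1$nTrnasWithOutsideCopies, 1L)
  expect_identical(rep1$grandTotalOutside, 1L)

  # no decoys planted
  g0 <- c(chr = paste0("TTTT", locusSeq, "TTTTTT"))
  rep0 <- ccaTerminalReport(c(t1 = mature), g0, sp, k = 16L)
  expect_identical(rep0$nTrnasWithOutsideCopies, 0L)
  expect_identical(rep0$grandTotalOutside, 0L)

  # grand total sums over tRNAs: two tRNAs sharing the terminal k-mer
  rep2 <- ccaTerminalReport(c(t1 = mature, t2 = mature), g, sp, k = 16L)
  expect_identical(rep2$grandTotalOutside, 2L)

  expect_warning(ccaTerminalReport(c(short = "ACCA"), g, sp, k = 16L),
                 "shorter")
})

test_that("crosstalk report counts shared canonical k-mers", {
  set.seed(5)
  m <- c(t1 = randomDna(40))
  # foreign sequence identical to the mature: shares L-k+1 k-mers
  ct <- crosstalkReport(m, c(f1 = m[[1]]), k = 16L)
  w <- substring(m[[1]], 1:25, 16:40)
  expected <- length(unique(pmin(w, rcBase(w))))
  expect_identical(unname(ct$perTrna["t1"]), expected)
  expect_identical(ct$nTrnasSharing, 1L)
  expect_identical(ct$nSharedKmers, expected)

  # sharing via reverse complement counts too
  ctRc <- crosstalkReport(m, c(f1 = rcBase(m[[1]])), k = 16L)
  expect_identical(ctRc$nSharedKmers, expected)

  # disjoint foreign set
  ct0 <- crosstalkReport(m, c(f1 = strrep("A", 40)), k = 16L)
  expect_identical(ct0$nTrnasSharing, 0L)
  expect_identical(ct0$nSharedKmers, 0L)

  expect_error(crosstalkReport(m, c(f = "ACGT"), k = 0L), "k must")
  expect_error(crosstalkReport(m, character(0)), "non-empty")
})

test_that("RepeatMasker parsing extracts class before the family slash", {
  out <- c(
    "   SW  perc perc perc  query    position in query  matching repeat",
    "score  div. del. ins.  sequence begin end (left)   repeat class/family begin end (left) ID",
    "",
    "  463  10.1  0.0  0.0  chr1  1000  1047  (500)  +  tRNA-Gly  tRNA  1  48  (0)  1",
    "  300   5.0  0.1  0.0  chr2  2000  2300  (100)  C  AluY      SINE/Alu  1  300  (0)  2")
  p <- tempfile(fileext = ".out")
  writeLines(out, p)
  feats <- readRepeatMaskerOut(p)
  expect_identical(nrow(feats), 2L)
  expect_identical(feats$repeatClass, c("tRNA", "SINE"))
  expect_identical(feats$strand, c("+", "-"))
  expect_identical(feats$length, c(48L, 301L))

  bad <- c(out[1:3], "  99  1.0  0.0  0.0  chr1  50  10  (0)  +  x  tRNA  1  5  (0)  3")
  pb <- tempfile(fileext = ".out")
  writeLines(bad, pb)
  expect_error(readRepeatMaskerOut(pb), "line 4")
})

test_that("short tRNA repeat filter applies class, length and containment", {
  mkFeat <- function(start, len, cls = "tRNA") {
    data.frame(chrom = "chr1", start = start, end = start + len - 1L,
               strand = "+", repeatName = "x", repeatClass = cls,
               length = len, stringsAsFactors = FALSE)
  }
  sp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000L, 1200L))
  expect_identical(filterShortTrnaRepeats(mkFeat(5000L, 48L), sp)$count, 1L)
  expect_identical(filterShortTrnaRepeats(mkFeat(1050L, 48L), sp)$count, 0L)
  expect_identical(filterShortTrnaRepeats(mkFeat(5000L, 51L), sp)$count, 0L)
  expect_identical(filterShortTrnaRepeats(mkFeat(5000L, 48L, "SINE"), sp)$count, 0L)
  # boundary: length exactly maxLen passes
  expect_identical(filterShortTrnaRepeats(mkFeat(5000L, 50L), sp)$count, 1L)
})

test_that("junction/CCA k-mers with zero genomic occurrences are exclusive", {
  fx <- defaultFixture()
  tb <- scanGenome(fx$genome, enumerateMatureKmers(fx$matures, 16L), fx$space)
  zero <- insideCounts(tb) == 0L & outsideCounts(tb) == 0L
  # the fixture has intronic tRNAs and CCA ends, so such k-mers exist
  expect_gt(sum(zero), 0L)
  s <- summarizeAmbiguity(tb)
  expect_identical(s$nExclusive, sum(outsideCounts(tb) == 0L))
})

test_that("counts are invariant under reverse-complementing the genome", {
  set.seed(9)
  g <- c(c1 = randomDna(5000))
  keys <- stats::setNames(substring(g, c(100, 900, 2500), c(115, 915, 2515)),
                          paste0("m", 1:3))
  sp <- GenomicRanges::GRanges("c1", IRanges::IRanges(50, 1500))
  tb <- scanGenome(g, enumerateMatureKmers(keys, 16L), sp)

  gRc <- c(c1 = rcBase(g[[1]]))
  L <- nchar(g[[1]])
  spRc <- GenomicRanges::GRanges("c1", IRanges::IRanges(L - 1500 + 1, L - 50 + 1))
  tbRc <- scanGenome(gRc, enumerateMatureKmers(keys, 16L), spRc)
  expect_identical(insideCounts(tb), insideCounts(tbRc))
  expect_identical(outsideCounts(tb), outsideCounts(tbRc))
})

test_that("enlarging tRNA space never increases outside counts", {
  fx <- defaultFixture()
  tb <- scanGenome(fx$genome, enumerateMatureKmers(fx$matures, 14L), fx$space)
  bigger <- GenomicRanges::reduce(GenomicRanges::resize(
    fx$space, GenomicRanges::width(fx$space) + 200L, fix = "center"))
  tbBig <- scanGenome(fx$genome, enumerateMatureKmers(fx$matures, 14L), bigger)
  expect_true(all(outsideCounts(tbBig) <= outsideCounts(tb)))
  # and an empty space turns every occurrence into an outside one
  tbNone <- scanGenome(fx$genome, enumerateMatureKmers(fx$matures, 14L), NULL)
  expect_true(all(insideCounts(tbNone) == 0L))
  expect_identical(outsideCounts(tbNone) + 0L,
                   outsideCounts(tb) + insideCounts(tb))
})
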