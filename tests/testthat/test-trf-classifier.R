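# Read dereplication, exact placement, fragment typing, ambiguity
# labeling and profile construction.

test_that("read loading dereplicates and orders by count then sequence", {
  x <- "ACGTACGTACGTACGTA"; y <- "TTTTACGTACGTACGT"
  p <- writeTempFastq(c(x, x, y))
  reads <- loadAndDereplicate(p)
  expect_identical(reads$seq, c(x, y))
  expect_identical(reads$count, c(2L, 1L))
  expect_identical(reads$length, nchar(c(x, y)))

  # FASTA accepted, multiplicity from records
  pf <- writeTempFasta(stats::setNames(c(x, y, y), c("a", "b", "c")))
  rf <- loadAndDereplicate(pf)
  expect_identical(rf$seq[1], y)
  expect_identical(rf$count, c(2L, 1L))

  pe <- tempfile(fileext = ".fq")
  writeLines(character(0), pe)
  expect_warning(r0 <- loadAndDereplicate(pe), "empty")
  expect_identical(nrow(r0), 0L)

  pm <- tempfile()
  writeLines(c("ACGT", "junk"), pm)
  expect_error(loadAndDereplicate(pm), "dialect")
})

test_that("length filter partitions conservatively at the boundary", {
  reads <- data.frame(seq = c(strrep("A", 14), strrep("C", 15), strrep("G", 16)),
                      count = c(1L, 1L, 1L),
                      length = c(14L, 15L, 16L), stringsAsFactors = FALSE)
  part <- lengthFilter(reads, minLen = 16L)
  expect_identical(part$tooShort$length, c(14L, 15L))
  expect_identical(part$pass$length, 16L)
  expect_identical(nrow(part$pass) + nrow(part$tooShort), nrow(reads))

  part15 <- lengthFilter(reads, minLen = 15L)
  expect_identical(part15$tooShort$length, 14L)
  expect_error(lengthFilter(reads, minLen = 0L), "minLen")
})

test_that("placement finds all exact forward occurrences", {
  set.seed(21)
  m1 <- paste0(randomDna(72), "CCA")
  matures <- c(t1 = m1, t2 = m1)      # two identical matures
  read <- substring(m1, 1, 18)
  pl <- placeOnMatures(read, matures)
  expect_identical(nrow(pl), 2L)
  expect_setequal(pl$trna, c("t1", "t2"))
  expect_true(all(pl$start == 1L & pl$end == 18L))

  expect_identical(nrow(placeOnMatures(strrep("T", 20), matures)), 0L)
  # overlapping occurrences are all reported
  plo <- placeOnMatures("AAA", c(t = "AAAAA"))
  expect_identical(plo$start, 1:3)
})

test_that("fragment typing follows the anticodon-window convention", {
  # mature length 75, anticodon at 35..37, window +/- 2 => [33, 39]
  cases <- list(
    list(1L, 18L, "FIVE_TRF"),
    list(1L, 36L, "FIVE_HALF"),
    list(40L, 75L, "THREE_TRF"),
    list(34L, 75L, "THREE_HALF"),
    list(20L, 50L, "I_TRF"),
    list(1L, 32L, "FIVE_TRF"),     # just outside the window
    list(1L, 33L, "FIVE_HALF"),    # window lower edge
    list(39L, 75L, "THREE_HALF"),  # window upper edge
    list(2L, 74L, "I_TRF"))        # neither terminus
  for (cs in cases) {
    expect_identical(callFragmentType(cs[[1]], cs[[2]], 75L, 35L),
                     cs[[3]], info = paste(cs[[1]], cs[[2]]))
  }
  # 3' slack lets a fragment stop short of the CCA end
  expect_identical(callFragmentType(50L, 72L, 75L, 35L, threePrimeSlack = 3L),
                   "THREE_TRF")
  expect_identical(callFragmentType(50L, 72L, 75L, 35L), "I_TRF")
})

test_that("every placement receives exactly one fragment type", {
  for (start in 1:20) {
    for (end in seq(start + 15L, 75L, by = 7L)) {
      type <- callFragmentType(start, end, 75L, 35L)
      expect_true(type %in% c("FIVE_TRF", "FIVE_HALF", "I_TRF",
                              "THREE_HALF", "THREE_TRF"))
    }
  }
})

test_that("ambiguity labels come from the genome, not tRNA space alone", {
  fx <- defaultFixture()
  feats <- truthFeatures(fx$gen$truth)
  # a read across a planted exon-exon junction: no contiguous genomic
  # copy exists, confirmed by the naive oracle
  intronic <- fx$gen$trnas[fx$gen$trnas$intronLen > 0L, ][1, ]
  junctionRead <- substring(intronic$matureSeq, 30L, 45L)   # spans pos 37|38
  expect_identical(
    unname(bruteForceCounts(fx$genome, junctionRead, fx$space)["outside"]), 0L)
  lab <- labelAmbiguity(junctionRead, fx$genome, fx$space)
  expect_identical(lab$label, "EXCLUSIVE")
  expect_identical(lab$outsideCount, 0L)

  # a read equal to a planted CCA decoy is ambiguous
  decoy <- feats[feats$kind == "CCA_DECOY", ][1, ]
  lab2 <- labelAmbiguity(decoy$seq, fx$genome, fx$space)
  expect_identical(lab2$label, "AMBIGUOUS")
  expect_gte(lab2$outsideCount, 1L)

  expect_error(labelAmbiguity(junctionRead, NULL, fx$space), "genome")
})

test_that("classifier keeps every placement and reports filter classes", {
  fx <- defaultFixture()
  m <- fx$gen$trnas$matureSeq[1]
  reads <- data.frame(
    seq = c(substring(m, 1, 18), substring(m, 20, 40), strrep("A", 14)),
    count = c(10L, 5L, 3L), stringsAsFactors = FALSE)
  reads$length <- nchar(reads$seq)
  res <- classifyReads(reads, fx$matures, fx$genome, fx$space)
  calls <- res$calls
  expect_identical(sum(calls$filtered == "TOO_SHORT"), 1L)
  expect_identical(unname(res$stats["nInput"]), 3L)
  expect_identical(unname(res$stats["nPass"] + res$stats["nTooShort"]), 3L)
  placed <- calls[!is.na(calls$trna), ]
  expect_true(all(placed$fragmentType %in%
                  c("FIVE_TRF", "FIVE_HALF", "I_TRF", "THREE_HALF", "THREE_TRF")))
  expect_true(all(placed$ambiguity %in% c("EXCLUSIVE", "AMBIGUOUS")))
  expect_true(all((placed$ambiguity == "AMBIGUOUS") ==
                  (placed$outsideCount >= 1L)))
})

test_that("profiles never collapse distinct fragment sequences", {
  set.seed(31)
  body <- randomDna(72)
  m <- c(t1 = paste0(body, "CCA"))
  g <- c(chr = paste0(randomDna(40), body, randomDna(40)))
  sp <- GenomicRanges::GRanges("chr", IRanges::IRanges(41L, 40L + 72L))
  fragA <- substring(m[[1]], 1, 18)
  fragB <- substring(m[[1]], 1, 19)   # differs by one extra nucleotide
  reads <- data.frame(seq = c(fragA, fragB), count = c(10L, 90L),
                      length = c(18L, 19L), stringsAsFactors = FALSE)
  res <- classifyReads(reads, m, g, sp)
  prof <- buildProfiles(res$calls)
  expect_identical(names(prof), "t1")
  p <- prof$t1
  expect_identical(nrow(p), 2L)
  expect_setequal(p$count, c(10L, 90L))
  expect_false(any(p$count == 100L))
  expect_identical(anyDuplicated(p$fragmentSeq), 0L)
  # no-collapse conservation: profile counts sum to placed read counts
  expect_identical(sum(p$count), 100L)
})

test_that("multi-mapping fragments appear in every matching profile", {
  set.seed(32)
  body <- randomDna(72)
  m <- stats::setNames(rep(paste0(body, "CCA"), 5), paste0("ArgTCT-", 1:5))
  g <- c(chr = paste0(randomDna(30), body, randomDna(30)))
  sp <- GenomicRanges::GRanges("chr", IRanges::IRanges(31L, 30L + 72L))
  reads <- data.frame(seq = substring(body, 1, 20), count = 7L, length = 20L,
                      stringsAsFactors = FALSE)
  res <- classifyReads(reads, m, g, sp)
  prof <- buildProfiles(res$calls)
  expect_identical(sort(names(prof)), sort(names(m)))
  expect_true(all(vapply(prof, function(p) all(p$multi), logical(1))))

  expect_identical(length(buildProfiles(res$calls[0, ])), 0L)
})
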