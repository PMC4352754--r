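test_that("sample-specific filtering discards shared variants and conserves the input", {
  v <- data.frame(
    sample = c("TAZ1", "control", "TAZ2", "TAZ1", "TAZ2"),
    chrom = c("chr1", "chr1", "chr2", "chr3", "chr2"),
    pos = c(100L, 100L, 200L, 300L, 250L),
    ref = c("A", "A", "G", "C", "T"),
    alt = c("T", "T", "C", "G", "A"),
    type = c("snv", "snv", "indel", "snv", "indel"),
    stringsAsFactors = FALSE)
  ret <- sampleSpecificVariants(v)
  ## chr1:100 A>T present in TAZ1 and control: removed from both
  expect_false(any(ret$chrom == "chr1" & ret$pos == 100L))
  ## variants unique to one sample are retained
  expect_true(any(ret$sample == "TAZ2" & ret$pos == 200L))
  expect_equal(nrow(ret), 3L)
  ## conservation: retained + discarded == input
  disc <- attr(ret, "discarded")
  expect_equal(nrow(ret) + nrow(disc), nrow(v))
  ## idempotence and order independence
  ret2 <- sampleSpecificVariants(ret)
  expect_equal(ret2[order(ret2$pos), ], ret[order(ret$pos), ],
               ignore_attr = TRUE)
  shuf <- v[sample(nrow(v)), ]
  ret3 <- sampleSpecificVariants(shuf)
  expect_equal(ret3[order(ret3$sample, ret3$pos), c("sample", "pos")],
               ret[order(ret$sample, ret$pos), c("sample", "pos")],
               ignore_attr = TRUE)
  expect_error(sampleSpecificVariants(v[v$sample == "TAZ1", ]),
               "two samples")
})

test_that("seeded synthetic clone tables filter to exact ground truth", {
  ct <- simulateCloneTables(3, 5, c(3L, 4L, 2L), supports = c(3L, 4L, 5L),
                            seed = 91)
  ret <- sampleSpecificVariants(ct$variants)
  counts <- table(ret$sample)
  expect_equal(unname(counts[paste0("clone", 1:3)]),
               c(3L, 4L, 2L), ignore_attr = TRUE)
  retKeys <- paste(ret$chrom, ret$pos, ret$ref, ret$alt, sep = ":")
  expect_setequal(retKeys, unlist(ct$truth$uniquePerSample))
  ## all variants shared -> nothing retained
  ctAll <- simulateCloneTables(3, 6, c(0L, 0L, 0L), supports = 4L, seed = 92)
  expect_equal(nrow(sampleSpecificVariants(ctAll$variants)), 0L)
})

test_that("rearrangement filtering applies the discordant-read threshold inclusively", {
  calls <- data.frame(sample = "c1",
                      type = c("deletion", "inversion", "duplication"),
                      support = c(3L, 4L, 7L), stringsAsFactors = FALSE)
  kept <- filterRearrangements(calls)
  expect_equal(kept$support, c(4L, 7L))   # support 3 dropped, 4 kept
  expect_equal(nrow(filterRearrangements(calls, minSupport = 100L)), 0L)
  mixed <- data.frame(support = c(0L, 1L, 4L, 5L, 3L, 9L))
  expect_equal(sort(filterRearrangements(mixed)$support),
               sort(mixed$support[mixed$support >= 4L]))
})

test_that("flanking homology search finds planted homologues in both orientations", {
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  L <- guideLength(g)
  set.seed(95)
  bg <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  ## plant the exact guide 30 bp downstream of the locus midpoint
  bg <- plantAt(bg, 330L, protospacer(g))
  gen <- Biostrings::DNAStringSet(c(c1 = bg))
  locus <- GenomicRanges::GRanges("c1", IRanges::IRanges(300L, width = 1L))
  hs <- flankingHomologySearch(gen, locus, g)
  pass <- hs[hs$passes, ]
  expect_true(any(pass$start == 330L & pass$strand == "+" &
                  pass$matchedBases == L))

  ## a 17/20 homologue planted on the minus strand passes with 17 matches
  pc <- strsplit(protospacer(g), "")[[1L]]
  for (p in c(2L, 9L, 16L))
    pc[L - p + 1L] <- setdiff(c("A", "C", "G", "T"), pc[L - p + 1L])[1L]
  homologue <- paste(pc, collapse = "")
  rcHom <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(homologue)))
  set.seed(96)
  bg2 <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  bg2 <- plantAt(bg2, 240L, rcHom)
  gen2 <- Biostrings::DNAStringSet(c(c1 = bg2))
  hs2 <- flankingHomologySearch(gen2, locus, g)
  pass2 <- hs2[hs2$passes & hs2$strand == "-", ]
  expect_true(any(pass2$start == 240L & pass2$matchedBases == 17L))

  ## seeded random window: no passing hit, maximum below the threshold
  set.seed(97)
  bg3 <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  gen3 <- Biostrings::DNAStringSet(c(c1 = bg3))
  hs3 <- flankingHomologySearch(gen3, locus, g)
  expect_false(any(hs3$passes))
  ## brute-force maximum over all offsets agrees
  bruteMax <- 0L
  for (st in 200:400) {
    win <- substr(bg3, st, st + L - 1L)
    rcWin <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(win)))
    bruteMax <- max(bruteMax,
                    L - oracleProfile(protospacer(g), win)$mismatches,
                    L - oracleProfile(protospacer(g), rcWin)$mismatches)
  }
  expect_equal(attr(hs3, "maxMatched"), bruteMax)
  expect_lt(bruteMax, 16L)
})

test_that("homology search is strand-symmetric under window reverse complementation", {
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  set.seed(98)
  bg <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  bg <- plantAt(bg, 310L, protospacer(g))
  gen <- Biostrings::DNAStringSet(c(c1 = bg))
  locus <- GenomicRanges::GRanges("c1", IRanges::IRanges(300L, width = 1L))
  hs <- flankingHomologySearch(gen, locus, g)

  rcgen <- Biostrings::reverseComplement(gen)
  names(rcgen) <- names(gen)
  n <- nchar(bg)
  L <- guideLength(g)
  locusRc <- GenomicRanges::GRanges("c1", IRanges::IRanges(n - 300L + 1L,
                                                           width = 1L))
  hsRc <- flankingHomologySearch(rcgen, locusRc, g)
  ## map the mirrored scores back to plus-strand coordinates: every L-mer
  ## evaluated in both searches must score identically with flipped strand
  hsRc$origStart <- n - (hsRc$start + L - 1L) + 1L
  hsRc$origStrand <- ifelse(hsRc$strand == "+", "-", "+")
  merged <- merge(hs, hsRc,
                  by.x = c("start", "strand"),
                  by.y = c("origStart", "origStrand"))
  expect_gt(nrow(merged), 300L)        # large common region
  expect_equal(merged$matchedBases.x, merged$matchedBases.y)
  ## the planted exact hit is seen from both sides
  expect_true(any(merged$start == 310L & merged$strand == "+" &
                  merged$matchedBases.x == L))
})

test_that("windows truncate at chromosome ends with notice", {
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  set.seed(99)
  gen <- randomGenomeSet(150)
  locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10L, width = 1L))
  expect_message(hs <- flankingHomologySearch(gen, locus, g), "truncated")
  expect_true(all(hs$start >= 1L))
  expect_true(all(hs$start + guideLength(g) - 1L <= 150L))
})
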