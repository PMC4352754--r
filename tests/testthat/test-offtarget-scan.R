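test_that("mismatch profiles are PAM-anchored and agree with position-wise comparison", {
  g <- GuideRna("g", "GGTACTGACTGCATTCAGGG")
  expect_equal(mismatchProfile(g, protospacer(g)),
               list(mismatches = 0L, positions = integer()))

  ## PAM-distal (5'-most) base is position L
  gA <- GuideRna("gA", strrep("A", 20))
  site <- paste0("C", strrep("A", 19))
  expect_equal(mismatchProfile(gA, site),
               list(mismatches = 1L, positions = 20L))

  ## a site mutated at PAM-anchored positions 11, 15, 19 is recovered as such
  pc <- strsplit(protospacer(g), "")[[1L]]
  for (p in c(11L, 15L, 19L)) {
    j <- 20L - p + 1L
    pc[j] <- setdiff(c("A", "C", "G", "T"), pc[j])[1L]
  }
  mutated <- paste(pc, collapse = "")
  expect_equal(mismatchProfile(g, mutated)$positions, c(11L, 15L, 19L))
  expect_equal(mismatchProfile(g, mutated), oracleProfile(protospacer(g), mutated))

  ## symmetry and zero-iff-equal, against the oracle, over random pairs
  set.seed(41)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    pab <- mismatchProfile(GuideRna("x", a), b)
    pba <- mismatchProfile(GuideRna("x", b), a)
    expect_equal(pab, pba)
    expect_equal(pab, oracleProfile(a, b))
    expect_equal(pab$mismatches == 0L, a == b)
  }
  expect_error(mismatchProfile(g, "ACGT"), "length")
})

test_that("PAM-site enumeration finds every NGG-adjacent N-free window on both strands", {
  g <- GuideRna("g", "ACGTACGTACGTACGTACGT")
  gen <- Biostrings::DNAStringSet(c(c1 = paste0(strrep("A", 20), "AGGG")))
  sites <- enumeratePamSites(gen, g)
  plus <- sites[as.character(GenomicRanges::strand(sites)) == "+"]
  expect_true(any(GenomicRanges::start(plus) == 1L &
                  S4Vectors::mcols(plus)$pamSeq == "AGG"))

  ## all-T genome: no NGG on either strand
  genT <- Biostrings::DNAStringSet(c(c1 = strrep("T", 60)))
  expect_length(enumeratePamSites(genT, g), 0L)

  ## windows containing N are excluded
  withN <- paste0(strrep("A", 10), "N", strrep("A", 9), "AGG")
  genN <- Biostrings::DNAStringSet(c(c1 = withN))
  sitesN <- enumeratePamSites(genN, g)
  expect_false(any(GenomicRanges::start(sitesN) == 1L &
                   as.character(GenomicRanges::strand(sitesN)) == "+"))

  ## exhaustive brute-force check on a random genome: every (start, strand)
  ## with a valid PAM and N-free window is enumerated, and nothing else
  set.seed(43)
  gen2 <- randomGenomeSet(600)
  sites2 <- enumeratePamSites(gen2, g)
  seqStr <- as.character(gen2[[1L]])
  expected <- list()
  for (st in 1:(600 - 19)) {
    win <- substr(seqStr, st, st + 19L)
    if (st + 22L <= 600 && substr(seqStr, st + 21L, st + 22L) == "GG")
      expected[[length(expected) + 1L]] <- c(st, "+")
    if (st - 3L >= 1L && substr(seqStr, st - 3L, st - 2L) == "CC")
      expected[[length(expected) + 1L]] <- c(st, "-")
  }
  got <- paste(GenomicRanges::start(sites2),
               as.character(GenomicRanges::strand(sites2)))
  want <- vapply(expected, paste, "", collapse = " ")
  expect_setequal(got, want)
})

test_that("planted off-target families are recovered with exact mismatch structure", {
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  sim <- simulateGenome(
    g, genomeLength = 50000,
    planted = data.frame(mismatches = 3L, copies = 5L), seed = 7)
  hits <- scanOfftargets(g, sim$genome, maxMismatch = 3)
  expect_equal(length(hits), 6L)  # on-target + 5 planted
  expect_equal(sort(S4Vectors::mcols(hits)$mismatches), c(0L, rep(3L, 5L)))
  expect_equal(hitsToDf(hits), hitsToDf(sim$truth)[order(GenomicRanges::start(sim$truth)), ],
               ignore_attr = TRUE)

  ## planted at specific PAM-anchored positions
  sim2 <- simulateGenome(
    g, genomeLength = 30000,
    planted = data.frame(mismatches = 3L, copies = 2L,
                         positions = I(list(c(11L, 15L, 19L)))),
    seed = 8)
  hits2 <- scanOfftargets(g, sim2$genome, maxMismatch = 3)
  off <- hits2[S4Vectors::mcols(hits2)$mismatches == 3L]
  for (i in seq_along(off))
    expect_equal(S4Vectors::mcols(off)$mismatchPositions[[i]], c(11L, 15L, 19L))

  ## maxMismatch = 0 finds exactly the perfect site
  h0 <- scanOfftargets(g, sim$genome, maxMismatch = 0)
  expect_equal(length(h0), 1L)
  expect_equal(S4Vectors::mcols(h0)$mismatches, 0L)
  expect_error(scanOfftargets(g, sim$genome, maxMismatch = 25), "exceeds")
})

test_that("seed-and-verify scanning equals brute force and the external matcher on random genomes", {
  set.seed(47)
  for (rep in 1:6) {
    gen <- randomGenomeSet(20000)
    guide <- randomGuide(paste0("r", rep))
    brute <- scanOfftargets(guide, gen, maxMismatch = 3, method = "brute")
    seeded <- scanOfftargets(guide, gen, maxMismatch = 3, method = "seed")
    expect_identical(as.data.frame(brute), as.data.frame(seeded))
    ## independent oracle: Biostrings mismatch matching + manual PAM filter
    expect_identical(hitsToDf(brute), oracleScan(guide, gen, 3L))
  }
  ## also with planted sites so non-empty hit sets are compared
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  sim <- simulateGenome(g, genomeLength = 30000,
                        planted = data.frame(mismatches = c(1L, 2L, 3L),
                                             copies = c(1L, 2L, 2L)),
                        seed = 17)
  brute <- scanOfftargets(g, sim$genome, maxMismatch = 3, method = "brute")
  seeded <- scanOfftargets(g, sim$genome, maxMismatch = 3, method = "seed")
  expect_identical(as.data.frame(brute), as.data.frame(seeded))
  expect_identical(hitsToDf(brute), oracleScan(g, sim$genome, 3L))
})

test_that("hits mirror under reverse complementation of the genome", {
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  sim <- simulateGenome(g, genomeLength = 30000,
                        planted = data.frame(mismatches = 3L, copies = 4L),
                        seed = 19)
  h <- scanOfftargets(g, sim$genome, 3)
  rcgen <- Biostrings::reverseComplement(sim$genome)
  names(rcgen) <- names(sim$genome)
  hrc <- scanOfftargets(g, rcgen, 3)
  n <- Biostrings::width(sim$genome)[1L]
  expect_equal(sort(n - GenomicRanges::end(h) + 1L),
               sort(GenomicRanges::start(hrc)))
  ## strand flips, mismatch structure is preserved
  expect_equal(sort(S4Vectors::mcols(h)$mismatches),
               sort(S4Vectors::mcols(hrc)$mismatches))
  expect_equal(table(as.character(GenomicRanges::strand(h)))[["+"]],
               table(as.character(GenomicRanges::strand(hrc)))[["-"]])
  dfA <- hitsToDf(h); dfB <- hitsToDf(hrc)
  dfB$start <- n - (dfB$start + guideLength(g) - 1L) + 1L
  dfB$strand <- ifelse(dfB$strand == "+", "-", "+")
  dfB <- dfB[order(dfB$chrom, dfB$start, dfB$strand), ]
  rownames(dfB) <- NULL
  expect_identical(dfA, dfB)
  ## and the PAM-anchored mismatch positions are identical per mirrored site
  key <- function(df, hits) order(df$start)
  posA <- S4Vectors::mcols(h)$mismatchPositions
  posB <- S4Vectors::mcols(hrc)$mismatchPositions
  mirroredStart <- n - GenomicRanges::end(hrc) + 1L
  mB <- match(GenomicRanges::start(h), mirroredStart)
  expect_equal(as.list(posA), as.list(posB[mB]))
})

test_that("hit sets are monotone in the mismatch budget", {
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  sim <- simulateGenome(g, genomeLength = 30000,
                        planted = data.frame(mismatches = c(1L, 2L, 3L),
                                             copies = c(2L, 2L, 2L)),
                        seed = 23)
  prev <- NULL
  for (k in 0:3) {
    hk <- hitsToDf(scanOfftargets(g, sim$genome, maxMismatch = k))
    if (!is.null(prev))
      expect_true(nrow(merge(prev, hk)) == nrow(prev))  # subset relation
    prev <- hk
  }
})

test_that("per-target off-target counting excludes the target's own locus", {
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  sim <- simulateGenome(g, genomeLength = 50000,
                        planted = data.frame(mismatches = 3L, copies = 4L),
                        seed = 29)
  counts <- countOfftargets(list(g), sim$genome, mismatches = 3L)
  expect_equal(unname(counts), 4L)

  ## explicit locus: verified, then excluded
  own <- sim$truth[S4Vectors::mcols(sim$truth)$mismatches == 0L]
  counts2 <- countOfftargets(list(g), sim$genome, mismatches = 3L, loci = own)
  expect_equal(unname(counts2), 4L)
  wrong <- GenomicRanges::shift(own, 5L)
  expect_error(countOfftargets(list(g), sim$genome, loci = wrong),
               "not found")

  ## a guide with no off-targets counts zero; two guides sharing an
  ## off-target both count it
  gIso <- GuideRna("iso", "TTACGGATCCGGAAGCTTGA")
  genIso <- Biostrings::DNAStringSet(c(
    c1 = paste0(strrep("T", 30), protospacer(gIso), "TGG", strrep("T", 30))))
  expect_equal(unname(countOfftargets(list(gIso), genIso)), 0L)

  pc <- strsplit(protospacer(g), "")[[1L]]
  for (p in c(3L, 7L)) pc[20L - p + 1L] <- setdiff(c("A", "C", "G", "T"),
                                                   pc[20L - p + 1L])[1L]
  gNear <- GuideRna("near", paste(pc, collapse = ""))  # 2 mm from g
  simShared <- simulateGenome(g, genomeLength = 40000,
                              planted = data.frame(mismatches = 3L, copies = 3L),
                              seed = 31)
  seqStr <- as.character(simShared$genome[[1L]])
  spot <- 35000L
  seqStr <- plantAt(seqStr, spot, paste0(protospacer(gNear), "CGG"))
  gen2 <- Biostrings::DNAStringSet(stats::setNames(seqStr, "chrSim"))
  hitsG <- scanOfftargets(g, gen2, 3)
  hitsNear <- scanOfftargets(gNear, gen2, 3)
  expect_true(spot %in% GenomicRanges::start(hitsG))     # 2 mm for g
  expect_true(spot %in% GenomicRanges::start(hitsNear))  # 0 mm for gNear
})
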