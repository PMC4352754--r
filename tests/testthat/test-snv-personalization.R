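## fixture: a guide, a genome with planted 3-mismatch sites, and SNVs
## constructed to correct or break specific protospacer positions
makeSite <- function(seed = 7, copies = 3L) {
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  sim <- simulateGenome(g, genomeLength = 30000,
                        planted = data.frame(mismatches = 3L, copies = copies),
                        seed = seed)
  list(g = g, sim = sim,
       hits = scanOfftargets(g, sim$genome, maxMismatch = 3))
}

snvAt <- function(chrom, pos, ref, alt, zygosity = "het", id = "s1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                         ref = ref, alt = alt, zygosity = zygosity, id = id)
}

test_that("a correcting SNV lowers the variant-allele mismatch count by one", {
  fx <- makeSite()
  site <- fx$hits[S4Vectors::mcols(fx$hits)$mismatches == 3L][1L]
  mmPos <- S4Vectors::mcols(site)$mismatchPositions[[1L]]
  p <- mmPos[1L]
  L <- guideLength(fx$g)
  j <- L - p + 1L                                       # plus-strand index
  gpos <- GenomicRanges::start(site) + j - 1L
  seqStr <- as.character(fx$sim$genome[[1L]])
  ref <- substr(seqStr, gpos, gpos)
  alt <- substr(protospacer(fx$g), j, j)                # restores the guide base
  ov <- overlaySnvs(site, fx$g, snvAt("chrSim", gpos, ref, alt), fx$sim$genome)
  expect_true(ov$valid)
  expect_equal(ov$mRef, 3L)
  expect_equal(ov$mVar, 2L)
  expect_equal(ov$snvOffsets, p)
  expect_false(p %in% ov$varPositions)
  ## recomputing the profile from the variant sequence agrees
  expect_equal(mismatchProfile(fx$g, ov$varSeq)$mismatches, ov$mVar)
})

test_that("a match-breaking SNV raises the variant mismatch count; joint SNVs cancel", {
  fx <- makeSite()
  site <- fx$hits[S4Vectors::mcols(fx$hits)$mismatches == 3L][1L]
  mmPos <- S4Vectors::mcols(site)$mismatchPositions[[1L]]
  L <- guideLength(fx$g)
  seqStr <- as.character(fx$sim$genome[[1L]])
  matchingP <- setdiff(seq_len(L), mmPos)[1L]
  jM <- L - matchingP + 1L
  gposM <- GenomicRanges::start(site) + jM - 1L
  refM <- substr(seqStr, gposM, gposM)
  altM <- setdiff(c("A", "C", "G", "T"), refM)[1L]
  ovBreak <- overlaySnvs(site, fx$g, snvAt("chrSim", gposM, refM, altM),
                         fx$sim$genome)
  expect_equal(ovBreak$mVar, ovBreak$mRef + 1L)

  ## one correcting + one breaking applied jointly: net zero, flagged multi
  p <- mmPos[1L]; jC <- L - p + 1L
  gposC <- GenomicRanges::start(site) + jC - 1L
  refC <- substr(seqStr, gposC, gposC)
  altC <- substr(protospacer(fx$g), jC, jC)
  both <- c(snvAt("chrSim", gposC, refC, altC, id = "c"),
            snvAt("chrSim", gposM, refM, altM, id = "b"))
  ovBoth <- overlaySnvs(site, fx$g, both, fx$sim$genome)
  expect_true(ovBoth$multiSnv)
  expect_equal(ovBoth$mVar, ovBoth$mRef)
  ## brute-force recomputation from the edited sequence agrees
  expect_equal(ovBoth$mVar, oracleProfile(protospacer(fx$g), ovBoth$varSeq)$mismatches)
})

test_that("an SNV whose ref disagrees with the genome flags the site invalid", {
  fx <- makeSite()
  site <- fx$hits[S4Vectors::mcols(fx$hits)$mismatches == 3L][1L]
  gpos <- GenomicRanges::start(site) + 2L
  seqStr <- as.character(fx$sim$genome[[1L]])
  trueRef <- substr(seqStr, gpos, gpos)
  wrongRef <- setdiff(c("A", "C", "G", "T"), trueRef)[1L]
  alt <- setdiff(c("A", "C", "G", "T"), c(trueRef, wrongRef))[1L]
  expect_warning(
    ov <- overlaySnvs(site, fx$g, snvAt("chrSim", gpos, wrongRef, alt),
                      fx$sim$genome),
    "inconsistent")
  expect_false(ov$valid)
})

test_that("minus-strand sites complement the SNV exactly once", {
  ## plant a 3-mismatch site on the minus strand by embedding the reverse
  ## complement of a mutated protospacer preceded by CCN
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  L <- guideLength(g)
  set.seed(53)
  bg <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  mmP <- c(5L, 9L, 14L)
  pc <- strsplit(protospacer(g), "")[[1L]]
  for (p in mmP) pc[L - p + 1L] <- setdiff(c("A", "C", "G", "T"), pc[L - p + 1L])[1L]
  mutated <- paste(pc, collapse = "")
  insert <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(mutated, "TGG"))))   # CCA + rc(protospacer)
  at <- 1001L
  bg <- plantAt(bg, at, insert)
  gen <- Biostrings::DNAStringSet(c(c1 = bg))
  hits <- scanOfftargets(g, gen, maxMismatch = 3)
  minus <- hits[as.character(GenomicRanges::strand(hits)) == "-" &
                S4Vectors::mcols(hits)$mismatches == 3L]
  expect_equal(length(minus), 1L)
  expect_equal(S4Vectors::mcols(minus)$mismatchPositions[[1L]], sort(mmP))

  ## correct the mismatch at position mmP[1]: on the minus strand the
  ## guide base must be complemented once when written into the genome
  p <- mmP[1L]
  gpos <- GenomicRanges::start(minus) + p - 1L  # window index = PAM position
  seqStr <- as.character(gen[[1L]])
  ref <- substr(seqStr, gpos, gpos)
  guideBase <- substr(protospacer(g), L - p + 1L, L - p + 1L)
  alt <- as.character(Biostrings::complement(Biostrings::DNAString(guideBase)))
  expect_true(ref != alt)
  ov <- overlaySnvs(minus, g, snvAt("c1", gpos, ref, alt), gen)
  expect_equal(ov$mRef, 3L)
  expect_equal(ov$mVar, 2L)
  expect_equal(ov$snvOffsets, p)

  ## cross-check: scanning the reverse-complemented genome with swapped
  ## coordinates yields the same conversion on the plus strand
  rcgen <- Biostrings::reverseComplement(gen)
  names(rcgen) <- names(gen)
  n <- Biostrings::width(gen)[1L]
  hitsRc <- scanOfftargets(g, rcgen, maxMismatch = 3)
  plusRc <- hitsRc[as.character(GenomicRanges::strand(hitsRc)) == "+" &
                   S4Vectors::mcols(hitsRc)$mismatches == 3L]
  expect_equal(length(plusRc), 1L)
  gposRc <- n - gpos + 1L
  refRc <- as.character(Biostrings::complement(Biostrings::DNAString(ref)))
  altRc <- guideBase
  ovRc <- overlaySnvs(plusRc, g, snvAt("c1", gposRc, refRc, altRc), rcgen)
  expect_equal(ovRc$mVar, 2L)
  expect_equal(ovRc$snvOffsets, p)
})

test_that("conversion detection returns exactly the planted events", {
  g <- GuideRna("TAZ", "GGTACTGACTGCATTCAGGG")
  sim <- simulateGenome(g, genomeLength = 50000,
                        planted = data.frame(mismatches = 3L, copies = 10L),
                        seed = 7)
  ps <- plantSnvs(sim, g, convertSites = c(3L, 7L), backgroundDensity = 1e-3,
                  seed = 11)
  hits <- scanOfftargets(g, sim$genome, 3)
  off <- hits[S4Vectors::mcols(hits)$mismatches > 0L]
  ev <- detectConversions(g, off, ps$snvs, sim$genome)
  expect_equal(nrow(ev), 2L)
  expect_equal(sort(ev$start), sort(GenomicRanges::start(sim$truth)[c(3L, 7L)]))
  expect_equal(ev$mBefore, c(3L, 3L))
  expect_equal(ev$mAfter, c(2L, 2L))
  expect_equal(ev$zygosity, c("het", "het"))
  ## conversion events are a subset of 3-mismatch hits with SNVs at
  ## mismatching positions
  expect_true(all(ev$start %in% GenomicRanges::start(
    off[S4Vectors::mcols(off)$mismatches == 3L])))

  ## SNVs only at already-matching positions yield no event
  site <- off[S4Vectors::mcols(off)$mismatches == 3L][1L]
  mmPos <- S4Vectors::mcols(site)$mismatchPositions[[1L]]
  L <- guideLength(g)
  matchingP <- setdiff(seq_len(L), mmPos)[1L]
  j <- L - matchingP + 1L
  gpos <- GenomicRanges::start(site) + j - 1L
  seqStr <- as.character(sim$genome[[1L]])
  ref <- substr(seqStr, gpos, gpos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  ev2 <- detectConversions(g, off, snvAt("chrSim", gpos, ref, alt),
                           sim$genome)
  expect_equal(nrow(ev2), 0L)
})

test_that("the genome conversion rate counts targets, not events, with exact edge cases", {
  g1 <- GuideRna("t1", "GGTACTGACTGCATTCAGGG")
  sim1 <- simulateGenome(g1, genomeLength = 40000,
                         planted = data.frame(mismatches = 3L, copies = 5L),
                         seed = 61)
  ## no SNVs anywhere -> rate 0
  none <- genomeConversionRate(list(g1), sim1$genome,
                               GenomicRanges::GRanges())
  expect_equal(none$rate, 0)
  expect_equal(none$nTargets, 1L)
  ## every target given one converting SNV -> rate 1
  ps <- plantSnvs(sim1, g1, convertSites = 2L, backgroundDensity = 0,
                  seed = 62)
  all1 <- genomeConversionRate(list(g1), sim1$genome, ps$snvs)
  expect_equal(all1$rate, 1)
  expect_equal(all1$perTarget$n3, 5L)
  expect_error(genomeConversionRate(list(), sim1$genome, ps$snvs), "empty")
})

test_that("observed cohort conversion rates match the closed-form expectation", {
  ## each target has N3 off-targets, each independently converting with
  ## probability p; the chance a target converts is 1 - (1 - p)^N3.
  ## Simulate at the summary level and compare to the closed form.
  set.seed(67)
  p <- 0.05
  n3 <- sample(0:40, 4000, replace = TRUE)
  converted <- stats::rbinom(length(n3), n3, p) > 0L
  expected <- mean(1 - (1 - p)^n3)
  obs <- mean(converted)
  se <- sqrt(expected * (1 - expected) / length(n3))
  expect_lt(abs(obs - expected), 3 * se)
})
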