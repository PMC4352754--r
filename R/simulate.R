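# Seeded synthetic-data generators with ground truth.
#
# Every generator takes an explicit seed and returns, alongside the data,
# the ground truth needed to validate the corresponding analysis module
# exactly. Genomes are built by construction-then-verification: planted
# sites are checked by a brute-force scan and the construction is resampled
# until the planted set is exactly the hit set (no accidental extra sites),
# which makes downstream oracle tests exact rather than probabilistic.

.randomDna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## mutate a protospacer at PAM-anchored positions, avoiding the original base
.mutateAtPositions <- function(proto, positions) {
  pc <- .chars(proto)
  L <- length(pc)
  for (p in positions) {
    j <- L - p + 1L                       # string index of PAM-position p
    pc[j] <- sample(setdiff(.DNA_BASES, pc[j]), 1L)
  }
  paste(pc, collapse = "")
}

#' Simulate a genome with planted on- and off-target sites
#'
#' Builds a random-background genome carrying one perfect on-target site
#' for the guide plus planted off-target families at requested mismatch
#' counts (and, optionally, at requested PAM-anchored mismatch positions),
#' each followed by a valid NGG-class PAM. Sites are placed on the plus
#' strand at non-overlapping offsets. After construction the genome is
#' verified by a brute-force [scanOfftargets()]: if the hit set at
#' `maxMismatch` differs from the planted truth (an accidental background
#' site, or a planted site matching better than intended), the genome is
#' resampled, up to `maxTries` times.
#'
#' @param guide A [GuideRna-class]. The PAM planted is the pattern with
#'   `N` positions drawn at random.
#' @param genomeLength Background length in bp (default 50000).
#' @param planted A data.frame with columns `mismatches` and `copies`, and
#'   optionally a `positions` list-column of PAM-anchored mismatch
#'   positions (sampled when absent). A perfect site (`mismatches = 0`)
#'   is always planted once in addition, as the on-target.
#' @param gc Background GC fraction (default 0.41, human-like).
#' @param seed Mandatory integer seed.
#' @param chrom Chromosome name (default `"chrSim"`).
#' @param maxMismatch Verification scan depth (default
#'   `max(planted$mismatches)`).
#' @param maxTries Construction attempts before giving up (default 20).
#' @return A list: `genome` (named `DNAStringSet`) and `truth`, a
#'   `GRanges` of all planted sites (on-target first) with metadata
#'   columns `mismatches`, `mismatchPositions` (`IntegerList`),
#'   `protospacerSeq`, `pamSeq`.
#' @export
simulateGenome <- function(guide, genomeLength = 50000L,
                           planted = data.frame(mismatches = 3L, copies = 5L),
                           gc = 0.41, seed, chrom = "chrSim",
                           maxMismatch = NULL, maxTries = 20L) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  L <- guideLength(guide)
  pamLen <- nchar(pamPattern(guide))
  siteLen <- L + pamLen
  copies <- c(1L, planted$copies)             # on-target + families
  mmSpec <- c(0L, planted$mismatches)
  posSpec <- c(list(integer()),
               if ("positions" %in% names(planted)) planted$positions
               else rep(list(NULL), nrow(planted)))
  nSites <- sum(copies)
  if (genomeLength < 10L * siteLen * nSites)
    stop("genomeLength too small for the requested planted sites")
  expandPam <- function() {
    pc <- .chars(pamPattern(guide))
    vapply(pc, function(ch) {
      allowed <- .chars(Biostrings::IUPAC_CODE_MAP[[ch]])
      if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    }, "") |> paste(collapse = "")
  }
  mm <- if (is.null(maxMismatch)) max(mmSpec) else as.integer(maxMismatch)

  for (try in seq_len(maxTries)) {
    bg <- .randomDna(genomeLength, gc = gc)
    ## non-overlapping slots, 1-bp guard on each side
    slotStarts <- sort(sample.int(genomeLength - siteLen - 2L, nSites * 4L))
    slotStarts <- slotStarts[c(TRUE, diff(slotStarts) > siteLen + 2L)]
    if (length(slotStarts) < nSites) next
    slotStarts <- sort(sample(slotStarts, nSites))
    chars <- .chars(bg)
    truthRows <- list()
    k <- 0L
    for (fam in seq_along(copies)) {
      for (cp in seq_len(copies[fam])) {
        k <- k + 1L
        m <- mmSpec[fam]
        pos <- if (is.null(posSpec[[fam]]))
          sort(sample.int(L, m)) else sort(as.integer(posSpec[[fam]]))
        if (length(pos) != m) stop("positions length must equal mismatches")
        proto <- .mutateAtPositions(protospacer(guide), pos)
        pam <- expandPam()
        st <- slotStarts[k]
        chars[st:(st + siteLen - 1L)] <- .chars(paste0(proto, pam))
        truthRows[[k]] <- list(start = st, mismatches = m, positions = pos,
                               proto = proto, pam = pam)
      }
    }
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(chars, collapse = ""), chrom))
    truth <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(vapply(truthRows, `[[`, 0, "start"), width = L),
      strand = "+",
      mismatches = vapply(truthRows, function(x) as.integer(x$mismatches), 0L),
      mismatchPositions = IRanges::IntegerList(
        lapply(truthRows, `[[`, "positions")),
      protospacerSeq = vapply(truthRows, `[[`, "", "proto"),
      pamSeq = vapply(truthRows, `[[`, "", "pam"))
    ## verification: brute-force scan must recover exactly the planted set
    hits <- scanOfftargets(guide, genome, maxMismatch = mm,
                           method = "brute")
    truthSorted <- .sortHits(truth)
    if (length(hits) == length(truthSorted) &&
        all(GenomicRanges::start(hits) == GenomicRanges::start(truthSorted)) &&
        all(as.character(GenomicRanges::strand(hits)) ==
            as.character(GenomicRanges::strand(truthSorted))) &&
        all(S4Vectors::mcols(hits)$mismatches ==
            S4Vectors::mcols(truthSorted)$mismatches) &&
        identical(as.list(S4Vectors::mcols(hits)$mismatchPositions),
                  as.list(S4Vectors::mcols(truthSorted)$mismatchPositions))) {
      return(list(genome = genome, truth = truth))
    }
  }
  stop("could not construct a verified genome in ", maxTries, " attempts")
}

#' Plant SNVs on a simulated genome
#'
#' Places "converting" SNVs at mismatching positions of chosen planted
#' three-mismatch sites (the variant base restores the guide base, so the
#' variant allele drops to two mismatches) plus background SNVs at a given
#' density, which avoid all planted protospacer+PAM footprints.
#'
#' @param sim Result of [simulateGenome()].
#' @param guide The guide used to build `sim`.
#' @param convertSites Integer indices into the planted truth (rows with 3
#'   mismatches) that receive a converting SNV.
#' @param backgroundDensity Background SNV density per bp (default 1e-3,
#'   a human-like heterozygosity scale).
#' @param zygosity Zygosity recorded for converting SNVs (default
#'   `"het"`).
#' @param seed Mandatory integer seed.
#' @return A list: `snvs` (`GRanges` with `ref`, `alt`, `zygosity`, `id`),
#'   and `truth`, a data.frame of the converting SNVs (siteIndex, chrom,
#'   pos, ref, alt, pamPosition).
#' @export
plantSnvs <- function(sim, guide, convertSites = integer(),
                      backgroundDensity = 1e-3, zygosity = "het", seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  genome <- sim$genome
  truth <- sim$truth
  L <- guideLength(guide)
  pamLen <- nchar(pamPattern(guide))
  chrom <- names(genome)[1L]
  chars <- .chars(as.character(genome[[1L]]))
  rows <- list()
  for (idx in convertSites) {
    site <- truth[idx]
    m <- S4Vectors::mcols(site)$mismatches
    pos <- S4Vectors::mcols(site)$mismatchPositions[[1L]]
    if (m == 0L || length(pos) == 0L)
      stop("site ", idx, " has no mismatch to correct")
    p <- sample(pos, 1L)                     # PAM-anchored position
    j <- L - p + 1L                          # plus-strand string index
    gpos <- GenomicRanges::start(site) + j - 1L
    ref <- chars[gpos]
    alt <- .chars(protospacer(guide))[j]     # restore the guide base
    stopifnot(ref != alt)
    rows[[length(rows) + 1L]] <- data.frame(
      siteIndex = idx, chrom = chrom, pos = gpos, ref = ref, alt = alt,
      pamPosition = p, stringsAsFactors = FALSE)
  }
  convTruth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(siteIndex = integer(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), pamPosition = integer(),
               stringsAsFactors = FALSE)
  ## background SNVs avoid all planted footprints (protospacer + PAM)
  nBg <- stats::rpois(1L, backgroundDensity * length(chars))
  forbid <- unique(unlist(lapply(seq_along(truth), function(i)
    seq.int(GenomicRanges::start(truth)[i],
            GenomicRanges::end(truth)[i] + pamLen))))
  avail <- setdiff(which(chars != "N"), c(forbid, convTruth$pos))
  bgPos <- if (nBg > 0L && length(avail) > 0L)
    sort(sample(avail, min(nBg, length(avail)))) else integer()
  bgRef <- chars[bgPos]
  bgAlt <- vapply(bgRef, function(b) sample(setdiff(.DNA_BASES, b), 1L), "")
  allPos <- c(convTruth$pos, bgPos)
  allRef <- c(convTruth$ref, bgRef)
  allAlt <- c(convTruth$alt, unname(bgAlt))
  allZyg <- c(rep(zygosity, nrow(convTruth)),
              sample(c("het", "hom"), length(bgPos), replace = TRUE,
                     prob = c(2 / 3, 1 / 3)))
  allId <- c(sprintf("conv%d", seq_len(nrow(convTruth))),
             sprintf("bg%d", seq_along(bgPos)))
  o <- order(allPos)
  snvs <- GenomicRanges::GRanges(
    rep(chrom, length(allPos)), IRanges::IRanges(allPos[o], width = 1L),
    ref = allRef[o], alt = allAlt[o], zygosity = allZyg[o], id = allId[o])
  list(snvs = snvs, truth = convTruth)
}

#' Simulate amplicon deep-sequencing reads
#'
#' Draws reads per allele at the requested ratio; the configured fraction
#' of each allele's reads receives an indel overlapping the cut junction
#' (deletions of 1-10 bp and insertions of 1-3 bp at an 80/20 ratio by
#' default, matching the short-deletion footprint of NHEJ repair).
#' Uniform substitution errors are then applied. Reads span the whole
#' amplicon unless `readLength` is set, in which case read placement is
#' constrained to cover the cut window and the discriminating SNV.
#'
#' @param amplicon An [Amplicon-class].
#' @param nReads Total read count.
#' @param indelFraction Named numeric: per-allele indel fractions. With a
#'   discriminating SNV use `c(ref = ..., var = ...)`; otherwise a single
#'   unnamed value.
#' @param alleleFractions Named numeric summing to 1 (default 50/50 when
#'   the amplicon has an SNV, all-ref otherwise).
#' @param delLengths,insLengths Integer ranges of indel sizes (defaults
#'   1:10 and 1:3).
#' @param delProb Probability that an indel is a deletion (default 0.8).
#' @param errorRate Per-base substitution error rate (default 0.002).
#' @param readLength Read length (default: full amplicon length).
#' @param seed Mandatory integer seed.
#' @return A list: `reads` (`DNAStringSet`) and `truth`, a data.frame per
#'   read (`id`, `allele`, `hasIndel`, `indelType`, `indelLength`).
#' @export
simulateAmpliconReads <- function(amplicon, nReads,
                                  indelFraction,
                                  alleleFractions = NULL,
                                  delLengths = 1:10, insLengths = 1:3,
                                  delProb = 0.8, errorRate = 0.002,
                                  readLength = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  ampSeq <- ampliconSeq(amplicon)
  ampLen <- nchar(ampSeq)
  cut <- cutOffset(amplicon)
  hasSnv <- !is.na(snvOffset(amplicon))
  if (is.null(alleleFractions))
    alleleFractions <- if (hasSnv) c(ref = 0.5, var = 0.5) else c(ref = 1)
  if (is.null(names(indelFraction))) {
    if (length(indelFraction) == 1L)
      indelFraction <- stats::setNames(rep(indelFraction,
                                           length(alleleFractions)),
                                       names(alleleFractions))
    else
      names(indelFraction) <- names(alleleFractions)[seq_along(indelFraction)]
  }
  if (!all(names(alleleFractions) %in% names(indelFraction)))
    stop("indelFraction must name every allele in alleleFractions")
  if (is.null(readLength)) readLength <- ampLen
  if (readLength > ampLen) stop("readLength exceeds amplicon length")
  if (nReads == 0L)
    return(list(reads = Biostrings::DNAStringSet(),
                truth = data.frame(id = character(), allele = character(),
                                   hasIndel = logical(),
                                   indelType = character(),
                                   indelLength = integer(),
                                   stringsAsFactors = FALSE)))
  alleleSeqs <- list(ref = ampSeq)
  if (hasSnv) {
    vc <- .chars(ampSeq)
    vc[snvOffset(amplicon)] <- amplicon@snvAlt
    alleleSeqs$var <- paste(vc, collapse = "")
  }
  alleles <- sample(names(alleleFractions), nReads, replace = TRUE,
                    prob = alleleFractions)
  ## plant the programmed fraction exactly: round(f * n) reads of each
  ## allele carry an indel (random placement); the realised per-allele
  ## fraction then equals the requested one up to rounding, so truth-based
  ## oracle checks are exact rather than binomially noisy
  hasIndel <- logical(nReads)
  for (a in names(alleleFractions)) {
    idx <- which(alleles == a)
    k <- round(indelFraction[[a]] * length(idx))
    if (k > 0L) hasIndel[sample(idx, k)] <- TRUE
  }
  reads <- character(nReads)
  indelType <- rep(NA_character_, nReads)
  indelLength <- rep(NA_integer_, nReads)
  for (i in seq_len(nReads)) {
    base <- alleleSeqs[[alleles[i]]]
    if (hasIndel[i]) {
      if (stats::runif(1L) < delProb) {
        d <- sample(delLengths, 1L)
        ## deletion overlapping the cut junction (between cut and cut + 1)
        st <- sample(max(1L, cut - d + 1L):min(cut + 1L, nchar(base) - d + 1L), 1L)
        base <- paste0(substr(base, 1L, st - 1L),
                       substr(base, st + d, nchar(base)))
        indelType[i] <- "del"; indelLength[i] <- d
      } else {
        d <- sample(insLengths, 1L)
        ins <- paste(sample(.DNA_BASES, d, replace = TRUE), collapse = "")
        at <- cut + sample(-2L:2L, 1L)      # insert near the junction
        at <- min(max(at, 1L), nchar(base))
        base <- paste0(substr(base, 1L, at), ins,
                       substr(base, at + 1L, nchar(base)))
        indelType[i] <- "ins"; indelLength[i] <- d
      }
    }
    if (readLength < nchar(base)) {
      ## keep the cut window and the SNV inside the read
      mustLo <- min(cut - 12L, if (hasSnv) snvOffset(amplicon) else cut)
      mustHi <- max(cut + 12L, if (hasSnv) snvOffset(amplicon) else cut)
      loMin <- max(1L, mustHi - readLength + 1L)
      loMax <- min(mustLo, nchar(base) - readLength + 1L)
      if (loMax < loMin) stop("readLength too short to cover cut window and SNV")
      st <- sample(loMin:loMax, 1L)
      base <- substr(base, st, st + readLength - 1L)
    }
    nErr <- stats::rbinom(1L, nchar(base), errorRate)
    if (nErr > 0L) {
      bc <- .chars(base)
      at <- sample.int(length(bc), nErr)
      bc[at] <- vapply(bc[at], function(b)
        sample(setdiff(.DNA_BASES, b), 1L), "")
      base <- paste(bc, collapse = "")
    }
    reads[i] <- base
  }
  ids <- sprintf("read%06d", seq_len(nReads))
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- ids
  list(reads = out,
       truth = data.frame(id = ids, allele = alleles,
                          hasIndel = hasIndel, indelType = indelType,
                          indelLength = indelLength,
                          stringsAsFactors = FALSE))
}

#' Simulate multi-sample variant tables and rearrangement calls
#'
#' Builds per-clone variant tables with a configurable number of shared
#' variants (each present in at least two samples) and sample-unique
#' variants, plus rearrangement calls with the requested discordant-read
#' supports.
#'
#' @param nSamples Number of samples (>= 2).
#' @param nShared Number of shared variants.
#' @param nUnique Integer vector (length `nSamples`) of unique variants
#'   per sample.
#' @param supports Integer vector of rearrangement supports (one call per
#'   element, assigned to samples round-robin).
#' @param chrom Chromosome name used for all variants.
#' @param chromLength Coordinate space for variant positions.
#' @param indelFractionUnique Fraction of unique variants that are indels
#'   (default 0.5); shared variants are SNVs.
#' @param seed Mandatory integer seed.
#' @return A list: `variants` (data.frame sample/chrom/pos/ref/alt/type),
#'   `rearrangements` (data.frame sample/type/chromA/posA/chromB/posB/
#'   support) and `truth` (list with `sharedKeys`, `uniquePerSample`).
#' @export
simulateCloneTables <- function(nSamples = 3L, nShared = 5L,
                                nUnique = c(3L, 4L, 2L),
                                supports = c(3L, 4L, 5L),
                                chrom = "chrSim", chromLength = 1000000L,
                                indelFractionUnique = 0.5, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (nSamples < 2L) stop("need at least two samples")
  if (length(nUnique) != nSamples)
    stop("nUnique must have one entry per sample")
  set.seed(seed)
  samples <- sprintf("clone%d", seq_len(nSamples))
  nVar <- nShared + sum(nUnique)
  pos <- sort(sample.int(chromLength, nVar))
  ref <- sample(.DNA_BASES, nVar, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.DNA_BASES, b), 1L), "")
  rows <- list()
  k <- 0L
  sharedKeys <- character()
  for (i in seq_len(nShared)) {
    k <- k + 1L
    carriers <- sample(samples, sample(2:nSamples, 1L))
    sharedKeys <- c(sharedKeys, paste(chrom, pos[k], ref[k], alt[k], sep = ":"))
    for (s in carriers)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, chrom = chrom, pos = pos[k], ref = ref[k],
        alt = unname(alt[k]), type = "snv", stringsAsFactors = FALSE)
  }
  uniquePerSample <- stats::setNames(vector("list", nSamples), samples)
  for (si in seq_len(nSamples)) {
    keys <- character()
    for (i in seq_len(nUnique[si])) {
      k <- k + 1L
      type <- if (stats::runif(1L) < indelFractionUnique) "indel" else "snv"
      a <- if (type == "indel") paste0(ref[k], "A") else unname(alt[k])
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples[si], chrom = chrom, pos = pos[k], ref = ref[k],
        alt = a, type = type, stringsAsFactors = FALSE)
      keys <- c(keys, paste(chrom, pos[k], ref[k], a, sep = ":"))
    }
    uniquePerSample[[si]] <- keys
  }
  variants <- do.call(rbind, rows)
  rearr <- data.frame(
    sample = rep(samples, length.out = length(supports)),
    type = sample(c("deletion", "duplication", "inversion", "translocation"),
                  length(supports), replace = TRUE),
    chromA = chrom,
    posA = sample.int(chromLength, length(supports)),
    chromB = chrom,
    posB = sample.int(chromLength, length(supports)),
    support = as.integer(supports), stringsAsFactors = FALSE)
  list(variants = variants, rearrangements = rearr,
       truth = list(sharedKeys = sharedKeys,
                    uniquePerSample = uniquePerSample))
}
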