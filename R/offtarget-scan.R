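# Genome-wide PAM-constrained off-target scanning.
#
# Two scanners are provided and must agree exactly: a brute-force scanner
# that evaluates every PAM-adjacent window position by position, and a
# pigeonhole seed-and-verify scanner that splits the protospacer into
# maxMismatch + 1 exact seeds (any site with <= maxMismatch mismatches must
# match at least one seed exactly) and verifies the candidates.
#
# Mismatch positions are PAM-anchored: position 1 is the protospacer base
# adjacent to the PAM, position L the most PAM-distal base.

#' Mismatch profile between a guide and a candidate site
#'
#' Compares the guide protospacer with a site sequence of the same length
#' (both 5'->3' on the guide-matching strand) and reports the number of
#' mismatched bases together with their PAM-anchored positions: position 1
#' is adjacent to the PAM, position L (the protospacer length) is the
#' PAM-distal 5' end.
#'
#' @param guide A [GuideRna-class] (or a plain protospacer string).
#' @param siteSeq Site sequence, same length as the protospacer, A/C/G/T.
#' @return A list with elements `mismatches` (integer) and `positions`
#'   (sorted integer vector of PAM-anchored mismatch positions).
#' @examples
#' g <- GuideRna("g", "ACGTACGTACGTACGTACGT")
#' mismatchProfile(g, "ACGTACGTACGTACGTACGT")$mismatches  # 0
#' @export
mismatchProfile <- function(guide, siteSeq) {
  gseq <- if (methods::is(guide, "GuideRna")) protospacer(guide) else
    toupper(guide)
  siteSeq <- toupper(siteSeq)
  L <- nchar(gseq)
  if (nchar(siteSeq) != L)
    stop("site sequence length (", nchar(siteSeq),
         ") differs from protospacer length (", L, ")")
  .assertBases(gseq, "protospacer")
  .assertBases(siteSeq, "site sequence")
  gc <- .chars(gseq); sc <- .chars(siteSeq)
  idx <- which(gc != sc)                # 5'->3' string index
  positions <- sort(L - idx + 1L)       # PAM-anchored: 1 = PAM-proximal
  list(mismatches = length(idx), positions = positions)
}

## Candidate PAM-adjacent windows on one chromosome, one strand.
## Returns protospacer start positions in plus-strand coordinates.
.pamWindowStarts <- function(chromSeq, pam, L, strand) {
  w <- nchar(pam)
  n <- length(chromSeq)
  if (n < L + w) return(integer())
  if (strand == "+") {
    ## PAM 3' of the protospacer: PAM start p => protospacer [p - L, p - 1]
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pam), chromSeq,
                                     fixed = FALSE)
    starts <- BiocGenerics::start(hits) - L
    starts[starts >= 1L]
  } else {
    ## Reverse-complement PAM 5' of the plus-strand window:
    ## rc(PAM) start q => protospacer window [q + w, q + w + L - 1]
    rcpam <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pam)))
    hits <- Biostrings::matchPattern(Biostrings::DNAString(rcpam), chromSeq,
                                     fixed = FALSE)
    starts <- BiocGenerics::start(hits) + w
    starts[starts + L - 1L <= n]
  }
}

## Build the hit GRanges for verified candidate starts on one chromosome.
## protStarts are plus-strand protospacer window starts; sequences are
## re-oriented 5'->3' on the guide-matching strand before comparison.
.evaluateWindows <- function(chrom, chromSeq, protStarts, guide, strand,
                             maxMismatch, requirePamCheck = FALSE) {
  L <- guideLength(guide)
  w <- nchar(pamPattern(guide))
  if (length(protStarts) == 0L) return(.emptyHits())
  protStarts <- sort(unique(protStarts))
  pamStarts <- if (strand == "+") protStarts + L else protStarts - w
  ok <- pamStarts >= 1L & pamStarts + w - 1L <= length(chromSeq) &
    protStarts >= 1L & protStarts + L - 1L <= length(chromSeq)
  protStarts <- protStarts[ok]; pamStarts <- pamStarts[ok]
  if (length(protStarts) == 0L) return(.emptyHits())

  protSet <- Biostrings::extractAt(
    chromSeq, IRanges::IRanges(protStarts, width = L))
  pamSet <- Biostrings::extractAt(
    chromSeq, IRanges::IRanges(pamStarts, width = w))
  ## discard candidates containing N anywhere in protospacer or PAM
  nFree <- Biostrings::letterFrequency(protSet, "N")[, 1L] == 0L &
    Biostrings::letterFrequency(pamSet, "N")[, 1L] == 0L
  protStarts <- protStarts[nFree]
  protSet <- protSet[nFree]; pamSet <- pamSet[nFree]
  if (length(protStarts) == 0L) return(.emptyHits())
  if (strand == "-") {
    protSet <- Biostrings::reverseComplement(protSet)
    pamSet <- Biostrings::reverseComplement(pamSet)
  }
  if (requirePamCheck) {
    pc <- .chars(pamPattern(guide))
    pamMat <- matrix(unlist(strsplit(as.character(pamSet), "")), ncol = w,
                     byrow = TRUE)
    okPam <- rep(TRUE, length(protStarts))
    for (j in seq_len(w))
      okPam <- okPam & .iupacMatch(rep(pc[j], nrow(pamMat)), pamMat[, j])
    protStarts <- protStarts[okPam]
    protSet <- protSet[okPam]; pamSet <- pamSet[okPam]
    if (length(protStarts) == 0L) return(.emptyHits())
  }

  ## vectorised mismatch counting over an n x L character matrix
  gc <- .chars(protospacer(guide))
  mat <- matrix(unlist(strsplit(as.character(protSet), "")),
                ncol = L, byrow = TRUE)
  mmMat <- t(t(mat) != gc)
  mm <- rowSums(mmMat)
  keep <- which(mm <= maxMismatch)
  if (length(keep) == 0L) return(.emptyHits())
  positions <- lapply(keep, function(i) sort(L - which(mmMat[i, ]) + 1L))
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(protStarts[keep], width = L), strand = strand,
    mismatches = as.integer(mm[keep]),
    mismatchPositions = IRanges::IntegerList(positions),
    protospacerSeq = as.character(protSet)[keep],
    pamSeq = as.character(pamSet)[keep])
}

.emptyHits <- function() {
  GenomicRanges::GRanges(
    mismatches = integer(),
    mismatchPositions = IRanges::IntegerList(),
    protospacerSeq = character(), pamSeq = character())
}

.sortHits <- function(gr) {
  if (length(gr) == 0L) return(gr)
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr),
             as.character(GenomicRanges::strand(gr)))
  gr[o]
}

#' Enumerate PAM-adjacent candidate sites genome-wide
#'
#' Yields every position, on both strands, where the guide's PAM pattern
#' matches immediately 3' of a protospacer-length window free of N bases.
#' The returned ranges cover the protospacer (not the PAM) in plus-strand
#' coordinates; `protospacerSeq`/`pamSeq` metadata columns carry the
#' sequences re-oriented 5'->3' on the guide-matching strand.
#'
#' @param genome A named `DNAStringSet` (see [validateGenome()]).
#' @param guide A [GuideRna-class].
#' @return A sorted `GRanges` of candidate sites.
#' @export
enumeratePamSites <- function(genome, guide) {
  genome <- validateGenome(genome)
  L <- guideLength(guide)
  pam <- pamPattern(guide)
  out <- lapply(names(genome), function(ch) {
    cs <- genome[[ch]]
    plus <- .evaluateWindows(ch, cs, .pamWindowStarts(cs, pam, L, "+"),
                             guide, "+", maxMismatch = L)
    minus <- .evaluateWindows(ch, cs, .pamWindowStarts(cs, pam, L, "-"),
                              guide, "-", maxMismatch = L)
    c(plus, minus)
  })
  .sortHits(do.call(c, out))
}

## seed partition: maxMismatch + 1 contiguous pieces covering 1..L
.seedRanges <- function(L, nSeeds) {
  sizes <- rep(L %/% nSeeds, nSeeds)
  extra <- L %% nSeeds
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  IRanges::IRanges(ends - sizes + 1L, ends)
}

.seedCandidateStarts <- function(chromSeq, orientedSeq, strand, seeds) {
  ## orientedSeq: the sequence a matching plus-strand window would carry
  ## (guide for "+", revcomp(guide) for "-"); seed ranges are in window
  ## coordinates matching orientedSeq.
  starts <- integer()
  oc <- Biostrings::DNAString(orientedSeq)
  for (k in seq_along(seeds)) {
    a <- BiocGenerics::start(seeds)[k]
    b <- BiocGenerics::end(seeds)[k]
    seed <- oc[a:b]
    hits <- Biostrings::matchPattern(seed, chromSeq, fixed = TRUE)
    starts <- c(starts, BiocGenerics::start(hits) - a + 1L)
  }
  unique(starts[starts >= 1L])
}

#' Scan a genome for off-target sites of a guide
#'
#' Finds all PAM-valid sites with at most `maxMismatch` mismatches to the
#' guide protospacer on both strands. Two interchangeable engines are
#' provided: `"brute"` evaluates every PAM-adjacent window position by
#' position; `"seed"` (default) splits the protospacer into
#' `maxMismatch + 1` exact seeds, collects seed matches and verifies each
#' candidate (pigeonhole principle: a site within the mismatch budget must
#' contain at least one exact seed). The two engines return identical hit
#' sets, ordered by (chromosome, start, strand).
#'
#' @param guide A [GuideRna-class].
#' @param genome A named `DNAStringSet`.
#' @param maxMismatch Maximum number of protospacer mismatches (default 3).
#' @param method `"seed"` or `"brute"`.
#' @return A sorted `GRanges` of hits with metadata columns `mismatches`,
#'   `mismatchPositions` (PAM-anchored, `IntegerList`), `protospacerSeq`
#'   and `pamSeq` (guide-oriented).
#' @examples
#' g <- GuideRna("g", "ACGTACGTACGTACGTACGT")
#' gen <- Biostrings::DNAStringSet(c(c1 = paste0("TT",
#'   "ACGTACGTACGTACGTACGT", "AGG", "TTTT")))
#' scanOfftargets(g, gen, maxMismatch = 0)
#' @export
scanOfftargets <- function(guide, genome, maxMismatch = 3L,
                           method = c("seed", "brute")) {
  method <- match.arg(method)
  genome <- validateGenome(genome)
  L <- guideLength(guide)
  if (maxMismatch > L)
    stop("maxMismatch (", maxMismatch, ") exceeds protospacer length (", L, ")")
  pam <- pamPattern(guide)
  if (method == "brute") {
    out <- lapply(names(genome), function(ch) {
      cs <- genome[[ch]]
      c(.evaluateWindows(ch, cs, .pamWindowStarts(cs, pam, L, "+"),
                         guide, "+", maxMismatch),
        .evaluateWindows(ch, cs, .pamWindowStarts(cs, pam, L, "-"),
                         guide, "-", maxMismatch))
    })
  } else {
    seeds <- .seedRanges(L, as.integer(maxMismatch) + 1L)
    rcGuide <- .revcomp(protospacer(guide))
    ## seed coordinates for the minus strand refer to the plus-strand window,
    ## whose matching sequence is revcomp(guide): mirror the seed ranges.
    seedsMinus <- IRanges::IRanges(L - BiocGenerics::end(seeds) + 1L,
                                   L - BiocGenerics::start(seeds) + 1L)
    out <- lapply(names(genome), function(ch) {
      cs <- genome[[ch]]
      plusStarts <- .seedCandidateStarts(cs, protospacer(guide), "+", seeds)
      minusStarts <- .seedCandidateStarts(cs, rcGuide, "-", seedsMinus)
      c(.evaluateWindows(ch, cs, plusStarts, guide, "+", maxMismatch,
                         requirePamCheck = TRUE),
        .evaluateWindows(ch, cs, minusStarts, guide, "-", maxMismatch,
                         requirePamCheck = TRUE))
    })
  }
  .sortHits(do.call(c, out))
}

#' Count off-target sites per target
#'
#' Batch wrapper over [scanOfftargets()]: for each guide, counts the sites
#' with exactly `mismatches` mismatches to the protospacer, excluding the
#' target's own locus. When `loci` is supplied (a `GRanges` parallel to
#' `guides`), the guide sequence is verified to occur at its stated locus
#' (error otherwise) and that locus is excluded; otherwise all
#' zero-mismatch hits are treated as the target's own occurrences and
#' excluded.
#'
#' @param guides A list of [GuideRna-class] objects.
#' @param genome A named `DNAStringSet`.
#' @param mismatches Number of mismatches defining an off-target (default 3,
#'   i.e. the N3 count).
#' @param loci Optional `GRanges` of the targets' own loci.
#' @return A named integer vector of off-target counts, one per guide.
#' @export
countOfftargets <- function(guides, genome, mismatches = 3L, loci = NULL) {
  genome <- validateGenome(genome)
  if (methods::is(guides, "GuideRna")) guides <- list(guides)
  counts <- vapply(seq_along(guides), function(i) {
    g <- guides[[i]]
    hits <- scanOfftargets(g, genome, maxMismatch = mismatches)
    if (!is.null(loci)) {
      own <- loci[i]
      seqAt <- extractSequence(genome, own)
      if (!identical(seqAt, protospacer(g)))
        stop("guide '", guideName(g),
             "' sequence not found at its stated locus")
      drop <- GenomicRanges::findOverlaps(hits, own, type = "equal")
      if (length(drop) > 0L) hits <- hits[-S4Vectors::queryHits(drop)]
    } else {
      hits <- hits[S4Vectors::mcols(hits)$mismatches > 0L]
    }
    sum(S4Vectors::mcols(hits)$mismatches == mismatches)
  }, integer(1L))
  names(counts) <- vapply(guides, guideName, "")
  counts
}
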