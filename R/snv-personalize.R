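# Overlay of personal SNVs onto off-target sites.
#
# An SNV falling inside the protospacer of an off-target site can either
# "correct" a mismatch (the variant base now matches the guide) or break a
# match. A conversion event is a 3-mismatch reference site whose variant
# allele reaches <= 2 mismatches, making it substantially more cuttable.
# SNVs that create or destroy PAMs are reported separately and never enter
# the headline conversion rate, which is defined purely on protospacer
# mismatch counts.

#' Overlay SNVs onto an off-target site
#'
#' Applies the SNVs that fall within a site's protospacer to build the
#' variant allele of the site and computes the mismatch profile of both
#' alleles against the guide. All SNVs on the site are applied jointly to a
#' single variant haplotype (cis phase assumed); sites carrying more than
#' one SNV are flagged `multiSnv`. SNVs overlapping the PAM are collected
#' separately (`pamSnvs`) and do not alter the protospacer alleles.
#'
#' An SNV whose `ref` base disagrees with the genome at its position marks
#' the site invalid (`valid = FALSE`); such sites are skipped by
#' [detectConversions()].
#'
#' @param hit A single-range `GRanges` hit from [scanOfftargets()] (with the
#'   `protospacerSeq` metadata column).
#' @param guide The [GuideRna-class] used for the scan.
#' @param snvs A `GRanges` of SNVs with `ref`, `alt`, `zygosity` columns
#'   (see [readVcfSnvs()]).
#' @param genome The genome the hit was found in.
#' @return A list: `site` (the hit), `refSeq`/`varSeq` (guide-oriented
#'   alleles), `mRef`/`mVar` (mismatch counts), `refPositions`/
#'   `varPositions` (PAM-anchored mismatch positions), `snvOffsets`
#'   (PAM-anchored positions of the applied SNVs), `snvIds`, `zygosity`,
#'   `pamSnvs` (`GRanges`), `multiSnv`, `valid`.
#' @export
overlaySnvs <- function(hit, guide, snvs, genome) {
  stopifnot(length(hit) == 1L)
  genome <- validateGenome(genome)
  L <- guideLength(guide)
  w <- nchar(pamPattern(guide))
  strand <- as.character(GenomicRanges::strand(hit))
  s <- GenomicRanges::start(hit); e <- GenomicRanges::end(hit)
  pamRange <- if (strand == "+")
    GenomicRanges::GRanges(GenomicRanges::seqnames(hit),
                           IRanges::IRanges(e + 1L, e + w)) else
    GenomicRanges::GRanges(GenomicRanges::seqnames(hit),
                           IRanges::IRanges(s - w, s - 1L))
  inProt <- snvs[IRanges::overlapsAny(snvs, hit, ignore.strand = TRUE)]
  inPam <- snvs[IRanges::overlapsAny(snvs, pamRange, ignore.strand = TRUE)]

  ## plus-strand window sequence of the site
  plusWindow <- extractSequence(
    genome, GenomicRanges::GRanges(GenomicRanges::seqnames(hit),
                                   IRanges::IRanges(s, e), strand = "+"))
  wc <- .chars(plusWindow)
  valid <- TRUE
  if (length(inProt) > 0L) {
    j <- GenomicRanges::start(inProt) - s + 1L   # index in plus-strand window
    refOk <- wc[j] == S4Vectors::mcols(inProt)$ref
    if (!all(refOk)) {
      warning("SNV ref allele inconsistent with genome at ",
              paste(GenomicRanges::start(inProt)[!refOk], collapse = ","),
              "; site skipped")
      valid <- FALSE
    }
    wc[j] <- S4Vectors::mcols(inProt)$alt
    ## PAM-anchored offset of each SNV within the protospacer
    snvOffsets <- if (strand == "+") L - j + 1L else j
  } else {
    snvOffsets <- integer()
  }
  varWindow <- paste(wc, collapse = "")
  refSeq <- if (strand == "+") plusWindow else .revcomp(plusWindow)
  varSeq <- if (strand == "+") varWindow else .revcomp(varWindow)
  profRef <- mismatchProfile(guide, refSeq)
  profVar <- mismatchProfile(guide, varSeq)
  zyg <- unique(S4Vectors::mcols(inProt)$zygosity)
  list(site = hit,
       refSeq = refSeq, varSeq = varSeq,
       mRef = profRef$mismatches, mVar = profVar$mismatches,
       refPositions = profRef$positions, varPositions = profVar$positions,
       snvOffsets = as.integer(snvOffsets),
       snvIds = as.character(S4Vectors::mcols(inProt)$id),
       zygosity = if (length(zyg) == 1L) zyg else
         if (length(zyg) == 0L) NA_character_ else "mixed",
       pamSnvs = inPam, multiSnv = length(inProt) > 1L,
       valid = valid)
}

#' Detect SNV-driven mismatch conversion events
#'
#' Scans a set of reference-genome off-target hits for sites where personal
#' SNVs convert the three-mismatch reference allele into a variant allele
#' with at most `threshold` mismatches (default 2), the configuration in
#' which Cas9 activity rises sharply. Only hits with exactly 3 reference
#' mismatches are considered; zygosity is carried through. Sites whose SNVs
#' touch only the PAM are excluded from events (reported via the
#' `pamOnlySites` attribute); sites with genome-inconsistent SNVs are
#' skipped and counted in the `skippedInconsistent` attribute.
#'
#' @param guide A [GuideRna-class].
#' @param hits `GRanges` of off-target hits from [scanOfftargets()].
#' @param snvs `GRanges` of SNVs.
#' @param genome The genome scanned.
#' @param threshold Maximum variant-allele mismatch count for an event
#'   (default 2).
#' @return A data.frame with one row per conversion event: `targetId`,
#'   `chrom`, `start`, `end`, `strand`, `mBefore`, `mAfter`, `snvIds`,
#'   `snvOffsets`, `zygosity`, `pamAffected`, `refSeq`, `varSeq`.
#' @export
detectConversions <- function(guide, hits, snvs, genome, threshold = 2L) {
  genome <- validateGenome(genome)
  hits3 <- hits[S4Vectors::mcols(hits)$mismatches == 3L]
  rows <- list()
  nSkipped <- 0L
  pamOnly <- 0L
  if (length(hits3) > 0L && length(snvs) > 0L) {
    cand <- which(IRanges::overlapsAny(hits3, snvs, ignore.strand = TRUE))
    for (i in cand) {
      ov <- withCallingHandlers(
        overlaySnvs(hits3[i], guide, snvs, genome),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!ov$valid) { nSkipped <- nSkipped + 1L; next }
      if (length(ov$snvOffsets) == 0L) { pamOnly <- pamOnly + 1L; next }
      if (ov$mVar <= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          targetId = guideName(guide),
          chrom = as.character(GenomicRanges::seqnames(hits3[i])),
          start = GenomicRanges::start(hits3[i]),
          end = GenomicRanges::end(hits3[i]),
          strand = as.character(GenomicRanges::strand(hits3[i])),
          mBefore = ov$mRef, mAfter = ov$mVar,
          snvIds = paste(ov$snvIds, collapse = ","),
          snvOffsets = paste(ov$snvOffsets, collapse = ","),
          zygosity = ov$zygosity,
          pamAffected = length(ov$pamSnvs) > 0L,
          refSeq = ov$refSeq, varSeq = ov$varSeq,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(targetId = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               mBefore = integer(), mAfter = integer(),
               snvIds = character(), snvOffsets = character(),
               zygosity = character(), pamAffected = logical(),
               refSeq = character(), varSeq = character(),
               stringsAsFactors = FALSE)
  attr(out, "skippedInconsistent") <- nSkipped
  attr(out, "pamOnlySites") <- pamOnly
  out
}

#' Fraction of targets acquiring an SNV-converted off-target
#'
#' For each guide, scans the genome for three-mismatch off-target sites
#' (excluding the guide's own perfect-match loci), detects conversion
#' events under the personal SNV set, and reports the fraction of guides
#' with at least one event. The numerator counts targets, not events.
#'
#' @param guides Non-empty list of [GuideRna-class] objects.
#' @param genome A named `DNAStringSet`.
#' @param snvs `GRanges` of SNVs.
#' @param maxMismatch Scan depth (default 3).
#' @param threshold Conversion threshold on the variant allele (default 2).
#' @return A list: `rate` (fraction), `converted` (numerator), `nTargets`
#'   (denominator) and `perTarget` (data.frame targetId, n3, converted).
#' @export
genomeConversionRate <- function(guides, genome, snvs, maxMismatch = 3L,
                                 threshold = 2L) {
  if (length(guides) == 0L) stop("empty target list")
  genome <- validateGenome(genome)
  per <- lapply(guides, function(g) {
    hits <- scanOfftargets(g, genome, maxMismatch = maxMismatch)
    hits <- hits[S4Vectors::mcols(hits)$mismatches > 0L]  # drop own loci
    ev <- detectConversions(g, hits, snvs, genome, threshold = threshold)
    data.frame(targetId = guideName(g),
               n3 = sum(S4Vectors::mcols(hits)$mismatches == 3L),
               converted = nrow(ev) > 0L, stringsAsFactors = FALSE)
  })
  perTarget <- do.call(rbind, per)
  list(rate = mean(perTarget$converted),
       converted = sum(perTarget$converted),
       nTargets = nrow(perTarget),
       perTarget = perTarget)
}
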