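# Clone-level off-target attribution filters.
#
# Cas9-induced double-strand breaks are repaired idiosyncratically, so a
# genuine off-target event is not expected to recur identically across
# independently derived clones. The screen therefore (i) keeps only
# variants private to a single sample, (ii) requires structural
# rearrangement calls to be supported by a minimum number of discordant
# read pairs, and (iii) asks whether a guide homologue lies within a
# flanking window of each retained indel, in either orientation.

#' Keep variants private to a single sample
#'
#' A variant (keyed by chromosome, position, ref, alt) is retained for a
#' sample iff it occurs in that sample and in no other; variants shared by
#' two or more samples are discarded from all of them (they are
#' pre-existing germline variation or recurrent calling artefacts, not
#' clone-specific Cas9 damage). The filter is undefined for a single
#' sample.
#'
#' @param variants A data.frame with columns `sample`, `chrom`, `pos`,
#'   `ref`, `alt` and optionally `type` (`"snv"`/`"indel"`).
#' @return The retained subset of `variants`, with the discarded rows
#'   attached as the `"discarded"` attribute (retained + discarded
#'   partition the input).
#' @export
sampleSpecificVariants <- function(variants) {
  req <- c("sample", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variant table needs columns: ", paste(req, collapse = ", "))
  if (length(unique(variants$sample)) < 2L)
    stop("sample-specific filtering requires at least two samples")
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = "\r")
  nSamples <- vapply(split(variants$sample, key),
                     function(s) length(unique(s)), integer(1L))
  keep <- nSamples[key] == 1L
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  disc <- variants[!keep, , drop = FALSE]
  rownames(disc) <- NULL
  attr(out, "discarded") <- disc
  out
}

#' Filter rearrangement calls on discordant-read support
#'
#' Keeps structural rearrangement calls supported by at least `minSupport`
#' discordant read pairs (including split reads), the threshold below
#' which calls are considered noise.
#'
#' @param calls A data.frame with a `support` column (and typically
#'   `sample`, `type`, breakpoint columns).
#' @param minSupport Minimum discordant-read support (default 4).
#' @return The passing subset of `calls`.
#' @export
filterRearrangements <- function(calls, minSupport = 4L) {
  if (!"support" %in% names(calls))
    stop("rearrangement table needs a 'support' column")
  out <- calls[calls$support >= minSupport, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search flanking windows for guide homologues
#'
#' Slides the guide protospacer across every offset of a window extending
#' `flank` bp either side of a locus (taken at its midpoint), on both
#' strands, scoring ungapped identity. Hits matching at least `minMatched`
#' of the L protospacer bases pass; PAM-anchored mismatch positions are
#' reported for passing hits. Windows are truncated at chromosome ends
#' (with a message).
#'
#' The default threshold of 16/20 encodes "more than 15 matching bases",
#' i.e. >75% identity for a 20-nt protospacer.
#'
#' @param genome A named `DNAStringSet`.
#' @param locus A single-range `GRanges` (e.g. an indel call); the window
#'   is centred on its midpoint.
#' @param guide A [GuideRna-class].
#' @param flank Window half-width in bp (default 100).
#' @param minMatched Minimum matched bases for a passing hit (default 16).
#' @return A data.frame with one row per window offset and strand:
#'   `start` (plus-strand coordinate of the L-mer), `strand`,
#'   `matchedBases`, `passes`, `mismatchPositions` (comma string, passing
#'   hits only). The `"maxMatched"` attribute gives the window maximum.
#' @export
flankingHomologySearch <- function(genome, locus, guide, flank = 100L,
                                   minMatched = 16L) {
  stopifnot(length(locus) == 1L)
  genome <- validateGenome(genome)
  L <- guideLength(guide)
  chrom <- as.character(GenomicRanges::seqnames(locus))
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  chromLen <- Biostrings::width(genome)[match(chrom, names(genome))]
  mid <- (GenomicRanges::start(locus) + GenomicRanges::end(locus)) %/% 2L
  if (mid < 1L || mid > chromLen)
    stop("locus midpoint (", mid, ") outside chromosome '", chrom,
         "' (length ", chromLen, ")")
  lo <- mid - flank
  hi <- mid + flank
  if (lo < 1L || hi + L - 1L > chromLen) {
    message("flankingHomologySearch: window truncated at chromosome end")
    lo <- max(1L, lo)
    hi <- min(hi, chromLen - L + 1L)
  }
  starts <- seq.int(lo, hi)
  if (length(starts) == 0L || hi < lo)
    stop("flanking window empty after truncation")
  windowSeqs <- as.character(Biostrings::extractAt(
    genome[[chrom]], IRanges::IRanges(starts, width = L)))
  gc <- .chars(protospacer(guide))
  rcgc <- .chars(.revcomp(protospacer(guide)))
  mat <- matrix(unlist(strsplit(windowSeqs, "")), ncol = L, byrow = TRUE)
  ## plus strand: window read 5'->3' equals guide orientation
  mmPlus <- t(t(mat) != gc)
  ## minus strand: the guide-matching strand is the reverse complement,
  ## so compare the plus-strand window to revcomp(guide)
  mmMinus <- t(t(mat) != rcgc)
  hasN <- rowSums(mat == "N") > 0L
  build <- function(mm, strand) {
    matched <- L - rowSums(mm)
    matched[hasN] <- 0L            # windows containing N cannot match
    passes <- matched >= minMatched
    mp <- character(length(starts))
    for (i in which(passes)) {
      idx <- which(mm[i, ])
      pos <- if (strand == "+") sort(L - idx + 1L) else sort(idx)
      mp[i] <- paste(pos, collapse = ",")
    }
    data.frame(start = starts, strand = strand,
               matchedBases = as.integer(matched), passes = passes,
               mismatchPositions = mp, stringsAsFactors = FALSE)
  }
  out <- rbind(build(mmPlus, "+"), build(mmMinus, "-"))
  attr(out, "maxMatched") <- max(out$matchedBases)
  out
}
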