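#' GuideRna: a Cas9 guide RNA and its PAM requirement
#'
#' Holds the protospacer-matching portion of a guide RNA (written 5'->3' as
#' DNA) together with the IUPAC PAM pattern required immediately 3' of a
#' genomic protospacer. The protospacer length `L` is taken from the sequence
#' (20 nt for standard S. pyogenes guides); mismatch positions throughout the
#' package are numbered 1..L starting at the PAM-proximal base.
#'
#' @slot name Identifier of the guide.
#' @slot protospacer A [Biostrings::DNAString] over A/C/G/T, length >= 10.
#' @slot pam IUPAC PAM pattern, default `"NGG"`.
#' @export
setClass("GuideRna",
         representation(name = "character",
                        protospacer = "DNAString",
                        pam = "character"))

setValidity("GuideRna", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@protospacer) < 10L)
    msg <- c(msg, "protospacer must be at least 10 nt")
  s <- as.character(object@protospacer)
  if (grepl("[^ACGT]", s))
    msg <- c(msg, "protospacer must contain only A, C, G, T")
  if (length(object@pam) != 1L || nchar(object@pam) < 1L)
    msg <- c(msg, "'pam' must be a single IUPAC string")
  else if (grepl("[^ACGTRYSWKMBDHVN]", object@pam))
    msg <- c(msg, "'pam' contains non-IUPAC characters")
  if (length(msg)) msg else TRUE
})

#' Construct a GuideRna
#'
#' @param name Guide identifier.
#' @param protospacer Protospacer-matching sequence, 5'->3', as a string or
#'   `DNAString` (A/C/G/T only, length >= 10; default guides are 20 nt).
#' @param pam IUPAC PAM pattern required 3' of the protospacer
#'   (default `"NGG"`, the S. pyogenes motif).
#' @return A [GuideRna-class] object.
#' @examples
#' g <- GuideRna("g1", "GGTACTGACTGCATTCAGGG")
#' guideLength(g)
#' @export
GuideRna <- function(name, protospacer, pam = "NGG") {
  if (is.character(protospacer))
    protospacer <- Biostrings::DNAString(toupper(protospacer))
  new("GuideRna", name = name, protospacer = protospacer,
      pam = toupper(pam))
}

#' @describeIn GuideRna Guide name accessor.
#' @param x,object A `GuideRna`.
#' @export
guideName <- function(x) x@name

#' @describeIn GuideRna Protospacer sequence as a character string.
#' @export
protospacer <- function(x) as.character(x@protospacer)

#' @describeIn GuideRna IUPAC PAM pattern.
#' @export
pamPattern <- function(x) x@pam

#' @describeIn GuideRna Protospacer length L.
#' @export
guideLength <- function(x) length(x@protospacer)

setMethod("show", "GuideRna", function(object) {
  cat("GuideRna '", object@name, "': 5'-",
      as.character(object@protospacer), "-3' + PAM ", object@pam,
      " (L = ", length(object@protospacer), ")\n", sep = "")
})

#' Amplicon: a deep-sequencing amplicon around a Cas9 cut site
#'
#' Describes an amplicon reference used to quantify Cas9 activity: its
#' sequence, the protospacer location and strand within it, the blunt-cut
#' position, and optionally an allele-discriminating SNV used to split reads
#' between the two haplotypes of a heterozygous site.
#'
#' The cut offset is defined as the amplicon position immediately 5' (in
#' amplicon coordinates) of the blunt cut, which falls between protospacer
#' positions 3 and 4 upstream of the PAM. It is derived from the protospacer
#' interval and strand unless given explicitly.
#'
#' @slot name Amplicon identifier.
#' @slot refseq Amplicon reference sequence ([Biostrings::DNAString]).
#' @slot protospacerRange [IRanges::IRanges] of the protospacer within the
#'   amplicon (1-based inclusive).
#' @slot strand `"+"` or `"-"`: strand of the protospacer relative to the
#'   amplicon reference.
#' @slot cutOffset Integer amplicon position; the cut lies between
#'   `cutOffset` and `cutOffset + 1`.
#' @slot snvOffset Integer amplicon position of the discriminating SNV, or
#'   `NA` when there is none.
#' @slot snvRef,snvAlt Reference/alternative base at `snvOffset` (amplicon
#'   strand), or `NA`.
#' @export
setClass("Amplicon",
         representation(name = "character",
                        refseq = "DNAString",
                        protospacerRange = "IRanges",
                        strand = "character",
                        cutOffset = "integer",
                        snvOffset = "integer",
                        snvRef = "character",
                        snvAlt = "character"))

setValidity("Amplicon", function(object) {
  msg <- character()
  n <- length(object@refseq)
  pr <- object@protospacerRange
  if (length(pr) != 1L)
    msg <- c(msg, "protospacerRange must contain exactly one range")
  else if (IRanges::start(pr) < 1L || IRanges::end(pr) > n)
    msg <- c(msg, "protospacer interval outside the amplicon")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (!is.na(object@cutOffset) &&
      (object@cutOffset < 1L || object@cutOffset >= n))
    msg <- c(msg, "cutOffset outside the amplicon")
  if (!is.na(object@snvOffset)) {
    if (object@snvOffset < 1L || object@snvOffset > n)
      msg <- c(msg, "snvOffset outside the amplicon")
    if (is.na(object@snvRef) || is.na(object@snvAlt) ||
        object@snvRef == object@snvAlt)
      msg <- c(msg, "snvRef and snvAlt must be distinct bases when snvOffset is set")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Amplicon
#'
#' @param name Amplicon identifier.
#' @param refseq Amplicon reference sequence (string or `DNAString`).
#' @param protospacerStart,protospacerEnd 1-based inclusive protospacer
#'   coordinates within the amplicon.
#' @param strand Strand of the protospacer relative to the amplicon
#'   (`"+"` or `"-"`).
#' @param cutOffset Optional explicit cut position (the cut lies between
#'   `cutOffset` and `cutOffset + 1`). By default it is placed between
#'   protospacer positions 3 and 4 upstream of the PAM: after
#'   `protospacerEnd - 3` on `"+"`, after `protospacerStart + 2` on `"-"`.
#' @param snvOffset,snvRef,snvAlt Optional allele-discriminating SNV:
#'   amplicon position and ref/alt bases on the amplicon strand.
#' @return An [Amplicon-class] object.
#' @examples
#' amp <- Amplicon("onT", paste(rep("ACGT", 30), collapse = ""),
#'                 41, 60, "+")
#' cutOffset(amp)  # 57: cut between positions 57 and 58
#' @export
Amplicon <- function(name, refseq, protospacerStart, protospacerEnd,
                     strand = "+", cutOffset = NULL,
                     snvOffset = NA_integer_, snvRef = NA_character_,
                     snvAlt = NA_character_) {
  if (is.character(refseq)) refseq <- Biostrings::DNAString(toupper(refseq))
  if (is.null(cutOffset)) {
    cutOffset <- if (strand == "+") protospacerEnd - 3L
                 else protospacerStart + 2L
  }
  new("Amplicon", name = name, refseq = refseq,
      protospacerRange = IRanges::IRanges(as.integer(protospacerStart),
                                          as.integer(protospacerEnd)),
      strand = strand, cutOffset = as.integer(cutOffset),
      snvOffset = as.integer(snvOffset),
      snvRef = as.character(snvRef), snvAlt = as.character(snvAlt))
}

#' @describeIn Amplicon Amplicon reference sequence as a character string.
#' @param x,object An `Amplicon`.
#' @export
ampliconSeq <- function(x) as.character(x@refseq)

#' @describeIn Amplicon The amplicon position 5' of the blunt cut.
#' @export
cutOffset <- function(x) x@cutOffset

#' @describeIn Amplicon Position of the discriminating SNV (`NA` if unset).
#' @export
snvOffset <- function(x) x@snvOffset

setMethod("show", "Amplicon", function(object) {
  cat("Amplicon '", object@name, "': ", length(object@refseq), " bp, ",
      "protospacer ", IRanges::start(object@protospacerRange), "-",
      IRanges::end(object@protospacerRange), " (", object@strand, "), ",
      "cut after ", object@cutOffset, sep = "")
  if (!is.na(object@snvOffset))
    cat(", SNV ", object@snvRef, ">", object@snvAlt,
        " at ", object@snvOffset, sep = "")
  cat("\n")
})

#' OriginRegression: a zero-intercept weighted fit of conversion fractions
#'
#' Result of regressing per-bin conversion fractions against off-target
#' counts with the intercept fixed at zero (see [fitThroughOrigin()]).
#' The slope is expressed in percent per off-target site so that it is
#' directly comparable with published regression slopes; the coefficient of
#' determination is the uncentered R^2 appropriate for through-origin fits.
#'
#' @slot slopePct Slope in percent per off-target.
#' @slot slopeSE Standard error of the slope, percent scale.
#' @slot r2 Uncentered weighted R^2.
#' @slot fitRange Numeric length-2: off-target count range used in the fit.
#' @slot bins The binned data actually fitted (data.frame).
#' @export
setClass("OriginRegression",
         representation(slopePct = "numeric", slopeSE = "numeric",
                        r2 = "numeric", fitRange = "numeric",
                        bins = "data.frame"))

setValidity("OriginRegression", function(object) {
  msg <- character()
  if (length(object@slopePct) != 1L) msg <- c(msg, "slopePct must be scalar")
  if (length(object@r2) == 1L && !is.na(object@r2) && object@r2 > 1 + 1e-12)
    msg <- c(msg, "R^2 cannot exceed 1")
  if (length(object@fitRange) != 2L) msg <- c(msg, "fitRange must have length 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn OriginRegression Slope in percent per off-target.
#' @param x,object An `OriginRegression`.
#' @export
regressionSlope <- function(x) x@slopePct

#' @describeIn OriginRegression Uncentered R^2 of the fit.
#' @export
regressionR2 <- function(x) x@r2

setMethod("show", "OriginRegression", function(object) {
  cat(sprintf("OriginRegression: slope = %.4g%% per off-target (SE %.3g), R^2 = %.4f, range [%g, %g], %d bins\n",
              object@slopePct, object@slopeSE, object@r2,
              object@fitRange[1L], object@fitRange[2L], nrow(object@bins)))
})

#' SiteEfficiency: per-site amplicon indel quantification
#'
#' Summary of Cas9 activity at one amplicon: read counts, the indel fraction
#' within the cut-site window with its Wilson 95% interval, a per-allele
#' split when a discriminating SNV is defined, and the efficiency relative
#' to an on-target site when its indel fraction is supplied.
#'
#' @slot name Amplicon name.
#' @slot nTotal,nPass,nIndel Integer read counts (all, aligned & passing,
#'   carrying a cut-site indel).
#' @slot fIndel Indel fraction among passing reads.
#' @slot ci Wilson 95% interval for `fIndel` (length-2 numeric).
#' @slot alleles Per-allele data.frame (allele, n, nIndel, fIndel, ciLower,
#'   ciUpper); zero rows when no discriminating SNV is set.
#' @slot relativeEfficiency `fIndel` divided by the on-target fraction
#'   (`NA` when not supplied).
#' @slot lowCoverage TRUE when fewer passing reads than the configured
#'   minimum were available.
#' @export
setClass("SiteEfficiency",
         representation(name = "character", nTotal = "integer",
                        nPass = "integer", nIndel = "integer",
                        fIndel = "numeric", ci = "numeric",
                        alleles = "data.frame",
                        relativeEfficiency = "numeric",
                        lowCoverage = "logical"))

setValidity("SiteEfficiency", function(object) {
  msg <- character()
  if (!is.na(object@fIndel) && (object@fIndel < 0 || object@fIndel > 1))
    msg <- c(msg, "fIndel must lie in [0, 1]")
  if (object@nIndel > object@nPass || object@nPass > object@nTotal)
    msg <- c(msg, "read counts must satisfy nIndel <= nPass <= nTotal")
  if (length(msg)) msg else TRUE
})

#' @describeIn SiteEfficiency Indel fraction among passing reads.
#' @param x,object A `SiteEfficiency`.
#' @export
indelFraction <- function(x) x@fIndel

#' @describeIn SiteEfficiency Per-allele summary table.
#' @export
alleleTable <- function(x) x@alleles

#' @describeIn SiteEfficiency On-target-normalised relative efficiency.
#' @export
relativeEfficiency <- function(x) x@relativeEfficiency

setMethod("show", "SiteEfficiency", function(object) {
  cat(sprintf("SiteEfficiency '%s': %d/%d passing reads with cut-site indels (f = %.4f, 95%% CI %.4f-%.4f)\n",
              object@name, object@nIndel, object@nPass, object@fIndel,
              object@ci[1L], object@ci[2L]))
  if (nrow(object@alleles) > 0L) {
    cat("  per-allele:\n")
    print(object@alleles, row.names = FALSE)
  }
  if (!is.na(object@relativeEfficiency))
    cat(sprintf("  relative efficiency vs on-target: %.3f\n",
                object@relativeEfficiency))
  if (object@lowCoverage)
    cat("  WARNING: low coverage (fewer passing reads than required)\n")
})

#' AuditReport: the assembled output of a specificity audit
#'
#' Produced by [runAudit()]. Bundles, per guide, the off-target hits,
#' detected SNV conversion events, the cohort conversion rate, an optional
#' through-origin regression, optional amplicon efficiencies, stage notes
#' (for skipped optional stages) and provenance.
#'
#' @slot guides List of [GuideRna-class] objects audited.
#' @slot hits Named list of hit `GRanges`, one per guide.
#' @slot conversions A data.frame of conversion events across guides.
#' @slot summaries Per-guide data.frame (targetId, n3, converted).
#' @slot rate List with elements `rate`, `converted`, `nTargets`.
#' @slot regression An [OriginRegression-class] or `NULL`.
#' @slot efficiencies Named list of [SiteEfficiency-class] or empty.
#' @slot notes Character vector of stage notes (e.g. skipped stages).
#' @slot provenance List: parameters and seed used.
#' @export
setClass("AuditReport",
         representation(guides = "list", hits = "list",
                        conversions = "data.frame", summaries = "data.frame",
                        rate = "list", regression = "ANY",
                        efficiencies = "list", notes = "character",
                        provenance = "list"))

setMethod("show", "AuditReport", function(object) {
  cat("AuditReport:", length(object@guides), "guide(s)\n")
  for (nm in names(object@hits))
    cat(sprintf("  %s: %d hit(s), %d conversion event(s)\n", nm,
                length(object@hits[[nm]]),
                sum(object@conversions$targetId == nm)))
  if (length(object@rate))
    cat(sprintf("  conversion rate: %d/%d = %.4f\n", object@rate$converted,
                object@rate$nTargets, object@rate$rate))
  if (!is.null(object@regression)) {
    cat("  ")
    show(object@regression)
  }
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
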