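# Amplicon deep-sequencing indel quantification.
#
# Cas9 activity at a site is read out as the fraction of amplicon reads
# carrying an insertion or deletion overlapping a window around the blunt
# cut position (substitutions never count: sequencing errors are
# substitution-dominated and must not inflate the estimate). When the
# amplicon carries a discriminating SNV, reads are additionally split by
# allele, which resolves allele-specific cutting at heterozygous sites.

.DEFAULT_SCORING <- list(match = 2, mismatch = -3, gapOpening = 6,
                         gapExtension = 1)

#' Align reads to an amplicon reference
#'
#' Globally aligns each read against the amplicon (read global, amplicon
#' local, affine gap penalties; defaults: match +2, mismatch -3, gap open
#' -6, gap extend -1). Reads shorter than `minLength` or with percent
#' identity below `minIdentity` over the aligned span are marked unaligned
#' and excluded from all denominators downstream.
#'
#' @param reads A `DNAStringSet` of reads.
#' @param amplicon An [Amplicon-class].
#' @param minIdentity Identity threshold on the aligned span (default 0.6).
#' @param minLength Minimum read length considered alignable (default 30).
#' @param scoring Named list overriding `match`, `mismatch`, `gapOpening`,
#'   `gapExtension`.
#' @return A list with elements `pa` (a `PairwiseAlignments` for the reads
#'   attempted), `aligned` (logical per read), `attempted` (logical per
#'   read; FALSE for length-filtered reads) and `reads`.
#' @export
alignReads <- function(reads, amplicon, minIdentity = 0.6, minLength = 30L,
                       scoring = list()) {
  sc <- utils::modifyList(.DEFAULT_SCORING, scoring)
  attempted <- Biostrings::width(reads) >= minLength
  aligned <- logical(length(reads))
  pa <- NULL
  if (any(attempted)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = sc$match, mismatch = sc$mismatch, baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      reads[attempted], amplicon@refseq, type = "global-local",
      substitutionMatrix = mat, gapOpening = sc$gapOpening,
      gapExtension = sc$gapExtension)
    identity <- Biostrings::pid(pa, type = "PID1") / 100
    aligned[attempted] <- identity >= minIdentity
  }
  list(pa = pa, aligned = aligned, attempted = attempted, reads = reads)
}

## Convert the insertion/deletion ranges reported by Biostrings for one
## alignment into amplicon (subject) coordinates. The reported ranges live
## in the gapped-pattern coordinate space: insertions are read positions,
## deletions count previously inserted read bases as well; walking the
## events in order and subtracting the running inserted length recovers
## subject coordinates. For deletions `offset` is the first deleted
## subject base; for insertions it is the subject base 5' of the
## insertion junction.
.indelEvents <- function(insR, delR, subStart) {
  starts <- c(BiocGenerics::start(insR), BiocGenerics::start(delR))
  lens <- c(BiocGenerics::width(insR), BiocGenerics::width(delR))
  types <- rep(c("ins", "del"), c(length(insR), length(delR)))
  o <- order(starts)
  cumIns <- 0L
  out <- vector("list", length(o))
  for (k in seq_along(o)) {
    i <- o[k]
    if (types[i] == "ins") {
      out[[k]] <- list(type = "ins",
                       offset = starts[i] - cumIns + subStart - 2L,
                       length = lens[i])
      cumIns <- cumIns + lens[i]
    } else {
      out[[k]] <- list(type = "del",
                       offset = starts[i] - cumIns + subStart - 1L,
                       length = lens[i])
    }
  }
  out
}

## Read position aligned over subject position `s`, given the indel events
## of .indelEvents(); NA when `s` is deleted or outside the aligned span.
.readPosAt <- function(events, subStart, subEnd, s) {
  if (s < subStart || s > subEnd) return(NA_integer_)
  pos <- s - subStart + 1L
  for (ev in events) {
    if (ev$type == "del") {
      if (s >= ev$offset && s <= ev$offset + ev$length - 1L)
        return(NA_integer_)
      if (ev$offset + ev$length - 1L < s) pos <- pos - ev$length
    } else {
      if (ev$offset < s) pos <- pos + ev$length
    }
  }
  pos
}

## does an indel overlap the cut window [wS, wE]?
.indelInWindow <- function(indel, wS, wE) {
  if (indel$type == "del") {
    indel$offset <= wE && (indel$offset + indel$length - 1L) >= wS
  } else {
    ## insertion sits in the junction after `offset`
    indel$offset >= wS - 1L && indel$offset <= wE
  }
}

#' Classify aligned reads at a cut site
#'
#' For each read, determines whether an insertion or deletion overlaps the
#' window of `window` bp either side of the amplicon's cut offset, and --
#' when the amplicon defines a discriminating SNV -- assigns the read to
#' the `ref` or `var` allele from the base aligned over the SNV position.
#' Reads whose SNV position is deleted or not covered are
#' `undetermined`.
#'
#' @param aln Result of [alignReads()].
#' @param amplicon The [Amplicon-class] aligned against.
#' @param window Half-width of the indel window around the cut (default 10).
#' @return A data.frame with one row per read: `id`, `aligned`,
#'   `hasIndel`, `nIns`, `nDel`, `allele`, `indels` (compact string
#'   `type:offset:length;...`).
#' @export
classifyReads <- function(aln, amplicon, window = 10L) {
  reads <- aln$reads
  n <- length(reads)
  ids <- if (!is.null(names(reads))) names(reads) else
    paste0("read", seq_len(n))
  out <- data.frame(id = ids, aligned = aln$aligned,
                    hasIndel = FALSE, nIns = 0L, nDel = 0L,
                    allele = NA_character_, indels = "",
                    stringsAsFactors = FALSE)
  if (is.null(aln$pa)) return(out)
  wS <- cutOffset(amplicon) - window
  wE <- cutOffset(amplicon) + window
  snvOff <- snvOffset(amplicon)
  hasSnv <- !is.na(snvOff)
  attempted <- which(aln$attempted)
  alignedIdx <- attempted[aln$aligned[attempted]]
  if (hasSnv) out$allele[alignedIdx] <- "undetermined"
  if (length(alignedIdx) == 0L) return(out)

  paPos <- match(alignedIdx, attempted)        # row in the PairwiseAlignments
  ni <- Biostrings::nindel(aln$pa)
  nIns <- Biostrings::insertion(ni)[paPos, 1L]
  nDel <- Biostrings::deletion(ni)[paPos, 1L]
  subStarts <- BiocGenerics::start(Biostrings::subject(aln$pa))[paPos]
  subEnds <- BiocGenerics::end(Biostrings::subject(aln$pa))[paPos]
  gapless <- nIns == 0L & nDel == 0L

  ## fast path: gapless alignments are colinear
  if (hasSnv && any(gapless)) {
    gi <- which(gapless)
    covered <- gi[subStarts[gi] <= snvOff & subEnds[gi] >= snvOff]
    if (length(covered) > 0L) {
      readPos <- snvOff - subStarts[covered] + 1L
      bases <- as.character(Biostrings::subseq(
        reads[alignedIdx[covered]], start = readPos, width = 1L))
      out$allele[alignedIdx[covered]] <-
        ifelse(bases == amplicon@snvRef, "ref",
               ifelse(bases == amplicon@snvAlt, "var", "undetermined"))
    }
  }

  ## slow path: convert the reported indel ranges for gapped alignments
  gapped <- which(!gapless)
  if (length(gapped) > 0L) {
    indelObj <- Biostrings::indel(aln$pa)
    insAll <- Biostrings::insertion(indelObj)
    delAll <- Biostrings::deletion(indelObj)
    for (k in seq_along(gapped)) {
      i <- alignedIdx[gapped[k]]
      j <- paPos[gapped[k]]
      events <- .indelEvents(insAll[[j]], delAll[[j]], subStarts[gapped[k]])
      inWin <- vapply(events, .indelInWindow, logical(1L), wS, wE)
      out$hasIndel[i] <- any(inWin)
      out$nIns[i] <- sum(vapply(events, function(x)
        x$type == "ins", logical(1L)))
      out$nDel[i] <- sum(vapply(events, function(x)
        x$type == "del", logical(1L)))
      out$indels[i] <- paste(vapply(events, function(x)
        sprintf("%s:%d:%d", x$type, x$offset, x$length), ""),
        collapse = ";")
      if (hasSnv) {
        rp <- .readPosAt(events, subStarts[gapped[k]], subEnds[gapped[k]],
                         snvOff)
        if (!is.na(rp) && rp >= 1L && rp <= Biostrings::width(reads)[i]) {
          base <- as.character(Biostrings::subseq(reads[[i]], rp, rp))
          out$allele[i] <- if (base == amplicon@snvRef) "ref"
            else if (base == amplicon@snvAlt) "var"
            else "undetermined"
        }
      }
    }
  }
  out
}

#' Quantify Cas9 cutting efficiency at an amplicon
#'
#' Aligns and classifies reads, then reports the cut-site indel fraction
#' with its Wilson 95% interval, a per-allele split when the amplicon
#' defines a discriminating SNV, and the efficiency relative to an
#' on-target site when `onTargetFraction` is supplied. With fewer than
#' `minReads` passing reads the report is flagged low-coverage (but still
#' computed).
#'
#' @param reads A `DNAStringSet` of amplicon reads.
#' @param amplicon An [Amplicon-class].
#' @param onTargetFraction Optional on-target indel fraction for
#'   normalisation.
#' @param minReads Minimum passing reads before the low-coverage flag is
#'   raised (default 100).
#' @param window Indel window half-width (default 10).
#' @param ... Passed to [alignReads()].
#' @return A [SiteEfficiency-class].
#' @export
siteEfficiency <- function(reads, amplicon, onTargetFraction = NULL,
                           minReads = 100L, window = 10L, ...) {
  aln <- alignReads(reads, amplicon, ...)
  calls <- classifyReads(aln, amplicon, window = window)
  pass <- calls[calls$aligned, , drop = FALSE]
  nPass <- nrow(pass)
  nIndel <- sum(pass$hasIndel)
  f <- if (nPass > 0L) nIndel / nPass else NA_real_
  ci <- .wilson(nIndel, nPass)
  alleles <- data.frame(allele = character(), n = integer(),
                        nIndel = integer(), fIndel = numeric(),
                        ciLower = numeric(), ciUpper = numeric(),
                        stringsAsFactors = FALSE)
  if (!is.na(snvOffset(amplicon)) && nPass > 0L) {
    alleles <- do.call(rbind, lapply(c("ref", "var", "undetermined"),
      function(a) {
        sub <- pass[pass$allele == a, , drop = FALSE]
        k <- sum(sub$hasIndel); m <- nrow(sub)
        w <- .wilson(k, m)
        data.frame(allele = a, n = m, nIndel = k,
                   fIndel = if (m > 0L) k / m else NA_real_,
                   ciLower = w[1L], ciUpper = w[2L],
                   stringsAsFactors = FALSE)
      }))
    rownames(alleles) <- NULL
  }
  if (nPass < minReads)
    warning("siteEfficiency('", amplicon@name, "'): only ", nPass,
            " passing read(s); report flagged low-coverage")
  methods::new("SiteEfficiency", name = amplicon@name,
               nTotal = length(reads), nPass = as.integer(nPass),
               nIndel = as.integer(nIndel), fIndel = f,
               ci = unname(ci),
               alleles = alleles,
               relativeEfficiency = if (is.null(onTargetFraction))
                 NA_real_ else f / onTargetFraction,
               lowCoverage = nPass < minReads)
}
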