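# Orchestration of the two audit workflows: the population audit
# (scan -> personalise -> cohort statistics -> optional amplicon
# efficiencies) and the clone screen (sample-specific variants ->
# rearrangement support filter -> flanking homology search).

#' Run a guide-specificity audit
#'
#' Runs the full population audit for a set of guides against a genome:
#' off-target scanning, SNV personalisation (skipped with a note when no
#' SNVs are supplied), cohort conversion statistics (binning and
#' through-origin regression when enough targets span the fit range), and
#' amplicon efficiency quantification when reads are supplied. Optional
#' stages degrade the report with a note; required stages error.
#'
#' @param genome A named `DNAStringSet` or FASTA path.
#' @param guides Non-empty list of [GuideRna-class] (or a guide TSV path).
#' @param snvs Optional `GRanges` of SNVs or VCF path.
#' @param ampliconReads Optional named list of `DNAStringSet` read sets,
#'   parallel to `amplicons`.
#' @param amplicons Optional named list of [Amplicon-class].
#' @param maxMismatch Scan depth (default 3).
#' @param threshold Conversion threshold (default 2).
#' @param binWidth,fitRange Binning/regression parameters (defaults 5 and
#'   `c(0, 100)`).
#' @param onTarget Name of the on-target amplicon within `amplicons` used
#'   for normalisation (default: first).
#' @return An [AuditReport-class].
#' @export
runAudit <- function(genome, guides, snvs = NULL, ampliconReads = NULL,
                     amplicons = NULL, maxMismatch = 3L, threshold = 2L,
                     binWidth = 5, fitRange = c(0, 100), onTarget = NULL) {
  if (is.character(genome)) genome <- readFastaGenome(genome)
  genome <- validateGenome(genome)
  if (is.character(guides)) guides <- readGuidesTsv(guides)
  if (methods::is(guides, "GuideRna")) guides <- list(guides)
  if (length(guides) == 0L) stop("empty guide list")
  if (is.character(snvs)) snvs <- readVcfSnvs(snvs)
  notes <- character()

  hits <- lapply(guides, function(g) {
    h <- scanOfftargets(g, genome, maxMismatch = maxMismatch)
    if (!any(S4Vectors::mcols(h)$mismatches == 0L))
      stop("guide '", guideName(g), "' has no perfect-match site in the genome")
    h
  })
  names(hits) <- vapply(guides, guideName, "")

  if (is.null(snvs)) {
    notes <- c(notes, "personalisation skipped: no SNVs supplied")
    conversions <- detectConversions(guides[[1L]], .emptyHits(),
                                     GenomicRanges::GRanges(), genome,
                                     threshold = threshold)
    summaries <- data.frame(
      targetId = names(hits),
      n3 = vapply(hits, function(h)
        sum(S4Vectors::mcols(h)$mismatches == 3L), 0L),
      converted = FALSE, stringsAsFactors = FALSE)
    rate <- list()
  } else {
    convList <- lapply(seq_along(guides), function(i) {
      off <- hits[[i]][S4Vectors::mcols(hits[[i]])$mismatches > 0L]
      detectConversions(guides[[i]], off, snvs, genome,
                        threshold = threshold)
    })
    conversions <- do.call(rbind, convList)
    summaries <- data.frame(
      targetId = names(hits),
      n3 = vapply(hits, function(h) {
        mc <- S4Vectors::mcols(h)
        sum(mc$mismatches == 3L)
      }, 0L),
      converted = vapply(convList, nrow, 0L) > 0L,
      stringsAsFactors = FALSE)
    rate <- list(rate = mean(summaries$converted),
                 converted = sum(summaries$converted),
                 nTargets = nrow(summaries))
  }
  rownames(summaries) <- NULL

  regression <- NULL
  if (!is.null(snvs) && nrow(summaries) >= 2L) {
    regression <- tryCatch({
      bins <- binFractions(summaries, binWidth = binWidth, range = fitRange)
      fitThroughOrigin(bins, range = fitRange)
    }, error = function(e) {
      notes <<- c(notes, paste0("regression skipped: ", conditionMessage(e)))
      NULL
    })
  } else if (!is.null(snvs)) {
    notes <- c(notes, "regression skipped: fewer than two targets")
  }

  efficiencies <- list()
  if (!is.null(ampliconReads)) {
    if (is.null(amplicons))
      stop("ampliconReads supplied without amplicon definitions")
    if (is.null(onTarget)) onTarget <- names(amplicons)[1L]
    onRep <- siteEfficiency(ampliconReads[[onTarget]], amplicons[[onTarget]])
    onF <- indelFraction(onRep)
    efficiencies <- lapply(names(amplicons), function(nm)
      siteEfficiency(ampliconReads[[nm]], amplicons[[nm]],
                     onTargetFraction = onF))
    names(efficiencies) <- names(amplicons)
  } else if (!is.null(amplicons)) {
    notes <- c(notes, "amplicon stage skipped: no reads supplied")
  }

  methods::new("AuditReport", guides = guides, hits = hits,
               conversions = conversions, summaries = summaries,
               rate = rate, regression = regression,
               efficiencies = efficiencies, notes = notes,
               provenance = list(maxMismatch = maxMismatch,
                                 threshold = threshold,
                                 binWidth = binWidth, fitRange = fitRange,
                                 nGuides = length(guides),
                                 version = as.character(
                                   utils::packageVersion("crisprAudit"))))
}

#' Run the clone-level off-target screen
#'
#' Applies the clone filters: retain variants private to one sample, keep
#' rearrangement calls with sufficient discordant-read support, and search
#' the flanking windows of each retained indel for guide homologues on
#' both strands.
#'
#' @param variants Per-clone variant data.frame (see
#'   [sampleSpecificVariants()]).
#' @param rearrangements Rearrangement data.frame with a `support` column.
#' @param genome A named `DNAStringSet`.
#' @param guide A [GuideRna-class].
#' @param flank Homology window half-width (default 100).
#' @param minMatched Homology pass threshold (default 16 of L).
#' @param minSupport Rearrangement support threshold (default 4).
#' @return A list: `retained` (data.frame), `retainedPerSample` (named
#'   integer), `passingRearrangements` (data.frame), `homology` (data.frame
#'   of passing homology hits per retained indel: sample, chrom, pos,
#'   start, strand, matchedBases).
#' @export
runCloneScreen <- function(variants, rearrangements, genome, guide,
                           flank = 100L, minMatched = 16L, minSupport = 4L) {
  genome <- validateGenome(genome)
  retained <- sampleSpecificVariants(variants)
  perSample <- table(factor(retained$sample,
                            levels = sort(unique(variants$sample))))
  passing <- filterRearrangements(rearrangements, minSupport = minSupport)
  indels <- retained[!is.na(retained$type) & retained$type == "indel", ,
                     drop = FALSE]
  homRows <- list()
  for (i in seq_len(nrow(indels))) {
    locus <- GenomicRanges::GRanges(indels$chrom[i],
                                    IRanges::IRanges(indels$pos[i],
                                                     width = 1L))
    hs <- flankingHomologySearch(genome, locus, guide, flank = flank,
                                 minMatched = minMatched)
    hsPass <- hs[hs$passes, , drop = FALSE]
    if (nrow(hsPass) > 0L)
      homRows[[length(homRows) + 1L]] <- data.frame(
        sample = indels$sample[i], chrom = indels$chrom[i],
        pos = indels$pos[i], start = hsPass$start,
        strand = hsPass$strand, matchedBases = hsPass$matchedBases,
        stringsAsFactors = FALSE)
  }
  homology <- if (length(homRows)) do.call(rbind, homRows) else
    data.frame(sample = character(), chrom = character(), pos = integer(),
               start = integer(), strand = character(),
               matchedBases = integer(), stringsAsFactors = FALSE)
  list(retained = retained,
       retainedPerSample = stats::setNames(as.integer(perSample),
                                           names(perSample)),
       passingRearrangements = passing,
       homology = homology)
}

#' Write an audit report to disk
#'
#' Serialises an [AuditReport-class] deterministically: a JSON summary
#' (schema version, per-target summaries, rate, regression, efficiencies,
#' notes) plus TSV side files of hits and conversion events. Re-running
#' the audit on identical inputs reproduces the files byte for byte.
#'
#' @param report An [AuditReport-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeAuditReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hitsDf <- do.call(rbind, lapply(names(report@hits), function(nm) {
    h <- report@hits[[nm]]
    mc <- S4Vectors::mcols(h)
    data.frame(targetId = nm,
               chrom = as.character(GenomicRanges::seqnames(h)),
               start = GenomicRanges::start(h),
               end = GenomicRanges::end(h),
               strand = as.character(GenomicRanges::strand(h)),
               mismatches = mc$mismatches,
               mismatchPositions = vapply(as.list(mc$mismatchPositions),
                                          paste, "", collapse = ","),
               protospacerSeq = mc$protospacerSeq, pamSeq = mc$pamSeq,
               stringsAsFactors = FALSE)
  }))
  hitsPath <- file.path(dir, "hits.tsv")
  utils::write.table(hitsDf, hitsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  convPath <- file.path(dir, "conversions.tsv")
  utils::write.table(report@conversions, convPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reg <- report@regression
  summary <- list(
    schema = "crisprAudit-report/1",
    summaries = report@summaries,
    rate = report@rate,
    regression = if (is.null(reg)) NULL else
      list(slopePct = regressionSlope(reg), slopeSE = reg@slopeSE,
           r2 = regressionR2(reg), fitRange = reg@fitRange),
    efficiencies = lapply(report@efficiencies, function(e)
      list(name = e@name, nPass = e@nPass, fIndel = e@fIndel,
           ci = e@ci, relativeEfficiency = e@relativeEfficiency,
           alleles = e@alleles)),
    notes = report@notes,
    provenance = report@provenance)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, dataframe = "rows")
  invisible(c(json = jsonPath, hits = hitsPath, conversions = convPath))
}
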