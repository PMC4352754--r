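## Shared fixture builders. All randomness is seeded at the call site.

randomGuide <- function(name = "g", L = 20L) {
  GuideRna(name, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = ""))
}

randomGenomeSet <- function(lengths, names = paste0("chr", seq_along(lengths)),
                            gc = 0.41) {
  seqs <- vapply(lengths, function(len)
    paste(sample(c("A", "C", "G", "T"), len,
                 replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), "")
  Biostrings::DNAStringSet(stats::setNames(seqs, names[seq_along(seqs)]))
}

## string surgery helper: replace a substring in place
plantAt <- function(seqStr, at, insert) {
  substr(seqStr, at, at + nchar(insert) - 1L) <- insert
  seqStr
}

## independent brute-force oracle for mismatch counting: position-wise
## character comparison, PAM-anchored numbering
oracleProfile <- function(guideSeq, siteSeq) {
  gc <- strsplit(guideSeq, "")[[1L]]
  sc <- strsplit(siteSeq, "")[[1L]]
  L <- length(gc)
  pos <- integer()
  for (i in seq_len(L)) if (gc[i] != sc[i]) pos <- c(pos, L - i + 1L)
  list(mismatches = length(pos), positions = sort(pos))
}

## independent scan oracle built on Biostrings max.mismatch matching plus
## an explicit PAM filter; returns a data.frame of (start, strand, mm)
oracleScan <- function(guide, genome, maxMismatch) {
  L <- guideLength(guide)
  out <- list()
  for (ch in names(genome)) {
    seqStr <- as.character(genome[[ch]])
    n <- nchar(seqStr)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") protospacer(guide) else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(protospacer(guide))))
      m <- Biostrings::matchPattern(pat, genome[[ch]],
                                    max.mismatch = maxMismatch,
                                    with.indels = FALSE)
      for (st in BiocGenerics::start(m)) {
        if (st < 1L || st + L - 1L > n) next
        win <- substr(seqStr, st, st + L - 1L)
        pamSeq <- if (strand == "+") {
          if (st + L + 2L > n) next
          substr(seqStr, st + L, st + L + 2L)
        } else {
          if (st - 3L < 1L) next
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(substr(seqStr, st - 3L, st - 1L))))
        }
        if (grepl("N", win) || grepl("N", pamSeq)) next
        ## NGG check on the guide-oriented PAM
        if (substr(pamSeq, 2L, 3L) != "GG") next
        oriented <- if (strand == "+") win else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(win)))
        mm <- sum(strsplit(oriented, "")[[1L]] !=
                  strsplit(protospacer(guide), "")[[1L]])
        if (mm <= maxMismatch)
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, start = st, strand = strand, mm = mm,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mm = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

hitsToDf <- function(hits) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(hits)),
                   start = GenomicRanges::start(hits),
                   strand = as.character(GenomicRanges::strand(hits)),
                   mm = S4Vectors::mcols(hits)$mismatches,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

## a fixed test amplicon with the guide protospacer embedded mid-sequence
testAmplicon <- function(guide, ampLen = 180L, protoStart = 81L,
                         snvOffset = NA_integer_, seed = 100L) {
  set.seed(seed)
  ampSeq <- paste(sample(c("A", "C", "G", "T"), ampLen, replace = TRUE),
                  collapse = "")
  ampSeq <- plantAt(ampSeq, protoStart,
                    paste0(protospacer(guide), "AGG"))
  if (!is.na(snvOffset)) {
    ref <- substr(ampSeq, snvOffset, snvOffset)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
    Amplicon("amp", ampSeq, protoStart,
             protoStart + guideLength(guide) - 1L, "+",
             snvOffset = snvOffset, snvRef = ref, snvAlt = alt)
  } else {
    Amplicon("amp", ampSeq, protoStart,
             protoStart + guideLength(guide) - 1L, "+")
  }
}
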