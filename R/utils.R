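# Internal helpers shared across modules.

#' @importFrom Biostrings DNAString DNAStringSet IUPAC_CODE_MAP reverseComplement
#' @importFrom methods is new validObject slot
NULL

.DNA_BASES <- c("A", "C", "G", "T")

## split a character string into single characters
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## does each site character satisfy the IUPAC pattern character?
.iupacMatch <- function(patternChars, siteChars) {
  allowed <- Biostrings::IUPAC_CODE_MAP[patternChars]
  if (anyNA(allowed))
    stop("invalid IUPAC code in PAM pattern: ",
         paste(patternChars[is.na(allowed)], collapse = ""))
  mapply(function(a, s) grepl(s, a, fixed = TRUE), allowed, siteChars,
         USE.NAMES = FALSE)
}

.assertBases <- function(x, what = "sequence", alphabet = .DNA_BASES) {
  bad <- setdiff(unique(.chars(x)), alphabet)
  if (length(bad) > 0L)
    stop(what, " contains illegal character(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

## Wilson 95% score interval for a binomial proportion
.wilson <- function(k, n, conf = 0.95) {
  if (n == 0L) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw  <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

## Parse a printed 1-based inclusive locus such as
## "chr.X: 153,647,923-153,647,944" into a GRanges.
#' Convert printed genomic loci to and from GRanges
#'
#' Published loci are conventionally printed 1-based and inclusive with
#' thousands separators (for example `"chr5: 7,924,778-7,924,799"`).
#' `parsePrintedLocus()` converts such strings into a [GenomicRanges::GRanges]
#' (which uses the same 1-based inclusive convention internally);
#' `formatPrintedLocus()` is its inverse. En dashes and a `"chr."` prefix are
#' tolerated on input.
#'
#' @param x Character vector of printed loci.
#' @param gr A `GRanges` object.
#' @return `parsePrintedLocus()` returns a `GRanges`; `formatPrintedLocus()`
#'   a character vector. The two are mutually inverse.
#' @examples
#' gr <- parsePrintedLocus("chr5: 7,924,778-7,924,799")
#' GenomicRanges::width(gr)  # 22
#' formatPrintedLocus(gr)
#' @export
parsePrintedLocus <- function(x) {
  x <- gsub(",", "", x, fixed = TRUE)
  x <- gsub("–", "-", x)                  # en dash
  x <- gsub("chr\\.", "chr", x)
  m <- regmatches(x, regexec("^\\s*([^:\\s]+)\\s*:\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("cannot parse locus: ", paste(x[bad], collapse = "; "))
  chrom <- vapply(m, `[`, "", 2L)
  start <- as.integer(vapply(m, `[`, "", 3L))
  end   <- as.integer(vapply(m, `[`, "", 4L))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

#' @rdname parsePrintedLocus
#' @export
formatPrintedLocus <- function(gr) {
  sprintf("%s: %s-%s",
          as.character(GenomicRanges::seqnames(gr)),
          formatC(GenomicRanges::start(gr), big.mark = ",", format = "d"),
          formatC(GenomicRanges::end(gr), big.mark = ",", format = "d"))
}
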