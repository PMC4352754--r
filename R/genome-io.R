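# Genome, variant and interval I/O.
#
# The genome container is a named Biostrings::DNAStringSet restricted to the
# A/C/G/T/N alphabet; all genomic intervals are GenomicRanges::GRanges and
# therefore 1-based inclusive, the convention shared by VCF and printed loci.
# BED import/export converts to/from 0-based half-open at the file boundary.

#' Read a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file into a named [Biostrings::DNAStringSet],
#' upper-casing the sequences and enforcing the A/C/G/T/N alphabet. Record
#' names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`; one element per FASTA record.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt", ">c2", "NNNN"), tf)
#' g <- readFastaGenome(tf)
#' as.character(g[["c1"]])
#' @export
readFastaGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ## the reader silently drops letters outside the DNA alphabet with a
  ## warning; promote that to an error to enforce the alphabet contract
  set <- withCallingHandlers(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("FASTA contains characters outside the DNA alphabet: ", path)
      invokeRestart("muffleWarning")
    })
  names(set) <- sub("\\s.*$", "", names(set))
  validateGenome(set)
}

#' Validate (and normalise) a genome object
#'
#' Checks that chromosome names are unique and non-empty, that every sequence
#' is non-empty, and that the alphabet is restricted to A/C/G/T/N.
#' Lower-case input is accepted and upper-cased. Called by [readFastaGenome()]
#' and usable directly on programmatically built genomes.
#'
#' @param genome A named `DNAStringSet` or a named character vector.
#' @return The validated genome as a named `DNAStringSet`.
#' @export
validateGenome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a named DNAStringSet or character vector")
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("every genome record must be named")
  if (anyDuplicated(names(genome)))
    stop("duplicate record name(s): ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  if (any(Biostrings::width(genome) == 0L))
    stop("empty sequence record(s): ",
         paste(names(genome)[Biostrings::width(genome) == 0L], collapse = ", "))
  freq <- Biostrings::alphabetFrequency(genome)
  extra <- freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"), drop = FALSE]
  if (any(rowSums(extra) > 0L)) {
    bad <- colnames(extra)[colSums(extra) > 0L]
    stop("genome contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  genome
}

#' Write a genome to FASTA
#'
#' @param genome A named `DNAStringSet` (see [validateGenome()]).
#' @param path Output file path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
writeFastaGenome <- function(genome, path, width = 70L) {
  genome <- validateGenome(genome)
  Biostrings::writeXStringSet(genome, path, format = "fasta", width = width)
  invisible(path)
}

#' Extract sequence for genomic intervals
#'
#' Returns the sequence of each interval; minus-strand intervals are
#' reverse-complemented so the result always reads 5'->3' on the requested
#' strand. Intervals with strand `"*"` are treated as `"+"`.
#'
#' @param genome A named `DNAStringSet`.
#' @param gr A `GRanges` of intervals to extract.
#' @return A character vector of sequences, one per interval.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "AAGTT"))
#' extractSequence(g, GenomicRanges::GRanges("c1:1-4:-"))  # "ACTT"
#' @export
extractSequence <- function(genome, gr) {
  genome <- validateGenome(genome)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(GenomicRanges::start(gr) < 1L) || any(GenomicRanges::end(gr) > lens))
    stop("interval out of chromosome bounds")
  out <- character(length(gr))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    views <- Biostrings::extractAt(
      genome[[ch]],
      IRanges::IRanges(GenomicRanges::start(gr)[idx],
                       GenomicRanges::end(gr)[idx]))
    seqs <- as.character(views)
    minus <- as.character(GenomicRanges::strand(gr)[idx]) == "-"
    if (any(minus))
      seqs[minus] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
    out[idx] <- seqs
  }
  out
}

#' Read single-nucleotide variants from a VCF
#'
#' Reads a VCF 4.x file and retains only biallelic single-base substitutions
#' (single-base REF and a single single-base ALT). Indels and multi-allelic
#' records are skipped and counted; the count is reported in a message and
#' attached as the `"skipped"` attribute. When a GT genotype field is present
#' it sets the zygosity (`het`/`hom`), otherwise zygosity is `unknown`.
#'
#' @param path Path to an uncompressed or bgzipped VCF file.
#' @return A `GRanges` with one range per SNV (width 1, VCF 1-based
#'   positions) and metadata columns `ref`, `alt`, `zygosity`, `id`.
#' @export
readVcfSnvs <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altL)
  alt1 <- rep(NA_character_, length(ref))
  alt1[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
  keep <- nAlt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% .DNA_BASES & alt1 %in% .DNA_BASES & ref != alt1
  nSkipped <- sum(!keep)
  if (nSkipped > 0L)
    message("readVcfSnvs: skipped ", nSkipped,
            " non-SNV (indel/multi-allelic/symbolic) record(s)")
  zyg <- rep("unknown", length(ref))
  gtMat <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
  if (!is.null(gtMat) && ncol(gtMat) >= 1L) {
    gt <- gtMat[, 1L]
    gt <- gsub("|", "/", gt, fixed = TRUE)
    zyg[gt %in% c("0/1", "1/0")] <- "het"
    zyg[gt %in% "1/1"] <- "hom"
  }
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(rr)[keep],
    IRanges::IRanges(GenomicRanges::start(rr)[keep], width = 1L),
    ref = ref[keep], alt = alt1[keep], zygosity = zyg[keep],
    id = names(rr)[keep])
  names(out) <- NULL
  attr(out, "skipped") <- nSkipped
  out
}

#' Write SNVs to a minimal VCF 4.2 file
#'
#' Emits the SNV `GRanges` produced by [readVcfSnvs()] or [plantSnvs()] as a
#' single-sample VCF with a GT genotype column derived from the `zygosity`
#' metadata column (`het` -> 0/1, `hom` -> 1/1, otherwise `./.`).
#'
#' @param snvs A `GRanges` with `ref`, `alt` and optionally `zygosity`,
#'   `id` metadata columns.
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
writeSnvVcf <- function(snvs, path, sample = "SAMPLE") {
  mc <- S4Vectors::mcols(snvs)
  zyg <- if ("zygosity" %in% names(mc)) mc$zygosity else rep("unknown", length(snvs))
  gt <- ifelse(zyg == "het", "0/1", ifelse(zyg == "hom", "1/1", "./."))
  id <- if ("id" %in% names(mc) && !all(is.na(mc$id))) {
    ifelse(is.na(mc$id) | !nzchar(mc$id), ".", mc$id)
  } else rep(".", length(snvs))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  body <- if (length(snvs) == 0L) character() else
    paste(as.character(GenomicRanges::seqnames(snvs)),
          GenomicRanges::start(snvs), id, mc$ref, mc$alt,
          ".", "PASS", ".", "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export hits or intervals as BED6
#'
#' Writes a `GRanges` to BED (0-based half-open start, as the format
#' requires). The score column carries the `mismatches` metadata column
#' when present, otherwise 0.
#'
#' @param gr A `GRanges`, e.g. the hits from [scanOfftargets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
exportBed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  score <- if ("mismatches" %in% names(mc)) mc$mismatches else rep(0L, length(gr))
  nm <- if (!is.null(names(gr)) && all(nzchar(names(gr)))) names(gr) else
    paste0("site", seq_along(gr))
  lines <- if (length(gr) == 0L) character() else
    paste(as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L,  # BED is 0-based half-open
          GenomicRanges::end(gr), nm, score,
          as.character(GenomicRanges::strand(gr)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Import a BED file as GRanges
#'
#' Reads BED3-BED6, converting the 0-based half-open coordinates to the
#' 1-based inclusive `GRanges` convention. Round-trips with [exportBed()].
#'
#' @param path Path to a BED file.
#' @return A `GRanges` (with `name` and `score` columns when present).
#' @export
importBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(df))]
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = strand)
  if ("name" %in% names(df)) names(gr) <- df$name
  if ("score" %in% names(df)) S4Vectors::mcols(gr)$score <- df$score
  gr
}

#' Read amplicon sequencing reads from FASTQ
#'
#' @param path Path to a FASTQ file.
#' @return A `DNAStringSet` of reads (qualities are not retained; indel
#'   calling is alignment-based).
#' @export
readFastqReads <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write reads to FASTQ with uniform qualities
#'
#' @param reads A `DNAStringSet` of reads.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastqReads <- function(reads, path) {
  if (length(reads) > 0L && is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  quals <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w)
    strrep("I", w), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read guide definitions from TSV
#'
#' Expects columns `name`, `protospacer` and optionally `pam`
#' (default `"NGG"`).
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A list of [GuideRna-class] objects.
#' @export
readGuidesTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("name", "protospacer") %in% names(df)))
    stop("guide TSV needs 'name' and 'protospacer' columns")
  pam <- if ("pam" %in% names(df)) df$pam else rep("NGG", nrow(df))
  lapply(seq_len(nrow(df)), function(i)
    GuideRna(df$name[i], df$protospacer[i], pam[i]))
}
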