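#' Read aligned records from SAM or BAM into a flat table
#'
#' SAM input is converted with `Rsamtools::asBam()` into a temporary BAM
#' and scanned from there, so both formats go through the same htslib
#' parser. Unmapped, secondary, supplementary and (by default) duplicate
#' records are dropped; the remaining records are the primary alignments
#' every downstream caller consumes.
#'
#' @param path SAM or BAM file.
#' @param drop_duplicates drop records with the PCR/optical duplicate
#'   flag (default TRUE).
#' @return data.frame with columns `qname`, `flag`, `chrom`, `pos`,
#'   `end` (reference-space end from the CIGAR), `mapq`, `cigar`,
#'   `mchrom`, `mpos`, `tlen`, `seq`, and logicals `reverse`,
#'   `first_of_pair`, `paired`, `proper`.
#' @export
read_alignments <- function(path, drop_duplicates = TRUE) {
  bam <- path
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^@", first) || grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = if (drop_duplicates) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq")
  )
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(b$qname)
  if (n == 0) {
    return(data.frame(qname = character(), flag = integer(), chrom = character(),
                      pos = integer(), end = integer(), mapq = integer(),
                      cigar = character(), mchrom = character(), mpos = integer(),
                      tlen = integer(), seq = character(), reverse = logical(),
                      first_of_pair = logical(), paired = logical(),
                      proper = logical(), stringsAsFactors = FALSE))
  }
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  data.frame(
    qname = b$qname, flag = b$flag,
    chrom = as.character(b$rname), pos = b$pos,
    end = b$pos + width - 1L, mapq = b$mapq, cigar = b$cigar,
    mchrom = as.character(b$mrnm), mpos = b$mpos, tlen = b$isize,
    seq = as.character(b$seq),
    reverse = bitwAnd(b$flag, 16L) > 0L,
    first_of_pair = bitwAnd(b$flag, 64L) > 0L,
    paired = bitwAnd(b$flag, 1L) > 0L,
    proper = bitwAnd(b$flag, 2L) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Aligned reference-space segments of each read
#'
#' Expands CIGAR strings into the genomic intervals their M/=/X
#' operations cover; soft-clipped and inserted bases contribute nothing.
#'
#' @param reads alignment table from `read_alignments()`.
#' @return `GRanges` of aligned segments with a `read_idx` metadata
#'   column pointing back into `reads`.
#' @keywords internal
aligned_segments <- function(reads) {
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$pos, ops = c("M", "=", "X")
  )
  n <- lengths(rng)
  flat <- unlist(rng, use.names = FALSE)
  GenomicRanges::GRanges(rep(reads$chrom, n), flat,
                         read_idx = rep(seq_len(nrow(reads)), n))
}
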