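#' Read alignment records from BAM/SAM
#'
#' Loads alignment records into the flat data.frame the rest of the
#' pipeline consumes. SAM input is converted, sorted and indexed on the
#' fly with Rsamtools; BAM input must be coordinate-sorted and indexed.
#' Secondary alignments are excluded by default (they re-describe a read
#' already counted); supplementary alignments are kept in the record set
#' but are used only for read-level clip statistics, never for pileup
#' depth (see [build_pileup()]).
#'
#' @param path path to a `.bam` (sorted + indexed) or `.sam` file.
#' @param region optional restriction: a list/row with `contig`, `start`,
#'   `end` (0-based half-open), e.g. one row of [load_loci()] output.
#'   Only records overlapping the region are returned.
#' @param include_secondary keep secondary alignments (default FALSE).
#' @return data.frame with one row per record: `qname`, `flag`, `contig`,
#'   `start`, `end` (0-based half-open reference span), `mapq`, `cigar`,
#'   `seq` (aligned orientation), `md`, `nm`, `strand`,
#'   `is_supplementary`.
#' @export
read_alignments <- function(path, region = NULL, include_secondary = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("BAM index not found for ", path,
         " -- sort and index it first (samtools sort; samtools index)")
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (include_secondary) NA else FALSE)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, tag = c("MD", "NM"), flag = flag)
  } else {
    Rsamtools::ScanBamParam(
      what = what, tag = c("MD", "NM"), flag = flag,
      which = GenomicRanges::GRanges(region$contig,
                                     .ir(region$start, region$end)))
  }
  res <- Rsamtools::scanBam(path, param = param)
  x <- res[[1]]
  n <- length(x$qname)
  if (n == 0L) return(empty_records())
  df <- data.frame(
    qname = x$qname,
    flag = x$flag,
    contig = as.character(x$rname),
    start = x$pos - 1L,
    mapq = x$mapq,
    cigar = x$cigar,
    seq = as.character(x$seq),
    md = if (is.null(x$tag$MD)) NA_character_ else as.character(x$tag$MD),
    nm = if (is.null(x$tag$NM)) NA_integer_ else as.integer(x$tag$NM),
    stringsAsFactors = FALSE)
  df$end <- df$start +
    GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
  df$strand <- ifelse(bitwAnd(df$flag, 16L) > 0L, "-", "+")
  df$is_supplementary <- bitwAnd(df$flag, 2048L) > 0L
  df[, record_cols()]
}

record_cols <- function() c("qname", "flag", "contig", "start", "end",
                            "mapq", "cigar", "seq", "md", "nm", "strand",
                            "is_supplementary")

empty_records <- function() {
  data.frame(qname = character(), flag = integer(), contig = character(),
             start = integer(), end = integer(), mapq = integer(),
             cigar = character(), seq = character(), md = character(),
             nm = integer(), strand = character(),
             is_supplementary = logical(), stringsAsFactors = FALSE)
}

#' Stream alignments overlapping one locus
#'
#' Thin wrapper over [read_alignments()] restricted to a locus interval;
#' equivalent to a brute-force overlap filter of the full file.
#'
#' @inheritParams read_alignments
#' @param locus a list/row with `contig`, `start`, `end`.
#' @return see [read_alignments()].
#' @export
stream_alignments <- function(path, locus, include_secondary = FALSE) {
  read_alignments(path, region = locus, include_secondary = include_secondary)
}

#' Write alignment records as SAM
#'
#' Serializes a record data.frame (the [read_alignments()] schema) to a
#' plain-text SAM file with a minimal header, suitable for conversion
#' with `Rsamtools::asBam` or samtools.
#'
#' @param records record data.frame.
#' @param assembly [ig_assembly][load_assembly] providing `@SQ` lines.
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, assembly, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(assembly$lengths),
                  "\tLN:", assembly$lengths))
  ord <- order(match(records$contig, names(assembly$lengths)), records$start)
  r <- records[ord, , drop = FALSE]
  body <- paste(r$qname, r$flag, r$contig, r$start + 1L, r$mapq, r$cigar,
                "*", 0L, 0L, r$seq, "*",
                paste0("NM:i:", r$nm), paste0("MD:Z:", r$md),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
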