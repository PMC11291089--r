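`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a region string
#'
#' Parses a human-facing `"contig:start-end"` region (1-based inclusive,
#' the samtools dialect; commas allowed) into internal 0-based half-open
#' coordinates.
#'
#' @param x character scalar, e.g. `"scaffold_8:75432695-75440919"`.
#' @return list with `contig`, `start` (0-based), `end` (exclusive) and
#'   `width` in bp.
#' @examples
#' parse_region("chr1:101-200")$width  # 100
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^(.+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", x)
  s1 <- as.numeric(gsub(",", "", m[3]))
  e1 <- as.numeric(gsub(",", "", m[4]))
  if (s1 < 1 || e1 < s1) stop("invalid region coordinates: ", x)
  list(contig = m[2], start = s1 - 1, end = e1, width = e1 - s1 + 1)
}

## 0-based half-open intervals -> IRanges (1-based closed)
.ir <- function(start0, end0) IRanges::IRanges(start = start0 + 1L, end = end0)

## IRanges -> data.frame of 0-based half-open intervals
.ir_df <- function(ir) {
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

#' Jaccard overlap of two interval sets
#'
#' Intersection-over-union of two sets of 0-based half-open intervals,
#' used to score recovered defect intervals against simulation truth.
#'
#' @param a_start,a_end,b_start,b_end integer vectors of interval
#'   endpoints.
#' @return Jaccard index in [0, 1]; NA if both sets are empty.
#' @export
interval_jaccard <- function(a_start, a_end, b_start, b_end) {
  a <- IRanges::reduce(.ir(a_start, a_end))
  b <- IRanges::reduce(.ir(b_start, b_end))
  inter <- sum(IRanges::width(IRanges::intersect(a, b)))
  uni <- sum(IRanges::width(IRanges::union(a, b)))
  if (uni == 0) return(NA_real_)
  inter / uni
}

## half-up rounding to 0.1 (report convention; round() is half-to-even)
round1 <- function(x) floor(x * 10 + 0.5) / 10

## write a TSV with '#'-prefixed header comment lines
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  read.delim(path, comment.char = "#", sep = "\t", stringsAsFactors = FALSE)
}
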