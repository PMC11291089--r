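#' Ingest samtools mpileup text
#'
#' Parses the 6-column `samtools mpileup` text layout (contig, 1-based
#' position, reference base, depth, read bases, qualities) into
#' per-position depth and mismatch counts for the basepair-oriented
#' view. The read-bases string is decoded per the mpileup grammar:
#' `.`/`,` match, `ACGTN`/`acgtn` mismatch, `*`/`#` deletion, `^X` and
#' `$` mark read starts/ends, `+n`/`-n` followed by `n` bases describe
#' adjacent indels (skipped), `>`/`<` are reference skips. Positions
#' where the reference base is N contribute no mismatches. Note the
#' read-level (E_j) metrics cannot be derived from mpileup -- it carries
#' no per-read identity -- so this path serves only the
#' basepair-oriented track.
#'
#' @param path path to an mpileup text file (optionally with `#`
#'   comment lines).
#' @return data.frame `contig`, `pos` (0-based), `ref`, `depth`,
#'   `delta` (mismatching reads), `deleted`, `rate` (delta/depth, NA at
#'   depth 0).
#' @export
load_mpileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), depth = integer(),
                      delta = integer(), deleted = integer(),
                      rate = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 5L
  if (any(bad)) stop("malformed mpileup line: ", lines[which(bad)[1]])
  contig <- vapply(parts, `[[`, "", 1L)
  pos1 <- as.integer(vapply(parts, `[[`, "", 2L))
  ref <- toupper(vapply(parts, `[[`, "", 3L))
  depth <- as.integer(vapply(parts, `[[`, "", 4L))
  bases <- vapply(parts, function(p) if (length(p) >= 5L) p[[5L]] else "", "")
  counts <- t(vapply(bases, decode_mpileup_bases, c(mm = 0L, del = 0L)))
  delta <- ifelse(ref == "N", 0L, counts[, "mm"])
  data.frame(contig = contig, pos = pos1 - 1L, ref = ref, depth = depth,
             delta = as.integer(delta), deleted = counts[, "del"],
             rate = ifelse(depth > 0, delta / depth, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

## counts of mismatching reads and deleted reads in one mpileup
## read-bases string
decode_mpileup_bases <- function(x) {
  chars <- strsplit(x, "")[[1]]
  i <- 1L; n <- length(chars)
  mm <- 0L; del <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                      # caret + mapping quality char
    } else if (ch == "$" || ch %in% c(">", "<")) {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                     # skip the inserted/deleted bases
    } else if (ch %in% c("*", "#")) {
      del <- del + 1L; i <- i + 1L
    } else if (ch %in% c(".", ",")) {
      i <- i + 1L
    } else if (toupper(ch) %in% c("A", "C", "G", "T", "N")) {
      mm <- mm + 1L; i <- i + 1L
    } else {
      i <- i + 1L                      # tolerate unknown markers
    }
  }
  c(mm = mm, del = del)
}
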