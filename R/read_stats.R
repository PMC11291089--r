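#' Per-read alignment statistics
#'
#' Computes, for every mapped record, the substitution count d(r,g)
#' against the assembly, the mismatch rate e_r = d(r,g)/n(r), clipped
#' bases, and indel events. Substitutions are aligned positions where the
#' read base differs from the assembly base; insertions, deletions and
#' clips are excluded from both the substitution count and the aligned
#' length, and positions where the assembly base is N are excluded from
#' the substitution count (comparison to N is undefined). Two routes are
#' available: a fast path that decodes the MD/NM tags, and a base-by-base
#' CIGAR walk against the reference; they agree wherever the MD tag is
#' consistent with the CIGAR.
#'
#' @param records record data.frame from [read_alignments()] (or the
#'   simulator's oracle placement).
#' @param assembly [ig_assembly][load_assembly]; required for the
#'   `basewalk` route.
#' @param theta per-read mismatch-rate threshold; a read is poorly
#'   aligned when `e_r > theta` (strict). Default 0.01, chosen to absorb
#'   HiFi sequencing error (<0.5%).
#' @param indel_min_len minimum run length (bp) for an insertion or
#'   deletion to count as an indel event. Default 2.
#' @param method `"auto"` uses MD when present and consistent, else the
#'   base walk; `"md"` / `"basewalk"` force a route.
#' @param denominator `"aligned"` (default) divides d(r,g) by the number
#'   of aligned (M/=/X) bases, keeping e_r in [0, 1] and insensitive to
#'   clipping; `"read"` divides by the full read length including clips.
#' @return data.frame of class `ig_read_stats`, one row per usable
#'   record: identification and span columns, `aligned_length`,
#'   `substitutions`, `mismatch_rate`, `soft_clip_bases`,
#'   `hard_clip_bases`, `indel_events`, `poorly_aligned`, plus
#'   list-columns `mm_pos` (0-based reference positions of
#'   substitutions) and `del_start`/`del_end` (deletion intervals)
#'   consumed by [build_pileup()]. Records whose CIGAR and sequence
#'   lengths disagree are skipped with a warning (count in attribute
#'   `n_skipped`).
#' @export
compute_read_stats <- function(records, assembly = NULL, theta = 0.01,
                               indel_min_len = 2L,
                               method = c("auto", "basewalk", "md"),
                               denominator = c("aligned", "read")) {
  method <- match.arg(method)
  denominator <- match.arg(denominator)
  n <- nrow(records)
  if (n == 0L) {
    out <- cbind(empty_records()[0, c("qname", "contig", "start", "end",
                                      "mapq", "strand", "is_supplementary")],
                 data.frame(aligned_length = integer(), substitutions = integer(),
                            mismatch_rate = numeric(), soft_clip_bases = integer(),
                            hard_clip_bases = integer(), indel_events = integer(),
                            poorly_aligned = logical()))
    out$mm_pos <- list(); out$del_start <- list(); out$del_end <- list()
    return(structure(out, class = c("ig_read_stats", "data.frame"),
                     theta = theta, n_skipped = 0L))
  }
  ops_all <- GenomicAlignments::explodeCigarOps(records$cigar)
  lens_all <- GenomicAlignments::explodeCigarOpLengths(records$cigar)
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(records$cigar)
  has_seq <- !is.na(records$seq) & records$seq != "*"
  bad <- has_seq & nchar(records$seq) != qwidth
  if (any(bad))
    warning(sum(bad), " record(s) skipped: CIGAR/sequence length mismatch")
  keep <- which(!bad)

  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    ops <- ops_all[[i]]; lens <- lens_all[[i]]
    soft <- sum(lens[ops == "S"])
    hard <- sum(lens[ops == "H"])
    aligned_len <- sum(lens[ops %in% c("M", "=", "X")])
    indel_events <- sum(ops %in% c("I", "D") & lens >= indel_min_len)
    dels <- cigar_del_ranges(ops, lens, records$start[i])
    use_md <- FALSE
    if (method %in% c("auto", "md") && !is.na(records$md[i])) {
      mm <- md_mismatch_positions(records$md[i], ops, lens, records$start[i])
      if (!is.null(mm)) use_md <- TRUE
      else if (method == "md")
        stop("MD tag inconsistent with CIGAR for read ", records$qname[i])
    }
    if (!use_md) {
      if (is.null(assembly))
        stop("assembly required for base-by-base mismatch counting ",
             "(no usable MD tag for read ", records$qname[i], ")")
      mm <- walk_mismatch_positions(records$seq[i], ops, lens,
                                    records$start[i],
                                    assembly, records$contig[i])
    }
    denom <- if (denominator == "aligned") aligned_len else
      qwidth[i] + hard
    rate <- if (denom > 0) length(mm) / denom else 0
    rows[[k]] <- list(qname = records$qname[i], contig = records$contig[i],
                      start = records$start[i], end = records$end[i],
                      mapq = records$mapq[i], strand = records$strand[i],
                      is_supplementary = records$is_supplementary[i],
                      aligned_length = aligned_len,
                      substitutions = length(mm),
                      mismatch_rate = rate,
                      soft_clip_bases = soft, hard_clip_bases = hard,
                      indel_events = indel_events,
                      mm = mm, del = dels)
  }
  out <- data.frame(
    qname = vapply(rows, `[[`, "", "qname"),
    contig = vapply(rows, `[[`, "", "contig"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    mapq = vapply(rows, `[[`, 0L, "mapq"),
    strand = vapply(rows, `[[`, "", "strand"),
    is_supplementary = vapply(rows, `[[`, FALSE, "is_supplementary"),
    aligned_length = vapply(rows, `[[`, 0L, "aligned_length"),
    substitutions = vapply(rows, function(r) length(r$mm), 0L),
    mismatch_rate = vapply(rows, `[[`, 0, "mismatch_rate"),
    soft_clip_bases = vapply(rows, `[[`, 0L, "soft_clip_bases"),
    hard_clip_bases = vapply(rows, `[[`, 0L, "hard_clip_bases"),
    indel_events = vapply(rows, `[[`, 0L, "indel_events"),
    stringsAsFactors = FALSE)
  out$poorly_aligned <- out$mismatch_rate > theta
  out$mm_pos <- lapply(rows, `[[`, "mm")
  out$del_start <- lapply(rows, function(r) r$del$start)
  out$del_end <- lapply(rows, function(r) r$del$end)
  structure(out, class = c("ig_read_stats", "data.frame"),
            theta = theta, n_skipped = sum(bad))
}

## deletion (D) and ref-skip (N) intervals on the reference, 0-based
cigar_del_ranges <- function(ops, lens, start0) {
  ref_consuming <- ops %in% c("M", "=", "X", "D", "N")
  off <- 0L
  ds <- integer(0); de <- integer(0)
  for (j in seq_along(ops)) {
    if (ops[j] %in% c("D", "N")) {
      ds <- c(ds, start0 + off); de <- c(de, start0 + off + lens[j])
    }
    if (ref_consuming[j]) off <- off + lens[j]
  }
  list(start = ds, end = de)
}

## base-by-base CIGAR walk: 0-based reference positions of substitutions,
## excluding positions where the reference base is N
walk_mismatch_positions <- function(seq, ops, lens, start0, assembly, contig) {
  ref_span <- sum(lens[ops %in% c("M", "=", "X", "D", "N")])
  refc <- strsplit(assembly_subseq(assembly, contig, start0,
                                   start0 + ref_span), "")[[1]]
  readc <- strsplit(seq, "")[[1]]
  roff <- 0L; qoff <- 0L
  mm <- integer(0)
  for (j in seq_along(ops)) {
    op <- ops[j]; len <- lens[j]
    if (op %in% c("M", "=", "X")) {
      a <- readc[(qoff + 1L):(qoff + len)]
      b <- refc[(roff + 1L):(roff + len)]
      hit <- which(a != b & b != "N")
      if (length(hit)) mm <- c(mm, start0 + roff + hit - 1L)
      roff <- roff + len; qoff <- qoff + len
    } else if (op %in% c("I", "S")) {
      qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      roff <- roff + len
    }
  }
  mm
}

## MD-tag fast path: 0-based reference positions of substitutions
## (reference-N mismatches excluded). Returns NULL when the MD tag does
## not tile the CIGAR's M/D extent.
md_mismatch_positions <- function(md, ops, lens, start0) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  if (length(toks) == 0L) return(NULL)
  ## genome position for each MD-space offset (M and D ops); linear when
  ## the CIGAR has no ref-consuming gaps
  md_len <- sum(lens[ops %in% c("M", "=", "X", "D")])
  simple <- !any(ops %in% c("D", "N"))
  map <- if (simple) NULL else {
    m <- integer(md_len)
    off <- 0L; g <- start0
    for (j in seq_along(ops)) {
      op <- ops[j]; len <- lens[j]
      if (op %in% c("M", "=", "X", "D")) {
        m[(off + 1L):(off + len)] <- g + seq_len(len) - 1L
        off <- off + len; g <- g + len
      } else if (op == "N") {
        g <- g + len
      }
    }
    m
  }
  pos <- integer(0)
  cur <- 0L
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      cur <- cur + as.integer(t)
    } else if (startsWith(t, "^")) {
      cur <- cur + nchar(t) - 1L
    } else {
      cur <- cur + 1L
      if (cur > md_len) return(NULL)
      if (t != "N")
        pos <- c(pos, if (simple) start0 + cur - 1L else map[cur])
    }
  }
  if (cur != md_len) return(NULL)
  pos
}

#' Flag poorly aligned reads
#'
#' A read is poorly aligned when its mismatch rate e_r strictly exceeds
#' the threshold theta (default 0.01): `e_r = 0.01` exactly is not
#' flagged.
#'
#' @param stats [ig_read_stats][compute_read_stats] data.frame.
#' @param theta threshold on e_r.
#' @return logical vector, one element per read.
#' @export
classify_read <- function(stats, theta = 0.01) {
  stats$mismatch_rate > theta
}

#' Read-level summary
#'
#' Aggregates per-read statistics into the quantities shown in read-level
#' summary panels: the MAPQ distribution, soft/hard-clip and mismatch-rate
#' distributions, indel event counts, and the fractions of reads that are
#' soft-clipped or poorly aligned.
#'
#' @inheritParams classify_read
#' @return list with `n_reads`, `mapq_hist` (counts over MAPQ 0..60),
#'   `mapq_bins` (counts in bins 0 / 1-59 / 60), `frac_soft_clipped`,
#'   `frac_poorly_aligned`, `mean_mismatch_rate`, `total_indel_events`,
#'   and the raw `mapq`, `soft_clip_bases`, `mismatch_rate`,
#'   `indel_events` vectors for plotting. An empty input yields a zeroed
#'   summary.
#' @export
summarize_reads <- function(stats, theta = attr(stats, "theta") %||% 0.01) {
  n <- nrow(stats)
  mq <- factor(stats$mapq, levels = 0:60)
  bins <- c(mapq0 = sum(stats$mapq == 0),
            mapq_mid = sum(stats$mapq >= 1 & stats$mapq <= 59),
            mapq60 = sum(stats$mapq == 60))
  list(n_reads = n,
       mapq_hist = table(mq),
       mapq_bins = bins,
       frac_soft_clipped = if (n) mean(stats$soft_clip_bases > 0) else 0,
       frac_poorly_aligned = if (n) mean(stats$mismatch_rate > theta) else 0,
       mean_mismatch_rate = if (n) mean(stats$mismatch_rate) else 0,
       total_indel_events = sum(stats$indel_events),
       mapq = stats$mapq,
       soft_clip_bases = stats$soft_clip_bases,
       mismatch_rate = stats$mismatch_rate,
       indel_events = stats$indel_events)
}
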