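#' Per-position pileup metrics over a locus
#'
#' For every position j of the locus, counts the covering reads (depth
#' |J_j|), the covering reads whose base at j differs from the assembly
#' base (the basepair-oriented mismatch count delta_j), the covering
#' reads whose whole-read mismatch rate exceeds theta (the read-oriented
#' count E_j), reads deleted at j, and depth split by MAPQ bin
#' (60 / 1-59 / 0).
#'
#' A read with a deletion at j still covers j for depth purposes -- it
#' spans the position -- but contributes neither a match nor a mismatch
#' there, so coverage breaks retain the meaning "no read spans here".
#' Insertions are anchored to no reference position. Supplementary and
#' secondary alignments are excluded from the pileup. Reads of every
#' MAPQ, including 0, contribute: multi-mapping reflects repeat structure,
#' not assembly error, and is surfaced through the MAPQ bins instead of a
#' filter (`mapq_min` exists for exploration, default 0).
#'
#' @param stats [ig_read_stats][compute_read_stats] for reads overlapping
#'   the locus.
#' @param locus list/row with `contig`, `start`, `end` (0-based
#'   half-open).
#' @param theta per-read mismatch-rate threshold used for E_j.
#' @param mapq_min minimum MAPQ for a read to enter the pileup.
#' @return data.frame of class `ig_pileup`, one row per locus position:
#'   `contig`, `pos` (0-based), `depth`, `delta`, `deleted`, `e_count`,
#'   `mapq60`, `mapq_mid`, `mapq0`, `support` (= (depth-delta)/depth, NA
#'   at depth 0). The locus and thresholds travel as attributes.
#' @export
build_pileup <- function(stats, locus, theta = attr(stats, "theta") %||% 0.01,
                         mapq_min = 0L) {
  ls <- locus$start; le <- locus$end
  w <- le - ls
  stopifnot(w > 0)
  s <- stats[stats$contig == locus$contig & !stats$is_supplementary &
               stats$mapq >= mapq_min &
               stats$start < le & stats$end > ls, , drop = FALSE]

  cov_of <- function(idx_start, idx_end) {
    if (length(idx_start) == 0L) return(integer(w))
    a <- pmax(idx_start, ls); b <- pmin(idx_end, le)
    ok <- a < b
    if (!any(ok)) return(integer(w))
    as.integer(IRanges::coverage(.ir(a[ok] - ls, b[ok] - ls), width = w))
  }

  depth <- cov_of(s$start, s$end)
  poor <- s$mismatch_rate > theta
  e_count <- cov_of(s$start[poor], s$end[poor])
  mapq0 <- cov_of(s$start[s$mapq == 0], s$end[s$mapq == 0])
  mapq60 <- cov_of(s$start[s$mapq == 60], s$end[s$mapq == 60])
  mid <- s$mapq >= 1 & s$mapq <= 59
  mapq_mid <- cov_of(s$start[mid], s$end[mid])

  dstart <- unlist(s$del_start, use.names = FALSE)
  dend <- unlist(s$del_end, use.names = FALSE)
  deleted <- if (length(dstart)) cov_of(dstart, dend) else integer(w)

  mm <- unlist(s$mm_pos, use.names = FALSE)
  mm <- mm[mm >= ls & mm < le]
  delta <- tabulate(mm - ls + 1L, nbins = w)

  support <- ifelse(depth > 0, (depth - delta) / depth, NA_real_)
  structure(
    data.frame(contig = locus$contig, pos = seq.int(ls, le - 1L),
               depth = depth, delta = delta, deleted = deleted,
               e_count = e_count, mapq60 = mapq60, mapq_mid = mapq_mid,
               mapq0 = mapq0, support = support,
               stringsAsFactors = FALSE),
    class = c("ig_pileup", "data.frame"),
    locus = locus, theta = theta, mapq_min = mapq_min)
}

#' Flag poorly supported positions (read-oriented view)
#'
#' Position j is poorly supported when E_j, the number of covering reads
#' whose mismatch rate exceeds theta, is strictly greater than
#' `min_bad_reads` (default 5): a position with exactly 5 such reads is
#' not flagged. Adjacent flagged positions are merged into maximal
#' intervals for reporting.
#'
#' @param pileup [ig_pileup][build_pileup].
#' @param min_bad_reads strict lower bound on E_j.
#' @return list of class `ig_flags`: `positions` (0-based), `intervals`
#'   (data.frame `contig`/`start`/`end`/`length`), `n_flagged`,
#'   `frac_flagged` (of locus length), `min_bad_reads`.
#' @export
flag_poorly_supported <- function(pileup, min_bad_reads = 5L) {
  hit <- pileup$pos[pileup$e_count > min_bad_reads]
  iv <- if (length(hit)) {
    r <- .ir_df(IRanges::reduce(.ir(hit, hit + 1L)))
    data.frame(contig = pileup$contig[1], start = r$start, end = r$end,
               length = r$end - r$start, stringsAsFactors = FALSE)
  } else {
    data.frame(contig = character(), start = integer(), end = integer(),
               length = integer(), stringsAsFactors = FALSE)
  }
  structure(list(positions = hit, intervals = iv,
                 n_flagged = length(hit),
                 frac_flagged = length(hit) / nrow(pileup),
                 min_bad_reads = min_bad_reads),
            class = "ig_flags")
}

#' @export
print.ig_flags <- function(x, ...) {
  cat("ig_flags:", x$n_flagged, "poorly supported position(s) in",
      nrow(x$intervals), "interval(s); fraction",
      signif(x$frac_flagged, 3), "\n")
  invisible(x)
}

#' Basepair-oriented mismatch rate track
#'
#' rate_j = delta_j / depth_j where depth > 0; uncovered positions are
#' reported as missing (NA), not zero.
#'
#' @inheritParams flag_poorly_supported
#' @return data.frame `contig`, `pos` (0-based), `depth`, `delta`,
#'   `rate`.
#' @export
basepair_mismatch_rate <- function(pileup) {
  data.frame(contig = pileup$contig, pos = pileup$pos,
             depth = pileup$depth, delta = pileup$delta,
             rate = ifelse(pileup$depth > 0,
                           pileup$delta / pileup$depth, NA_real_),
             stringsAsFactors = FALSE)
}

#' Annotate columns of elevated coverage
#'
#' Marks positions whose depth exceeds `factor` times the median locus
#' depth. Sudden coverage increases accompany missing-sequence errors
#' (displaced reads pile onto the retained homolog) but are duplication
#' signals too, so this is an annotation, never an error call by itself.
#'
#' @inheritParams flag_poorly_supported
#' @param factor multiple of the median locus depth.
#' @return the pileup with a logical `high_coverage` column; the median
#'   used is stored in attribute `median_depth`.
#' @export
annotate_high_coverage <- function(pileup, factor = 2) {
  med <- median(pileup$depth)
  pileup$high_coverage <- pileup$depth > factor * med
  attr(pileup, "median_depth") <- med
  pileup
}
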