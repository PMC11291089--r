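#' Detect breaks in read coverage
#'
#' A coverage break is a maximal run of positions whose depth is at or
#' below `break_threshold` (default 2 reads). Near-uniform multi-read
#' coverage is expected everywhere in a correct assembly, so such runs
#' mark minimal support and candidate misassemblies. For each break the
#' minimum depth over the run and the number of reads fully spanning the
#' whole run are reported ("0 reads spanning" confirms a true gap).
#'
#' @param pileup [ig_pileup][build_pileup].
#' @param stats optional [ig_read_stats][compute_read_stats] used to
#'   count spanning reads (reads whose alignment covers the entire break
#'   interval); without it `spanning_reads` is NA.
#' @param break_threshold depth at or below which a position is in a
#'   break.
#' @param min_break_len drop runs shorter than this many bp (default 1,
#'   i.e. keep all).
#' @return data.frame of class `ig_breaks`: `contig`, `start`, `end`
#'   (0-based half-open), `length`, `min_depth`, `spanning_reads`.
#' @export
detect_coverage_breaks <- function(pileup, stats = NULL,
                                   break_threshold = 2L,
                                   min_break_len = 1L) {
  low <- pileup$depth <= break_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_break_len)
  locus_start <- pileup$pos[1]
  out <- data.frame(
    contig = rep(pileup$contig[1], length(keep)),
    start = locus_start + starts[keep] - 1L,
    end = locus_start + ends[keep],
    stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  out$min_depth <- vapply(keep, function(k) {
    min(pileup$depth[starts[k]:ends[k]])
  }, 0L)
  out$spanning_reads <- if (is.null(stats)) rep(NA_integer_, nrow(out)) else
    vapply(seq_len(nrow(out)), function(i) {
      sum(stats$contig == out$contig[i] & !stats$is_supplementary &
            stats$start <= out$start[i] & stats$end >= out$end[i])
    }, 0L)
  structure(out, class = c("ig_breaks", "data.frame"),
            break_threshold = break_threshold)
}

#' Classify coverage breaks
#'
#' Assigns each break a category by deterministic priority:
#' \enumerate{
#'   \item `n_gap` -- the interval overlaps a run of Ns in the assembly
#'     (a scaffolding gap; missing sequence at a join);
#'   \item `contig_end` -- within `end_margin` bp of a contig boundary,
#'     where coverage tapers for purely geometric reasons;
#'   \item `zero_coverage` -- minimum depth 0 mid-contig;
#'   \item `low_coverage` -- everything else.
#' }
#'
#' @param breaks [ig_breaks][detect_coverage_breaks].
#' @param assembly [ig_assembly][load_assembly] supplying N-runs and
#'   contig lengths.
#' @param end_margin distance (bp) from a contig boundary within which a
#'   break is attributed to the boundary. Default 5000.
#' @return `breaks` with a `category` column.
#' @export
classify_breaks <- function(breaks, assembly, end_margin = 5000L) {
  breaks$category <- vapply(seq_len(nrow(breaks)), function(i) {
    classify_break(breaks[i, ], assembly, end_margin)
  }, "")
  breaks
}

#' @rdname classify_breaks
#' @param brk single-row break (list or one row of `ig_breaks`).
#' @export
classify_break <- function(brk, assembly, end_margin = 5000L) {
  if (overlaps_n_run(assembly, brk$contig, brk$start, brk$end))
    return("n_gap")
  clen <- assembly$lengths[[brk$contig]]
  if (brk$start < end_margin || clen - brk$end < end_margin)
    return("contig_end")
  if (brk$min_depth == 0) return("zero_coverage")
  "low_coverage"
}
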