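#' Gene-level read-oriented support
#'
#' Counts, for each annotated V/D/J gene, the poorly aligned reads
#' (mismatch rate above theta) whose alignment span overlaps the gene by
#' at least 1 bp. Genes are short (tens to hundreds of bp) relative to
#' long reads, so any overlap attests. A gene is read-affected when the
#' count is strictly greater than `gene_poor_read_max` (default 5:
#' exactly 5 poor reads do not affect a gene).
#'
#' @param genes data.frame from [load_genes()] (or the simulator truth).
#' @param stats [ig_read_stats][compute_read_stats].
#' @param gene_poor_read_max strict upper bound on tolerated poor reads.
#' @param theta per-read mismatch-rate threshold.
#' @return data.frame `gene_id`, `overlapping_poor_reads`,
#'   `read_affected`.
#' @export
gene_read_support <- function(genes, stats, gene_poor_read_max = 5L,
                              theta = attr(stats, "theta") %||% 0.01) {
  poor <- stats[stats$mismatch_rate > theta & !stats$is_supplementary, ,
                drop = FALSE]
  cnt <- vapply(seq_len(nrow(genes)), function(i) {
    sum(poor$contig == genes$contig[i] &
          poor$start < genes$end[i] & poor$end > genes$start[i])
  }, 0L)
  data.frame(gene_id = genes$gene_id,
             overlapping_poor_reads = cnt,
             read_affected = cnt > gene_poor_read_max,
             stringsAsFactors = FALSE)
}

#' Gene-level basepair-oriented support
#'
#' A gene has perfect support when every one of its positions is covered
#' (depth > 0) and has support fraction strictly above `support_min`
#' (default 0.8, i.e. ">80% confidence at every position"; exactly 80.0%
#' is not perfect). Uncovered gene positions make the gene affected --
#' no support is not perfect support. Weak positions are listed with
#' their support percentage rounded to 0.1%. A gene-level deletion
#' observation is reported when more than half the covering reads carry
#' a deletion at some gene position (diagnostic annotation only).
#'
#' @param genes data.frame of gene annotations, all within the pileup's
#'   locus (a gene outside it is an error).
#' @param pileup [ig_pileup][build_pileup].
#' @param support_min strict lower bound on per-position support
#'   fraction.
#' @return data.frame `gene_id`, `min_support_pct` (NA if any position
#'   uncovered), `n_weak_positions`, `weak_positions` (semicolon-joined
#'   `pos:pct` with 1-based positions), `n_uncovered`, `base_affected`,
#'   `deletion_observed`.
#' @export
gene_base_support <- function(genes, pileup, support_min = 0.8) {
  locus <- attr(pileup, "locus")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$contig != locus$contig || g$start < locus$start ||
        g$end > locus$end)
      stop("gene ", g$gene_id, " outside analyzed locus ",
           locus$contig, ":", locus$start, "-", locus$end)
    rows <- (g$start - locus$start + 1L):(g$end - locus$start)
    depth <- pileup$depth[rows]
    support <- pileup$support[rows]
    uncovered <- depth == 0
    weak <- !uncovered & support <= support_min
    weak_idx <- which(weak | uncovered)
    weak_str <- if (length(weak_idx)) {
      pct <- round(100 * support[weak_idx], 1)
      pct[uncovered[weak_idx]] <- 0
      paste(sprintf("%d:%.1f", pileup$pos[rows][weak_idx] + 1L, pct),
            collapse = ";")
    } else ""
    del_frac <- ifelse(depth > 0, pileup$deleted[rows] / depth, 0)
    data.frame(
      gene_id = g$gene_id,
      min_support_pct = if (any(uncovered)) NA_real_ else
        round(100 * min(support), 1),
      n_weak_positions = sum(weak),
      weak_positions = weak_str,
      n_uncovered = sum(uncovered),
      base_affected = any(uncovered) || any(weak),
      deletion_observed = any(del_frac > 0.5),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Combined per-gene support report
#'
#' Joins the read-oriented and basepair-oriented gene views into one
#' report row per gene.
#'
#' @inheritParams gene_read_support
#' @inheritParams gene_base_support
#' @return data.frame of class `ig_gene_report` with the annotation
#'   columns plus both views' fields.
#' @export
gene_support_report <- function(genes, stats, pileup,
                                gene_poor_read_max = 5L,
                                support_min = 0.8,
                                theta = attr(stats, "theta") %||% 0.01) {
  rs <- gene_read_support(genes, stats, gene_poor_read_max, theta)
  bs <- gene_base_support(genes, pileup, support_min)
  out <- cbind(genes[, c("gene_id", "segment_type", "contig", "start",
                         "end", "strand")],
               rs[, c("overlapping_poor_reads", "read_affected")],
               bs[, setdiff(names(bs), "gene_id")])
  structure(out, class = c("ig_gene_report", "data.frame"))
}

#' Fractions of affected genes
#'
#' Summarizes a gene report into fractions of genes affected in the
#' read-oriented view and lacking perfect base support, overall and by
#' segment type, as percentages rounded to 0.1%.
#'
#' @param report [ig_gene_report][gene_support_report].
#' @return data.frame with rows `all`, `V`, `D`, `J`: `n_genes`,
#'   `n_read_affected`, `pct_read_affected`, `n_base_affected`,
#'   `pct_base_affected`. An empty gene set yields the zeroed `all` row
#'   with a warning.
#' @export
gene_panel_summary <- function(report) {
  one <- function(label, df) {
    n <- nrow(df)
    data.frame(group = label, n_genes = n,
               n_read_affected = sum(df$read_affected),
               pct_read_affected = if (n) round1(100 * mean(df$read_affected)) else 0,
               n_base_affected = sum(df$base_affected),
               pct_base_affected = if (n) round1(100 * mean(df$base_affected)) else 0,
               stringsAsFactors = FALSE)
  }
  if (nrow(report) == 0L) {
    warning("empty gene set: zeroed summary")
    return(one("all", report))
  }
  rbind(one("all", report),
        do.call(rbind, lapply(intersect(.SEGMENT_TYPES,
                                        unique(report$segment_type)),
                              function(s)
                                one(s, report[report$segment_type == s, ]))))
}
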