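.HAP_COLOURS <- c("#2C7FB8", "#E6C229")   # blue = primary, yellow = alternate
.MAPQ_COLOURS <- c(mapq60 = "#1B7837", mapq_mid = "#A6DBA0", mapq0 = "#BDBDBD")
.FLAG_COLOUR <- "#E41A1C"                 # red: poorly supported positions
.BREAK_COLOUR <- "#7B3294"                # purple: coverage breaks

#' Locus diagnostic plot
#'
#' Renders the per-locus diagnostic panel: (i) read depth stacked by
#' MAPQ bin (60 / 1-59 / 0); (ii) the basepair-oriented support track
#' with translucent red spans over poorly supported intervals and purple
#' bars over coverage breaks; (iii) a heatmap strip of weak-position
#' counts per bin (darker = more). Overlay coordinates are taken
#' verbatim from the supplied flag/break objects -- the plot never
#' recomputes metrics -- and are exported as a sidecar TSV so tests can
#' assert on coordinates instead of pixels.
#'
#' @param pileup [ig_pileup][build_pileup].
#' @param flags [ig_flags][flag_poorly_supported].
#' @param breaks classified [ig_breaks][classify_breaks].
#' @param bin_width heatmap bin width in bp (default 10000). Weak
#'   positions are those with support fraction <= 0.8 or no coverage,
#'   consistent with the gene-level rule.
#' @param support_min weak-position threshold for the heatmap strip.
#' @param path optional image path (extension selects the device;
#'   PDF/SVG/PNG).
#' @param sidecar_path optional TSV path for the drawn overlay
#'   intervals.
#' @param max_points loci longer than this are drawn from track means
#'   over small windows (sub-pixel at figure scale); overlay and
#'   heatmap coordinates are never thinned.
#' @return a patchwork/ggplot object; the overlay table is attached as
#'   attribute `overlays`.
#' @export
plot_locus_diagnostics <- function(pileup, flags, breaks,
                                   bin_width = 10000L, support_min = 0.8,
                                   path = NULL, sidecar_path = NULL,
                                   max_points = 20000L) {
  if (nrow(pileup) == 0L) stop("empty pileup: nothing to plot")
  stopifnot(bin_width >= 1)
  pos <- pileup$pos
  thin <- max(1L, ceiling(length(pos) / max_points))
  grp <- (pos - pos[1]) %/% thin
  thin_mean <- function(x) as.numeric(tapply(x, grp, mean, na.rm = TRUE))
  tpos <- pos[1] + unique(grp) * thin
  depth_df <- data.frame(
    pos = rep(tpos, 3L),
    bin = factor(rep(c("mapq60", "mapq_mid", "mapq0"), each = length(tpos)),
                 levels = c("mapq0", "mapq_mid", "mapq60")),
    depth = c(thin_mean(pileup$mapq60), thin_mean(pileup$mapq_mid),
              thin_mean(pileup$mapq0)))
  overlays <- rbind(
    if (nrow(flags$intervals))
      data.frame(type = "flag", contig = flags$intervals$contig,
                 start = flags$intervals$start, end = flags$intervals$end,
                 category = "poorly_supported", stringsAsFactors = FALSE),
    if (nrow(breaks))
      data.frame(type = "break", contig = breaks$contig,
                 start = breaks$start, end = breaks$end,
                 category = breaks$category %||% NA_character_,
                 stringsAsFactors = FALSE))
  if (is.null(overlays))
    overlays <- data.frame(type = character(), contig = character(),
                           start = integer(), end = integer(),
                           category = character(), stringsAsFactors = FALSE)

  weak <- pileup$depth == 0 | (!is.na(pileup$support) &
                                 pileup$support <= support_min)
  bins <- (pos - pos[1]) %/% bin_width
  heat <- data.frame(bin_start = pos[1] + unique(bins) * bin_width,
                     n_weak = as.integer(tapply(weak, bins, sum)))
  heat$bin_end <- pmin(heat$bin_start + bin_width, pos[length(pos)] + 1L)

  p_depth <- ggplot2::ggplot(depth_df,
                             ggplot2::aes(x = .data$pos, y = .data$depth,
                                          fill = .data$bin)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::scale_fill_manual(values = .MAPQ_COLOURS, name = "MAPQ") +
    ggplot2::labs(y = "depth", x = NULL,
                  title = paste0(pileup$contig[1], ":", pos[1] + 1, "-",
                                 pos[length(pos)] + 1)) +
    ggplot2::theme_minimal()

  sup_df <- data.frame(pos = tpos,
                       mismatch = thin_mean(
                         ifelse(pileup$depth > 0,
                                pileup$delta / pileup$depth, NA)))
  p_sup <- ggplot2::ggplot(sup_df, ggplot2::aes(x = .data$pos,
                                                y = .data$mismatch)) +
    ggplot2::geom_line(linewidth = 0.2, na.rm = TRUE) +
    ggplot2::labs(y = "mismatch rate", x = "position") +
    ggplot2::theme_minimal()
  fl <- overlays[overlays$type == "flag", , drop = FALSE]
  if (nrow(fl))
    p_sup <- p_sup + ggplot2::annotate(
      "rect", xmin = fl$start, xmax = fl$end, ymin = -Inf, ymax = Inf,
      fill = .FLAG_COLOUR, alpha = 0.25)
  bk <- overlays[overlays$type == "break", , drop = FALSE]
  if (nrow(bk))
    p_sup <- p_sup + ggplot2::annotate(
      "rect", xmin = bk$start, xmax = bk$end, ymin = -Inf, ymax = Inf,
      fill = .BREAK_COLOUR, alpha = 0.6)

  p_heat <- ggplot2::ggplot(heat, ggplot2::aes(xmin = .data$bin_start,
                                               xmax = .data$bin_end,
                                               ymin = 0, ymax = 1,
                                               fill = .data$n_weak)) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_gradient(low = "white", high = "#67000D",
                                 name = "weak positions") +
    ggplot2::theme_void()

  p <- patchwork::wrap_plots(p_heat, p_depth, p_sup, ncol = 1,
                             heights = c(0.08, 1, 1))
  attr(p, "overlays") <- overlays
  attr(p, "heatmap_bins") <- heat
  if (!is.null(sidecar_path))
    write_tsv_commented(overlays, sidecar_path,
                        "overlay intervals drawn; 0-based half-open")
  if (!is.null(path))
    ggplot2::ggsave(path, p, width = 10, height = 6)
  p
}

#' Read-level summary panels
#'
#' Four panels -- MAPQ frequency, soft-clip bases, per-read mismatch
#' rate, indel event counts -- overlaid for each haplotype with the
#' blue (primary) / yellow (alternate) convention.
#'
#' @param summaries named list of [summarize_reads()] results (typically
#'   `primary` and `alternate`).
#' @param path optional image path.
#' @return a patchwork object; the long-format panel data is attached as
#'   attribute `panel_data`.
#' @export
plot_read_summaries <- function(summaries, path = NULL) {
  stopifnot(length(summaries) >= 1, !is.null(names(summaries)))
  long <- do.call(rbind, lapply(names(summaries), function(h) {
    s <- summaries[[h]]
    data.frame(haplotype = h, mapq = s$mapq,
               soft_clip = s$soft_clip_bases,
               mismatch_rate = s$mismatch_rate,
               indel_events = s$indel_events,
               stringsAsFactors = FALSE)
  }))
  cols <- setNames(.HAP_COLOURS[seq_along(summaries)], names(summaries))
  base <- function(aes_x, xlab, bins = 30) {
    ggplot2::ggplot(long, ggplot2::aes(x = {{ aes_x }},
                                       fill = .data$haplotype)) +
      ggplot2::geom_histogram(bins = bins, position = "identity",
                              alpha = 0.6) +
      ggplot2::scale_fill_manual(values = cols) +
      ggplot2::labs(x = xlab, y = "reads") +
      ggplot2::theme_minimal()
  }
  p <- patchwork::wrap_plots(
    base(.data$mapq, "MAPQ", bins = 61),
    base(.data$soft_clip, "soft-clipped bases"),
    base(.data$mismatch_rate, "read mismatch rate"),
    base(.data$indel_events, "indel events"),
    ncol = 2, guides = "collect")
  attr(p, "panel_data") <- long
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 9, height = 6)
  p
}

#' Locus length comparison
#'
#' Grouped bar chart of total locus length per haplotype label (a
#' fragmented haplotype contributes the sum of its parts).
#'
#' @param loci data.frame from [load_loci()].
#' @param path optional image path.
#' @return a ggplot; the summed lengths are attached as attribute
#'   `lengths`.
#' @export
plot_locus_lengths <- function(loci, path = NULL) {
  agg <- stats::aggregate(cbind(length = end - start) ~ haplotype + locus,
                          data = loci, FUN = sum)
  cols <- setNames(.HAP_COLOURS[seq_along(unique(agg$haplotype))],
                   sort(unique(agg$haplotype)))
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$locus,
                                         y = .data$length,
                                         fill = .data$haplotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::labs(y = "locus length (bp)", x = NULL) +
    ggplot2::theme_minimal()
  attr(p, "lengths") <- agg
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 5, height = 4)
  p
}
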