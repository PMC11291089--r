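#' Pipeline thresholds
#'
#' Bundles every tunable threshold with its default. Defaults follow
#' the method's stated operating points: theta = 0.01 (a read is poorly
#' aligned above 1% mismatch), positions flagged when more than
#' `min_bad_reads` = 5 poor reads cover them, coverage breaks at depth
#' <= 2, genes require support strictly above 80% at every position and
#' tolerate at most 5 overlapping poor reads, indel events need runs of
#' at least 2 bp. The remaining knobs (end margin, evidence floors,
#' MAPQ filter) are package-level choices. All thresholds are echoed
#' into output table headers.
#'
#' @param theta per-read mismatch-rate threshold.
#' @param min_bad_reads strict E_j bound for flagging a position.
#' @param break_threshold depth at or below which a position is in a
#'   coverage break.
#' @param support_min strict per-position support bound for perfect gene
#'   support.
#' @param gene_poor_read_max strict bound on poor reads overlapping a
#'   gene.
#' @param indel_min_len minimum indel run length (bp).
#' @param end_margin contig-end attribution distance for breaks (bp).
#' @param min_break_len minimum break length (bp) to raise the locus
#'   break flag.
#' @param mapq_min minimum MAPQ admitted to the pileup (default 0: keep
#'   everything, surface MAPQ via bins).
#' @param flag_min_interval,flag_frac_min locus-level mismatch evidence
#'   floors (see [call_locus()]).
#' @param high_cov_factor elevated-coverage annotation factor.
#' @return list of class `ig_options`.
#' @export
qc_options <- function(theta = 0.01, min_bad_reads = 5L,
                       break_threshold = 2L, support_min = 0.8,
                       gene_poor_read_max = 5L, indel_min_len = 2L,
                       end_margin = 5000L, min_break_len = 10L,
                       mapq_min = 0L, flag_min_interval = 100L,
                       flag_frac_min = 0.005, high_cov_factor = 2) {
  structure(list(theta = theta, min_bad_reads = min_bad_reads,
                 break_threshold = break_threshold,
                 support_min = support_min,
                 gene_poor_read_max = gene_poor_read_max,
                 indel_min_len = indel_min_len, end_margin = end_margin,
                 min_break_len = min_break_len, mapq_min = mapq_min,
                 flag_min_interval = flag_min_interval,
                 flag_frac_min = flag_frac_min,
                 high_cov_factor = high_cov_factor),
            class = "ig_options")
}

options_header <- function(opts) {
  paste0("thresholds: ",
         paste(names(opts), unlist(opts), sep = "=", collapse = " "))
}

#' Evaluate an assembly over its IG loci
#'
#' The in-memory pipeline core: per locus interval, computes read
#' statistics, the pileup, poorly supported positions, classified
#' coverage breaks and the gene report, then calls each locus class
#' (union over its haplotype intervals).
#'
#' @param assembly [ig_assembly][load_assembly].
#' @param loci data.frame from [load_loci()].
#' @param genes data.frame from [load_genes()] (may be NULL).
#' @param records alignment record data.frame ([read_alignments()]), or
#'   a function(locus) returning records for one locus interval.
#' @param opts [qc_options()].
#' @return list of class `ig_evaluation`: per-interval results
#'   (`intervals`, each with `stats`, `summary`, `pileup`, `flags`,
#'   `breaks`, `gene_report`) and per-locus-class `calls`.
#' @export
evaluate_assembly <- function(assembly, loci, genes = NULL, records,
                              opts = qc_options()) {
  fetch <- if (is.function(records)) records else function(locus) {
    records[records$contig == locus$contig &
              records$start < locus$end & records$end > locus$start, ,
            drop = FALSE]
  }
  intervals <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- as.list(loci[i, ])
    recs <- fetch(locus)
    stats <- compute_read_stats(recs, assembly, theta = opts$theta,
                                indel_min_len = opts$indel_min_len)
    pre_pileup <- stats[!stats$is_supplementary, , drop = FALSE]
    pileup <- build_pileup(pre_pileup, locus, theta = opts$theta,
                           mapq_min = opts$mapq_min)
    pileup <- annotate_high_coverage(pileup, factor = opts$high_cov_factor)
    flags <- flag_poorly_supported(pileup, opts$min_bad_reads)
    breaks <- detect_coverage_breaks(pileup, pre_pileup,
                                     break_threshold = opts$break_threshold)
    breaks <- classify_breaks(breaks, assembly, end_margin = opts$end_margin)
    g <- if (is.null(genes)) NULL else
      genes[genes$contig == locus$contig & genes$start >= locus$start &
              genes$end <= locus$end, , drop = FALSE]
    gene_report <- if (!is.null(g) && nrow(g)) {
      gene_support_report(g, stats, pileup,
                          gene_poor_read_max = opts$gene_poor_read_max,
                          support_min = opts$support_min,
                          theta = opts$theta)
    } else NULL
    list(locus = locus, stats = stats, summary = summarize_reads(stats),
         pileup = pileup, flags = flags, breaks = breaks,
         gene_report = gene_report)
  })
  names(intervals) <- paste0(loci$contig, ":", loci$start, "-", loci$end)
  calls <- lapply(split(seq_len(nrow(loci)), loci$locus), function(idx) {
    call_locus(lapply(intervals[idx], `[[`, "flags"),
               lapply(intervals[idx], `[[`, "breaks"),
               locus_length = sum(loci$end[idx] - loci$start[idx]),
               min_flag_interval = opts$flag_min_interval,
               flag_frac_min = opts$flag_frac_min,
               min_break_len = opts$min_break_len)
  })
  structure(list(intervals = intervals, calls = calls, opts = opts),
            class = "ig_evaluation")
}

#' Write the pipeline's tabular outputs
#'
#' Emits deterministic TSVs (positions, flagged intervals, breaks, gene
#' report, per-read stats, locus calls) with `#` header comments
#' recording the coordinate dialect and every threshold. Human-facing
#' coordinates are 1-based inclusive.
#'
#' @param evaluation [ig_evaluation][evaluate_assembly].
#' @param out_dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_metric_tables <- function(evaluation, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  hdr <- c("coordinates: 1-based inclusive",
           options_header(evaluation$opts))
  iv <- evaluation$intervals

  positions <- do.call(rbind, lapply(iv, function(x) {
    p <- x$pileup
    data.frame(contig = p$contig, pos = p$pos + 1L, depth = p$depth,
               delta = p$delta, e_count = p$e_count,
               support = round(ifelse(is.na(p$support), NA, 100 * p$support), 1),
               mapq60 = p$mapq60, mapq_mid = p$mapq_mid, mapq0 = p$mapq0,
               high_coverage = as.integer(p$high_coverage),
               stringsAsFactors = FALSE)
  }))
  flags <- do.call(rbind, lapply(iv, function(x) x$flags$intervals))
  flags_out <- if (nrow(flags)) transform(flags, start = start + 1L) else flags
  breaks <- do.call(rbind, lapply(iv, function(x) as.data.frame(x$breaks)))
  breaks_out <- if (nrow(breaks)) transform(breaks, start = start + 1L) else breaks
  genes <- do.call(rbind, lapply(iv, function(x) x$gene_report))
  reads <- do.call(rbind, lapply(iv, function(x) {
    s <- x$stats
    data.frame(qname = s$qname, contig = s$contig, start = s$start + 1L,
               end = s$end, mapq = s$mapq,
               aligned_length = s$aligned_length,
               substitutions = s$substitutions,
               mismatch_rate = signif(s$mismatch_rate, 6),
               soft_clip_bases = s$soft_clip_bases,
               hard_clip_bases = s$hard_clip_bases,
               indel_events = s$indel_events,
               poorly_aligned = as.integer(s$poorly_aligned),
               stringsAsFactors = FALSE)
  }))
  calls <- do.call(rbind, lapply(names(evaluation$calls), function(lc) {
    cl <- evaluation$calls[[lc]]
    data.frame(locus = lc, category = cl$category,
               mismatch_flag = as.integer(cl$mismatch_flag),
               break_flag = as.integer(cl$break_flag),
               n_flagged_positions = cl$n_flagged_positions,
               n_significant_breaks = cl$n_significant_breaks,
               locus_length = cl$locus_length, stringsAsFactors = FALSE)
  }))
  paths <- c(positions = file.path(out_dir, "positions.tsv"),
             flags = file.path(out_dir, "flagged_intervals.tsv"),
             breaks = file.path(out_dir, "breaks.tsv"),
             genes = file.path(out_dir, "gene_report.tsv"),
             reads = file.path(out_dir, "read_stats.tsv"),
             calls = file.path(out_dir, "locus_calls.tsv"))
  write_tsv_commented(positions, paths["positions"], hdr)
  write_tsv_commented(flags_out, paths["flags"], hdr)
  write_tsv_commented(breaks_out, paths["breaks"], hdr)
  if (!is.null(genes)) write_tsv_commented(
    transform(genes, start = start + 1L), paths["genes"], hdr)
  write_tsv_commented(reads, paths["reads"], hdr)
  write_tsv_commented(calls, paths["calls"], hdr)
  invisible(paths)
}

#' Read a written breaks table back
#'
#' Restores internal 0-based half-open coordinates from a breaks TSV
#' written by [write_metric_tables()] (round-trip identity).
#'
#' @param path breaks TSV path.
#' @return `ig_breaks`-shaped data.frame.
#' @export
read_breaks_tsv <- function(path) {
  df <- read_tsv_commented(path)
  if (nrow(df)) df$start <- df$start - 1L
  df
}

#' Run the end-to-end evaluation from files
#'
#' Fig-1-style orchestration: loads the assembly, loci, genes and
#' alignments, computes all metrics per locus, writes the metric tables,
#' optional diagnostic plots, and a JSON run manifest (configuration
#' echo, input checksums, package version).
#'
#' @param config list (or path to a YAML file) with elements `assembly`,
#'   `alignments`, `loci`, `genes` (optional), `out_dir`, optional
#'   `thresholds` (passed to [qc_options()]), optional `plots` (logical)
#'   and `haplotype_patterns`.
#' @return the [ig_evaluation][evaluate_assembly], invisibly.
#' @export
run_evaluate <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("assembly", "alignments", "loci", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("[config] missing field(s): ", paste(miss, collapse = ", "))
  opts <- do.call(qc_options, config$thresholds %||% list())
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("[", label, "] ", conditionMessage(e), call. = FALSE))
  }
  assembly <- stage("load_assembly", load_assembly(config$assembly))
  loci <- stage("load_loci", load_loci(
    config$loci, assembly,
    haplotype_patterns = config$haplotype_patterns))
  genes <- if (!is.null(config$genes))
    stage("load_genes", load_genes(config$genes, assembly, loci = loci))
  fetch <- function(locus)
    stream_alignments(config$alignments, locus)
  evaluation <- stage("evaluate",
                      evaluate_assembly(assembly, loci, genes, fetch, opts))
  paths <- stage("write_tables",
                 write_metric_tables(evaluation, config$out_dir))
  if (isTRUE(config$plots)) {
    for (nm in names(evaluation$intervals)) {
      x <- evaluation$intervals[[nm]]
      safe <- gsub("[:]", "_", nm)
      stage("plots", plot_locus_diagnostics(
        x$pileup, x$flags, x$breaks,
        path = file.path(config$out_dir, paste0(safe, "_diagnostics.pdf")),
        sidecar_path = file.path(config$out_dir,
                                 paste0(safe, "_overlays.tsv"))))
    }
  }
  manifest <- list(
    tool = "igqc", version = as.character(packageVersion("igqc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    thresholds = unclass(opts),
    inputs = lapply(config[intersect(c("assembly", "alignments", "loci",
                                       "genes"), names(config))],
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    outputs = as.list(paths),
    calls = lapply(evaluation$calls, function(cl)
      list(category = cl$category, mismatch_flag = cl$mismatch_flag,
           break_flag = cl$break_flag)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(evaluation)
}

#' Summarize per-species calls
#'
#' Reads a calls TSV (or takes a data.frame), aggregates it with
#' [aggregate_species()] and optionally writes the grouped summary and
#' any-error tables.
#'
#' @param calls path to a calls TSV or a data.frame.
#' @param out_dir optional output directory for `summary_by_group.tsv`
#'   and `summary_any_error.tsv`.
#' @param mode counting mode, see [aggregate_species()].
#' @return the [ig_summary][aggregate_species].
#' @export
run_summarize <- function(calls, out_dir = NULL,
                          mode = c("nonexclusive", "exclusive")) {
  mode <- match.arg(mode)
  if (is.character(calls)) calls <- read_calls_tsv(calls)
  summary <- aggregate_species(calls, mode = mode)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_commented(summary$by_group,
                        file.path(out_dir, "summary_by_group.tsv"),
                        paste("counting mode:", mode))
    write_tsv_commented(summary$any_error,
                        file.path(out_dir, "summary_any_error.tsv"),
                        paste("counting mode:", mode))
  }
  summary
}

#' Generate a fixture directory
#'
#' Builds a synthetic fixture ([make_fixture()]) and writes it to disk
#' ([write_fixture()]).
#'
#' @param config [sim_config()] or path to a YAML file of its fields.
#' @param out_dir output directory.
#' @param type defect type, see [make_fixture()].
#' @param ... passed to [make_fixture()] (defect geometry).
#' @return the [ig_fixture][make_fixture], invisibly.
#' @export
run_simulate <- function(config, out_dir,
                         type = c("clean", "deletion", "inversion"), ...) {
  type <- match.arg(type)
  if (is.character(config)) config <- do.call(sim_config,
                                              yaml::read_yaml(config))
  fixture <- make_fixture(type, config, ...)
  write_fixture(fixture, out_dir)
  invisible(fixture)
}

#' Shell out to minimap2 (optional plumbing)
#'
#' Convenience wrapper running `minimap2 -ax map-pb` and samtools
#' sort/index to produce a coordinate-sorted BAM. Untested plumbing: it
#' requires the external binaries on PATH and is provided only so the
#' pipeline can be pointed at real read sets; all shipped tests use the
#' oracle placement instead.
#'
#' @param assembly_fasta,reads_fastq input paths.
#' @param out_bam output BAM path.
#' @param threads minimap2/samtools threads.
#' @return `out_bam`, invisibly.
#' @export
align_with_minimap2 <- function(assembly_fasta, reads_fastq, out_bam,
                                threads = 1L) {
  if (Sys.which("minimap2") == "" || Sys.which("samtools") == "")
    stop("minimap2 and samtools must be on PATH")
  cmd <- sprintf(
    "minimap2 -t %d -ax map-pb %s %s | samtools sort -@ %d -o %s - && samtools index %s",
    threads, shQuote(assembly_fasta), shQuote(reads_fastq), threads,
    shQuote(out_bam), shQuote(out_bam))
  status <- system(cmd)
  if (status != 0) stop("alignment pipeline failed (exit ", status, ")")
  invisible(out_bam)
}
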