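.LOCUS_CLASSES <- c("IGH", "IGK", "IGL")
.SEGMENT_TYPES <- c("V", "D", "J")

#' Load IG locus intervals
#'
#' Reads locus intervals from a BED4 file (0-based half-open, the native
#' internal convention) or an IgDetective-style table with columns
#' `contig`, `start`, `end`, `locus` (declare its coordinate dialect with
#' `coords`). Intervals are validated against the assembly and assigned a
#' haplotype label from contig-name patterns, since assemblies encode
#' haplotype identity inconsistently.
#'
#' @param path path to a `.bed` file or a tab-separated table.
#' @param assembly an [ig_assembly][load_assembly] used for bounds checks.
#' @param format `"auto"` (by extension), `"bed"`, or `"table"`.
#' @param coords coordinate dialect of a `"table"` input: `"zero_half_open"`
#'   or `"one_inclusive"` (shifted internally). BED is always 0-based.
#' @param haplotype_patterns named character vector mapping regular
#'   expressions on contig names to haplotype labels, e.g.
#'   `c("hap1|^h1" = "primary", "hap2|^h2" = "alternate")`. First match
#'   wins; unmatched contigs get label `"unassigned"`.
#' @return data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `locus` (IGH/IGK/IGL), `haplotype`.
#' @export
load_loci <- function(path, assembly,
                      format = c("auto", "bed", "table"),
                      coords = c("zero_half_open", "one_inclusive"),
                      haplotype_patterns = NULL) {
  format <- match.arg(format)
  coords <- match.arg(coords)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "table"
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     locus = gr$name %||% NA_character_,
                     stringsAsFactors = FALSE)
  } else {
    df <- read_tsv_commented(path)
    need <- c("contig", "start", "end", "locus")
    if (!all(need %in% names(df)))
      stop("locus table must have columns: ", paste(need, collapse = ", "))
    df <- df[, need]
    if (coords == "one_inclusive") df$start <- df$start - 1L
  }
  df$locus <- toupper(df$locus)
  bad_locus <- !df$locus %in% .LOCUS_CLASSES
  if (any(bad_locus))
    stop("unknown locus label(s): ", paste(unique(df$locus[bad_locus]),
                                           collapse = ", "))
  validate_intervals(df, assembly, what = "locus interval")
  df$haplotype <- haplotype_label(df$contig, haplotype_patterns)
  df
}

#' Load gene annotations
#'
#' Reads a V/D/J gene annotation table (columns `gene_id`, `segment_type`,
#' `contig`, `start`, `end`, `strand`) and validates it against the
#' assembly and, optionally, its parent loci.
#'
#' @inheritParams load_loci
#' @param loci optional data.frame from [load_loci()]; when given, every
#'   gene must fall within a locus interval on its contig.
#' @return data.frame with the input columns, coordinates 0-based
#'   half-open.
#' @export
load_genes <- function(path, assembly,
                       coords = c("zero_half_open", "one_inclusive"),
                       loci = NULL) {
  coords <- match.arg(coords)
  df <- read_tsv_commented(path)
  need <- c("gene_id", "segment_type", "contig", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (coords == "one_inclusive") df$start <- df$start - 1L
  df$segment_type <- toupper(df$segment_type)
  if (!all(df$segment_type %in% .SEGMENT_TYPES))
    stop("segment_type must be one of V, D, J")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  validate_intervals(df, assembly, what = "gene")
  if (!is.null(loci)) {
    inside <- vapply(seq_len(nrow(df)), function(i) {
      l <- loci[loci$contig == df$contig[i], , drop = FALSE]
      any(l$start <= df$start[i] & l$end >= df$end[i])
    }, logical(1))
    if (!all(inside))
      stop("gene(s) outside any locus interval: ",
           paste(df$gene_id[!inside], collapse = ", "))
  }
  df
}

validate_intervals <- function(df, assembly, what = "interval") {
  unknown <- !df$contig %in% names(assembly$lengths)
  if (any(unknown))
    stop(what, " on unknown contig(s): ",
         paste(unique(df$contig[unknown]), collapse = ", "))
  len <- assembly$lengths[df$contig]
  bad <- df$start < 0 | df$start >= df$end | df$end > len
  if (any(bad)) {
    i <- which(bad)[1]
    stop(what, " out of bounds: ", df$contig[i], ":", df$start[i], "-",
         df$end[i], " (contig length ", len[i], ")")
  }
  invisible(TRUE)
}

haplotype_label <- function(contigs, patterns = NULL) {
  if (is.null(patterns))
    patterns <- c("hap1|h1tg|^pri|primary" = "primary",
                  "hap2|h2tg|^alt|alternate" = "alternate")
  out <- rep("unassigned", length(contigs))
  for (p in names(patterns)) {
    hit <- out == "unassigned" & grepl(p, contigs, ignore.case = TRUE)
    out[hit] <- patterns[[p]]
  }
  out
}
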