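#' Simulation configuration
#'
#' Parameters of the synthetic diploid IG-like locus and HiFi-like read
#' simulator. Defaults are desk-scale study conditions that preserve the
#' error signatures of real 1-2.5 Mb IG loci with 15-25 kb reads at a
#' fraction of the compute: a 120 kb locus per haplotype carrying 8
#' tandem gene cassettes of 6 kb, 2% inter-haplotype divergence (IG loci
#' are highly heterozygous), reads of mean 3.5 kb (sd 800, min 1.5 kb)
#' with 0.2% substitution error (HiFi error is below 0.5%), at 30x per
#' haplotype.
#'
#' @param seed integer seed; every downstream draw is reproducible from
#'   it.
#' @param locus_length haplotype length in bp.
#' @param n_cassettes,cassette_length number and size of tandem
#'   gene-cassette repeats embedded in haplotype 1.
#' @param cassette_divergence substitution fraction between cassette
#'   copies (paralog identity).
#' @param divergence inter-haplotype substitution fraction.
#' @param cassette_cnv number of trailing cassettes removed from
#'   haplotype 2 (copy-number difference between haplotypes). Default 0.
#' @param read_length_mean,read_length_sd,read_length_min read length
#'   distribution (truncated normal), bp.
#' @param error_rate per-base substitution error rate of simulated
#'   reads.
#' @param depth target mean depth per haplotype.
#' @return list of class `ig_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       locus_length = 120000L,
                       n_cassettes = 8L,
                       cassette_length = 6000L,
                       cassette_divergence = 0.05,
                       divergence = 0.02,
                       cassette_cnv = 0L,
                       read_length_mean = 3500,
                       read_length_sd = 800,
                       read_length_min = 1500,
                       error_rate = 0.002,
                       depth = 30) {
  cfg <- list(seed = as.integer(seed), locus_length = as.integer(locus_length),
              n_cassettes = as.integer(n_cassettes),
              cassette_length = as.integer(cassette_length),
              cassette_divergence = cassette_divergence,
              divergence = divergence, cassette_cnv = as.integer(cassette_cnv),
              read_length_mean = read_length_mean,
              read_length_sd = read_length_sd,
              read_length_min = read_length_min,
              error_rate = error_rate, depth = depth)
  stopifnot(cfg$locus_length > 0, cfg$depth >= 1,
            cfg$divergence >= 0, cfg$divergence < 1,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$cassette_divergence >= 0, cfg$cassette_divergence < 1,
            cfg$read_length_min > 0, cfg$cassette_cnv >= 0,
            cfg$cassette_cnv <= cfg$n_cassettes)
  structure(cfg, class = "ig_sim_config")
}

.BASES <- c("A", "C", "G", "T")

random_dna_chars <- function(n) sample(.BASES, n, replace = TRUE)

## substitute chars at 1-based idx with a different base
substitute_chars <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  cur <- chars[idx]
  new <- vapply(cur, function(b) sample(setdiff(.BASES, b), 1L), "")
  chars[idx] <- new
  chars
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate a diploid IG-like locus
#'
#' Builds haplotype 1 as a random background sequence carrying
#' `n_cassettes` tandem gene cassettes (copies of a template diverged at
#' `cassette_divergence`, each containing a V, a D and a J segment) and
#' haplotype 2 as haplotype 1 substituted at rate `divergence`,
#' optionally with trailing cassettes deleted (`cassette_cnv`). The two
#' haplotypes share coordinates over the region up to the copy-number
#' deletion point (`hom_len`), which downstream code uses to map
#' homologous positions.
#'
#' @param config [sim_config()].
#' @param seed seed (defaults to `config$seed`).
#' @return list of class `ig_sim_genome`: `seqs` (named character,
#'   `hap1`/`hap2`), `genes` (annotation data.frame over both
#'   haplotypes, 0-based half-open), `div_pos` (0-based shared-frame
#'   positions where the haplotypes differ), `hom_len`, `cassettes`
#'   (intervals on hap1), `config`.
#' @export
generate_diploid_locus <- function(config, seed = config$seed) {
  set.seed(seed)
  L <- config$locus_length
  block <- config$n_cassettes * config$cassette_length
  cass_start <- floor(0.2 * L)
  if (cass_start + block > floor(0.95 * L))
    stop("infeasible config: ", config$n_cassettes, " cassettes of ",
         config$cassette_length, " bp exceed the locus")
  h1 <- random_dna_chars(L)
  template <- random_dna_chars(config$cassette_length)
  cassettes <- data.frame(cassette = seq_len(config$n_cassettes),
                          start = cass_start +
                            (seq_len(config$n_cassettes) - 1L) *
                            config$cassette_length)
  cassettes$end <- cassettes$start + config$cassette_length
  for (k in seq_len(config$n_cassettes)) {
    n_sub <- rbinom(1L, config$cassette_length, config$cassette_divergence)
    copy <- substitute_chars(template,
                             sort(sample(config$cassette_length, n_sub)))
    h1[(cassettes$start[k] + 1L):cassettes$end[k]] <- copy
  }
  genes1 <- do.call(rbind, lapply(seq_len(config$n_cassettes), function(k) {
    cs <- cassettes$start[k]
    data.frame(
      gene_id = paste0("hap1_IGH", c("V", "D", "J"), k),
      segment_type = c("V", "D", "J"),
      contig = "hap1",
      start = cs + c(500L, 2500L, 4000L),
      end = cs + c(800L, 2528L, 4060L),
      strand = c("+", "+", "-"),
      stringsAsFactors = FALSE)
  }))

  n_div <- rbinom(1L, L, config$divergence)
  div_pos <- sort(sample(L, n_div)) - 1L   # 0-based
  h2 <- substitute_chars(h1, div_pos + 1L)
  genes2 <- genes1
  genes2$contig <- "hap2"
  genes2$gene_id <- sub("^hap1", "hap2", genes2$gene_id)

  hom_len <- L
  if (config$cassette_cnv > 0L) {
    del_from <- cassettes$start[config$n_cassettes - config$cassette_cnv + 1L]
    del_to <- cassettes$end[config$n_cassettes]
    h2 <- h2[-((del_from + 1L):del_to)]
    genes2 <- lift_genes_deletion(genes2, "hap2", del_from, del_to)
    div_pos <- div_pos[div_pos < del_from]
    hom_len <- del_from
  }
  structure(list(
    seqs = c(hap1 = paste(h1, collapse = ""),
             hap2 = paste(h2, collapse = "")),
    genes = rbind(genes1, genes2),
    div_pos = div_pos,
    hom_len = hom_len,
    cassettes = cassettes,
    config = config),
    class = "ig_sim_genome")
}

## drop genes overlapping [ds, de) on `contig`, shift downstream ones left
lift_genes_deletion <- function(genes, contig, ds, de) {
  on <- genes$contig == contig
  hit <- on & genes$start < de & genes$end > ds
  genes <- genes[!hit, , drop = FALSE]
  shift <- genes$contig == contig & genes$start >= de
  genes$start[shift] <- genes$start[shift] - (de - ds)
  genes$end[shift] <- genes$end[shift] - (de - ds)
  rownames(genes) <- NULL
  genes
}

#' Simulate HiFi-like reads
#'
#' Draws reads uniformly along each sequence at the configured depth,
#' with lengths from a truncated normal and i.i.d. substitution errors
#' at the configured rate. Every read records its true origin.
#'
#' @param seqs named character vector of source sequences (usually
#'   `genome$seqs`).
#' @param config [sim_config()].
#' @param seed seed for the read draws.
#' @return data.frame of class `ig_sim_reads`: `read_id`,
#'   `source_contig`, `start`, `end` (0-based half-open origin),
#'   `length`, `n_errors`, `seq`, plus list-column `err_offsets`
#'   (1-based offsets within the read).
#' @export
simulate_reads <- function(seqs, config, seed = config$seed + 1L) {
  set.seed(seed)
  out <- lapply(names(seqs), function(ctg) {
    L <- nchar(seqs[[ctg]])
    n <- ceiling(config$depth * L / config$read_length_mean)
    len <- as.integer(pmin(L, pmax(config$read_length_min,
                                   round(rnorm(n, config$read_length_mean,
                                               config$read_length_sd)))))
    start <- as.integer(floor(runif(n, 0, L - len + 1)))   # 0-based
    seq <- substring(seqs[[ctg]], start + 1L, start + len)
    n_err <- rbinom(n, len, config$error_rate)
    err <- vector("list", n)
    for (i in which(n_err > 0L)) {
      off <- sort(sample(len[i], n_err[i]))
      chars <- substitute_chars(strsplit(seq[i], "")[[1]], off)
      seq[i] <- paste(chars, collapse = "")
      err[[i]] <- off
    }
    err[n_err == 0L] <- list(integer(0))
    df <- data.frame(read_id = sprintf("%s_r%05d", ctg, seq_len(n)),
                     source_contig = ctg, start = start,
                     end = start + len, length = len, n_errors = n_err,
                     seq = seq, stringsAsFactors = FALSE)
    df$err_offsets <- err
    df
  })
  structure(do.call(rbind, out), class = c("ig_sim_reads", "data.frame"))
}

#' Inject a missing-segment defect
#'
#' Deletes `[start, end)` of one haplotype from the evaluated assembly
#' while reads remain simulated from the full genome -- the
#' missing-sequence error archetype: reads from the deleted segment can
#' only align to the retained homolog, producing clusters of poorly
#' aligned reads and locally elevated depth there. Gene annotations are
#' lifted (overlapping genes dropped, downstream genes shifted). A
#' zero-length interval leaves the assembly unchanged.
#'
#' @param genome [ig_sim_genome][generate_diploid_locus].
#' @param contig haplotype to delete from (must lie within the
#'   coordinate-shared region of the two haplotypes).
#' @param start,end 0-based half-open interval to delete.
#' @return list of class `ig_sim_assembly`: `seqs`, `genes`, `defect`
#'   (kind `"deleted_segment"`, the interval, and the homologous
#'   interval on the retained haplotype).
#' @export
inject_missing_segment <- function(genome, contig = "hap2",
                                   start, end) {
  stopifnot(contig %in% names(genome$seqs))
  start <- as.integer(start); end <- as.integer(end)
  L <- nchar(genome$seqs[[contig]])
  if (start < 0 || end > L || start > end)
    stop("deletion interval out of bounds: ", contig, ":", start, "-", end)
  if (end > genome$hom_len)
    stop("deletion interval must lie within the coordinate-shared region ",
         "(first ", genome$hom_len, " bp)")
  seqs <- genome$seqs
  genes <- genome$genes
  defect <- NULL
  if (end > start) {
    s <- seqs[[contig]]
    seqs[[contig]] <- paste0(substr(s, 1L, start), substr(s, end + 1L, L))
    genes <- lift_genes_deletion(genes, contig, start, end)
    homolog <- setdiff(names(genome$seqs), contig)[1]
    defect <- list(kind = "deleted_segment", contig = contig,
                   start = start, end = end,
                   homolog_contig = homolog,
                   homolog_start = start, homolog_end = end)
  }
  structure(list(seqs = seqs, genes = genes, defect = defect),
            class = "ig_sim_assembly")
}

#' Inject an inversion with an N-gap at the breakpoint
#'
#' Reverse-complements `[start, end)` of one haplotype in the evaluated
#' assembly and replaces the first `gap_len` bases of the inverted
#' segment with Ns, emulating a false inversion introduced at a
#' scaffolding join. Reads remain simulated from the original
#' orientation, so reads crossing a breakpoint cannot be placed and the
#' planted gap shows up as a coverage break overlapping an N-run.
#' Applying the same inversion twice restores the original sequence
#' (gap aside).
#'
#' @inheritParams inject_missing_segment
#' @param gap_len length (bp) of the planted N-run, >= 1.
#' @return list of class `ig_sim_assembly` with `defect` of kind
#'   `"inversion"` recording the interval and the gap interval.
#' @export
inject_inversion_with_gap <- function(genome, contig = "hap1",
                                      start, end, gap_len = 200L) {
  stopifnot(contig %in% names(genome$seqs), gap_len >= 1L)
  start <- as.integer(start); end <- as.integer(end)
  gap_len <- as.integer(gap_len)
  L <- nchar(genome$seqs[[contig]])
  if (start < 0 || end > L || start >= end)
    stop("inversion interval out of bounds: ", contig, ":", start, "-", end)
  if (gap_len > end - start) stop("gap_len exceeds inversion length")
  s <- genome$seqs[[contig]]
  seg <- revcomp(substr(s, start + 1L, end))
  seg <- paste0(strrep("N", gap_len), substr(seg, gap_len + 1L, end - start))
  seqs <- genome$seqs
  seqs[[contig]] <- paste0(substr(s, 1L, start), seg,
                           substr(s, end + 1L, L))
  genes <- genome$genes
  on <- genes$contig == contig
  cross <- on & ((genes$start < start & genes$end > start) |
                   (genes$start < end & genes$end > end))
  genes <- genes[!cross, , drop = FALSE]
  inside <- genes$contig == contig & genes$start >= start & genes$end <= end
  if (any(inside)) {
    ns <- start + (end - genes$end[inside])
    ne <- start + (end - genes$start[inside])
    genes$start[inside] <- ns
    genes$end[inside] <- ne
    genes$strand[inside] <- ifelse(genes$strand[inside] == "+", "-", "+")
  }
  rownames(genes) <- NULL
  structure(list(seqs = seqs, genes = genes,
                 defect = list(kind = "inversion", contig = contig,
                               start = start, end = end,
                               gap_len = gap_len,
                               gap_start = start, gap_end = start + gap_len)),
            class = "ig_sim_assembly")
}

#' Oracle read placement
#'
#' Places simulated reads onto the evaluated assembly at their known
#' origins, with recorded edits -- a hermetic stand-in for an external
#' aligner so unit tests need no binaries. Placement rules at injected
#' defects mirror what a long-read aligner does to full-length reads:
#' reads overlapping a deleted segment are placed full-length on the
#' retained homolog (divergence sites become substitutions); reads
#' crossing an inversion breakpoint, or whose placement would overlap
#' the planted N-run, are unplaceable and dropped. A read whose origin
#' span contains no inter-haplotype divergence site is ambiguous between
#' haplotypes and gets MAPQ 0 (placed at its origin); all other reads
#' get MAPQ 60. CIGARs are full-length matches; MD/NM tags are computed
#' against the assembly.
#'
#' @param reads [ig_sim_reads][simulate_reads].
#' @param genome [ig_sim_genome][generate_diploid_locus].
#' @param assembly_spec [ig_sim_assembly][inject_missing_segment], or
#'   NULL for the defect-free assembly (the genome itself).
#' @return record data.frame (the [read_alignments()] schema); ids of
#'   dropped (unplaceable) reads in attribute `dropped`.
#' @export
align_reads_oracle <- function(reads, genome, assembly_spec = NULL) {
  if (is.null(assembly_spec))
    assembly_spec <- structure(list(seqs = genome$seqs,
                                    genes = genome$genes, defect = NULL),
                               class = "ig_sim_assembly")
  defect <- assembly_spec$defect
  aseqs <- assembly_spec$seqs
  n <- nrow(reads)
  tgt_contig <- reads$source_contig
  tgt_start <- reads$start
  strand <- rep("+", n)
  drop <- rep(FALSE, n)

  if (!is.null(defect) && defect$kind == "deleted_segment") {
    on <- reads$source_contig == defect$contig
    after <- on & reads$start >= defect$end
    tgt_start[after] <- reads$start[after] - (defect$end - defect$start)
    hit <- on & reads$start < defect$end & reads$end > defect$start
    tgt_contig[hit] <- defect$homolog_contig
    ## identity coordinates on the homolog
  } else if (!is.null(defect) && defect$kind == "inversion") {
    on <- reads$source_contig == defect$contig
    inside <- on & reads$start >= defect$start & reads$end <= defect$end
    crossing <- on & !inside &
      reads$start < defect$end & reads$end > defect$start
    drop[crossing] <- TRUE
    tgt_start[inside] <- defect$start + (defect$end - reads$end[inside])
    strand[inside] <- "-"
    ## placement over the planted N-run is impossible
    drop[inside & tgt_start < defect$gap_end] <- TRUE
  }

  ## MAPQ: ambiguous between haplotypes unless the origin span contains a
  ## divergence site (spans beyond the shared frame are unique)
  mapq <- rep(60L, n)
  if (length(genome$div_pos)) {
    has_div <- vapply(seq_len(n), function(i) {
      reads$end[i] > genome$hom_len ||
        any(genome$div_pos >= reads$start[i] & genome$div_pos < reads$end[i])
    }, logical(1))
  } else {
    has_div <- reads$end > genome$hom_len
  }
  mapq[!has_div] <- 0L

  keep <- which(!drop)
  recs <- lapply(keep, function(i) {
    len <- reads$length[i]
    sq <- if (strand[i] == "-") revcomp(reads$seq[i]) else reads$seq[i]
    ref <- substr(aseqs[[tgt_contig[i]]], tgt_start[i] + 1L,
                  tgt_start[i] + len)
    a <- strsplit(sq, "")[[1]]
    b <- strsplit(ref, "")[[1]]
    mm <- which(a != b)
    list(qname = reads$read_id[i],
         flag = if (strand[i] == "-") 16L else 0L,
         contig = tgt_contig[i], start = tgt_start[i],
         end = tgt_start[i] + len, mapq = mapq[i],
         cigar = paste0(len, "M"), seq = sq,
         md = make_md(b, mm), nm = length(mm),
         strand = strand[i], is_supplementary = FALSE)
  })
  out <- data.frame(
    qname = vapply(recs, `[[`, "", "qname"),
    flag = vapply(recs, `[[`, 0L, "flag"),
    contig = vapply(recs, `[[`, "", "contig"),
    start = vapply(recs, `[[`, 0L, "start"),
    end = vapply(recs, `[[`, 0L, "end"),
    mapq = vapply(recs, `[[`, 0L, "mapq"),
    cigar = vapply(recs, `[[`, "", "cigar"),
    seq = vapply(recs, `[[`, "", "seq"),
    md = vapply(recs, `[[`, "", "md"),
    nm = vapply(recs, `[[`, 0L, "nm"),
    strand = vapply(recs, `[[`, "", "strand"),
    is_supplementary = vapply(recs, `[[`, FALSE, "is_supplementary"),
    stringsAsFactors = FALSE)
  attr(out, "dropped") <- reads$read_id[drop]
  out
}

## MD string for an all-M alignment: refchars and 1-based mismatch offsets
make_md <- function(refchars, mm_idx) {
  if (length(mm_idx) == 0L) return(as.character(length(refchars)))
  parts <- character(0)
  prev <- 0L
  for (i in mm_idx) {
    parts <- c(parts, as.character(i - prev - 1L), refchars[i])
    prev <- i
  }
  paste0(paste(parts, collapse = ""), length(refchars) - prev)
}

#' Build a complete synthetic fixture
#'
#' One call generates the diploid locus, simulates reads, optionally
#' injects a defect, places the reads with the oracle aligner and wraps
#' everything as pipeline-ready inputs plus machine-readable truth.
#' For `type = "clean"` reads are simulated from the evaluated assembly
#' itself (the error-free control); for `"deletion"` and `"inversion"`
#' reads come from the full genome while the assembly carries the
#' defect.
#'
#' @param type `"clean"`, `"deletion"` or `"inversion"`.
#' @param config [sim_config()].
#' @param defect_start 0-based start of the injected defect (default:
#'   mid-locus).
#' @param defect_len defect length in bp (default 20000).
#' @param gap_len N-run length for inversions (default 200).
#' @return list of class `ig_fixture`: `config`, `type`, `genome`,
#'   `assembly` ([ig_assembly][as_assembly] of the evaluated sequences),
#'   `genes` (annotations on the evaluated assembly), `loci`, `reads`,
#'   `records` (oracle placements), `truth` (defect + per-read origins +
#'   dropped read ids).
#' @export
make_fixture <- function(type = c("clean", "deletion", "inversion"),
                         config = sim_config(),
                         defect_start = NULL, defect_len = 20000L,
                         gap_len = 200L) {
  type <- match.arg(type)
  genome <- generate_diploid_locus(config)
  L <- config$locus_length
  spec <- switch(
    type,
    clean = NULL,
    deletion = {
      ds <- defect_start %||% floor(0.45 * L)
      inject_missing_segment(genome, "hap2", ds, ds + defect_len)
    },
    inversion = {
      is <- defect_start %||% floor(0.40 * L)
      inject_inversion_with_gap(genome, "hap1", is, is + defect_len,
                                gap_len = gap_len)
    })
  src_seqs <- if (type == "clean") genome$seqs else genome$seqs
  reads <- simulate_reads(src_seqs, config, seed = config$seed + 1L)
  records <- align_reads_oracle(reads, genome, spec)
  aseqs <- if (is.null(spec)) genome$seqs else spec$seqs
  agenes <- if (is.null(spec)) genome$genes else spec$genes
  assembly <- as_assembly(aseqs)
  loci <- data.frame(contig = names(aseqs),
                     start = 0L,
                     end = unname(nchar(aseqs)),
                     locus = "IGH",
                     haplotype = c("primary", "alternate")[
                       seq_along(aseqs)],
                     stringsAsFactors = FALSE)
  structure(list(config = config, type = type, genome = genome,
                 assembly = assembly, genes = agenes, loci = loci,
                 reads = reads, records = records,
                 truth = list(defect = if (is.null(spec)) NULL else
                   spec$defect,
                   reads = reads[, c("read_id", "source_contig", "start",
                                     "end", "n_errors")],
                   dropped = attr(records, "dropped"))),
            class = "ig_fixture")
}

#' Write a fixture to disk
#'
#' Serializes a fixture as plain-text standard formats: the true genome
#' and evaluated assembly (FASTA), reads (FASTQ), oracle alignments
#' (SAM), gene annotations and loci (TSV/BED), defect and per-read truth
#' (TSV), and the configuration (YAML).
#'
#' @param fixture [ig_fixture][make_fixture].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fixture$genome$seqs), p("genome.fasta"))
  Biostrings::writeXStringSet(fixture$assembly$seqs, p("assembly.fasta"))
  reads <- Biostrings::DNAStringSet(setNames(fixture$reads$seq,
                                             fixture$reads$read_id))
  quals <- Biostrings::BStringSet(strrep("~", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, p("reads.fastq"), format = "fastq",
                              qualities = quals)
  write_tsv_commented(fixture$genes, p("genes.tsv"),
                      "gene annotations on the evaluated assembly; 0-based half-open")
  gr <- GenomicRanges::GRanges(fixture$loci$contig,
                               .ir(fixture$loci$start, fixture$loci$end),
                               name = fixture$loci$locus)
  rtracklayer::export(gr, p("loci.bed"), format = "BED")
  if (!is.null(fixture$truth$defect)) {
    d <- fixture$truth$defect
    write_tsv_commented(
      data.frame(kind = d$kind, contig = d$contig, start = d$start,
                 end = d$end, stringsAsFactors = FALSE),
      p("truth_defect.tsv"), "injected defect; 0-based half-open")
  }
  write_tsv_commented(fixture$truth$reads, p("truth_reads.tsv"),
                      "per-read origin truth; 0-based half-open")
  write_sam(fixture$records, fixture$assembly, p("alignments.sam"))
  yaml::write_yaml(unclass(fixture$config), p("config.yaml"))
  invisible(dir)
}
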