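# Independent brute-force oracles and shared fixtures for the suite.
# Oracles deliberately avoid the package's IRanges/vectorised code paths:
# they recount per position / per character with plain loops.

make_record <- function(qname = "r1", contig = "c1", start = 0L, cigar,
                        seq, mapq = 60L, md = NA_character_,
                        nm = NA_integer_, flag = 0L) {
  data.frame(
    qname = qname, flag = flag, contig = contig, start = start,
    end = start + GenomicAlignments::cigarWidthAlongReferenceSpace(cigar),
    mapq = mapq, cigar = cigar, seq = seq, md = md, nm = nm,
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    is_supplementary = bitwAnd(flag, 2048L) > 0,
    stringsAsFactors = FALSE)
}

# character-at-a-time walk of one record against the reference; the
# dumbest possible implementation of the mismatch/indel/clip bookkeeping
naive_read_compare <- function(record, assembly) {
  ops <- strsplit(gsub("([0-9]+)([MIDNSHP=X])", "\\2 ", record$cigar),
                  " ")[[1]]
  lens <- as.integer(strsplit(gsub("([0-9]+)([MIDNSHP=X])", "\\1 ",
                                   record$cigar), " ")[[1]])
  refc <- strsplit(as.character(assembly$seqs[[record$contig]]), "")[[1]]
  readc <- strsplit(record$seq, "")[[1]]
  rpos <- record$start + 1L   # 1-based index into refc
  qpos <- 1L
  subs <- integer(0); aligned <- 0L; soft <- 0L; hard <- 0L
  dels <- list()
  for (k in seq_along(ops)) {
    for (step in seq_len(lens[k])) {
      if (ops[k] %in% c("M", "=", "X")) {
        aligned <- aligned + 1L
        if (readc[qpos] != refc[rpos] && refc[rpos] != "N")
          subs <- c(subs, rpos - 1L)
        rpos <- rpos + 1L; qpos <- qpos + 1L
      } else if (ops[k] == "I") {
        qpos <- qpos + 1L
      } else if (ops[k] %in% c("D", "N")) {
        rpos <- rpos + 1L
      } else if (ops[k] == "S") {
        soft <- soft + 1L; qpos <- qpos + 1L
      } else if (ops[k] == "H") {
        hard <- hard + 1L
      }
    }
  }
  list(substitutions = length(subs), mm_pos = subs, aligned = aligned,
       soft = soft, hard = hard)
}

# per-position recount of every pileup column with plain loops over reads
# (valid for the oracle-placed fixtures, whose CIGARs are all-match)
brute_pileup <- function(records, assembly, locus, theta = 0.01) {
  stopifnot(all(grepl("^[0-9]+M$", records$cigar)))
  w <- locus$end - locus$start
  depth <- delta <- e_count <- m60 <- mmid <- m0 <- integer(w)
  refc <- strsplit(as.character(assembly$seqs[[locus$contig]]), "")[[1]]
  r <- records[records$contig == locus$contig &
                 records$start < locus$end & records$end > locus$start, ]
  for (i in seq_len(nrow(r))) {
    s <- r$start[i]; e <- r$end[i]
    readc <- strsplit(r$seq[i], "")[[1]]
    ref_i <- refc[(s + 1L):e]
    mm <- which(readc != ref_i & ref_i != "N")
    er <- length(mm) / (e - s)
    idx <- (max(s, locus$start) - locus$start + 1L):
      (min(e, locus$end) - locus$start)
    depth[idx] <- depth[idx] + 1L
    if (er > theta) e_count[idx] <- e_count[idx] + 1L
    if (r$mapq[i] == 60) m60[idx] <- m60[idx] + 1L
    else if (r$mapq[i] == 0) m0[idx] <- m0[idx] + 1L
    else mmid[idx] <- mmid[idx] + 1L
    mm_abs <- s + mm - 1L
    mm_in <- mm_abs[mm_abs >= locus$start & mm_abs < locus$end]
    for (p in mm_in) delta[p - locus$start + 1L] <-
        delta[p - locus$start + 1L] + 1L
  }
  list(depth = depth, delta = delta, e_count = e_count,
       mapq60 = m60, mapq_mid = mmid, mapq0 = m0)
}

# fixtures are expensive; build each once per test run
.fx_cache <- new.env(parent = emptyenv())
cached_fixture <- function(type, seed, ...) {
  key <- paste(type, seed, ...)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_fixture(type, sim_config(seed = seed, ...))
  .fx_cache[[key]]
}

evaluate_fixture <- function(fx, opts = qc_options()) {
  evaluate_assembly(fx$assembly, fx$loci, fx$genes, fx$records, opts)
}

cached_eval <- function(type, seed, ...) {
  key <- paste("eval", type, seed, ...)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- evaluate_fixture(cached_fixture(type, seed, ...))
  .fx_cache[[key]]
}

# the study-condition clean control: 100 kb per haplotype at 25x
clean_control_fixture <- function() cached_fixture("clean", 101,
                                                   locus_length = 100000,
                                                   depth = 25)
clean_control_eval <- function() cached_eval("clean", 101,
                                             locus_length = 100000,
                                             depth = 25)

# construct a calls table realizing given per-group counts; `both`
# species carry the mismatch and break flags simultaneously
calls_for_group <- function(locus, resolution, n, mm, bk, both, prefix) {
  n_err <- mm + bk - both
  flags <- data.frame(mismatch_flag = rep(FALSE, n),
                      break_flag = rep(FALSE, n))
  if (mm > 0) flags$mismatch_flag[seq_len(mm)] <- TRUE
  if (bk > 0) flags$break_flag[mm - both + seq_len(bk)] <- TRUE
  stopifnot(sum(flags$mismatch_flag | flags$break_flag) == n_err)
  data.frame(species = paste0(prefix, seq_len(n)), locus = locus,
             resolution = resolution, flags, stringsAsFactors = FALSE)
}

# per-group counts of the published cross-species survey:
# group total, mismatch, break, overlap
survey_calls <- function() {
  rbind(
    calls_for_group("IGH", "resolved",   26,  1, 15,  1, "hr"),
    calls_for_group("IGH", "unresolved", 48, 24, 15, 11, "hu"),
    calls_for_group("IGK", "resolved",   21,  1,  3,  1, "kr"),
    calls_for_group("IGK", "unresolved", 36,  9,  4,  3, "ku"),
    calls_for_group("IGL", "resolved",   23,  2,  7,  2, "lr"),
    calls_for_group("IGL", "unresolved", 38, 17, 12,  7, "lu"))
}

# a small deterministic assembly for unit tests
toy_assembly <- function() {
  set.seed(42)
  as_assembly(c(
    c1 = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = ""),
    c2 = paste0(paste(rep("ACGT", 30), collapse = ""), strrep("N", 12),
                paste(rep("TTGA", 30), collapse = ""))))
}
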