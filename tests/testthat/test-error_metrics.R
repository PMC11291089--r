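pileup_from_depths <- function(depth, contig = "c1", start = 0L,
                               e_count = rep(0L, length(depth)),
                               delta = rep(0L, length(depth)),
                               deleted = rep(0L, length(depth))) {
  structure(
    data.frame(contig = contig, pos = seq.int(start, start + length(depth) - 1L),
               depth = depth, delta = delta, deleted = deleted,
               e_count = e_count, mapq60 = depth, mapq_mid = 0L, mapq0 = 0L,
               support = ifelse(depth > 0, (depth - delta) / depth, NA)),
    class = c("ig_pileup", "data.frame"),
    locus = list(contig = contig, start = start,
                 end = start + length(depth)),
    theta = 0.01)
}

test_that("a single matching read yields depth 1, no errors", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 100)))
  rec <- make_record("r", "c1", 50L, "100M",
                     assembly_subseq(asm, "c1", 50L, 150L))
  st <- compute_read_stats(rec, asm, method = "basewalk")
  p <- build_pileup(st, list(contig = "c1", start = 0L, end = 400L))
  expect_equal(sum(p$depth), 100L)
  expect_true(all(p$depth[51:150] == 1L))
  expect_equal(sum(p$delta), 0L)
  expect_equal(sum(p$e_count), 0L)
})

test_that("13 covering reads with 3 mismatching bases give 76.9% support", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 50)))
  ref <- assembly_subseq(asm, "c1", 0L, 100L)
  target <- 40L   # 0-based position under test; ref base there is 'A'
  expect_equal(substr(ref, 41, 41), "A")
  recs <- do.call(rbind, lapply(1:13, function(i) {
    ch <- strsplit(ref, "")[[1]]
    if (i <= 3) ch[41] <- "G"
    make_record(paste0("r", i), "c1", 0L, "100M", paste(ch, collapse = ""))
  }))
  st <- compute_read_stats(recs, asm, method = "basewalk")
  p <- build_pileup(st, list(contig = "c1", start = 0L, end = 200L))
  expect_equal(p$depth[target + 1L], 13L)
  expect_equal(p$delta[target + 1L], 3L)
  expect_equal(round(100 * p$support[target + 1L], 1), 76.9)
})

test_that("position flagging is strict in E and merges adjacent runs", {
  e <- rep(0L, 30); e[11:13] <- 6L; e[14] <- 5L; e[20] <- 7L
  p <- pileup_from_depths(rep(20L, 30), e_count = e)
  fl <- flag_poorly_supported(p, min_bad_reads = 5L)
  expect_equal(fl$positions, c(10L, 11L, 12L, 19L))   # E = 5 not flagged
  expect_equal(fl$intervals$start, c(10L, 19L))
  expect_equal(fl$intervals$end, c(13L, 20L))
  expect_equal(fl$n_flagged, 4L)
})

test_that("E_j never exceeds depth; flags grow as theta shrinks", {
  fx <- cached_fixture("clean", 301, locus_length = 20000, n_cassettes = 2,
                       depth = 8)
  st <- compute_read_stats(fx$records, fx$assembly)
  locus <- as.list(fx$loci[1, ])
  prev <- -1L
  for (th in c(0.02, 0.005, 0.001, 0)) {
    p <- build_pileup(st, locus, theta = th)
    expect_true(all(p$e_count <= p$depth))
    n <- flag_poorly_supported(p, 5L)$n_flagged
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("basepair mismatch rate is NA where uncovered", {
  p <- pileup_from_depths(c(30L, 12L, 0L), delta = c(0L, 4L, 0L))
  r <- basepair_mismatch_rate(p)
  expect_equal(r$rate[1], 0)
  expect_equal(r$rate[2], 1 / 3)
  expect_true(is.na(r$rate[3]))
})

test_that("deleted positions count toward depth but not delta", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 100)))
  seq <- paste0(assembly_subseq(asm, "c1", 0L, 50L),
                assembly_subseq(asm, "c1", 60L, 110L))
  rec <- make_record("d", "c1", 0L, "50M10D50M", seq)
  st <- compute_read_stats(rec, asm, method = "basewalk")
  p <- build_pileup(st, list(contig = "c1", start = 0L, end = 120L))
  expect_true(all(p$depth[51:60] == 1L))      # deletion still spans
  expect_true(all(p$delta[51:60] == 0L))
  expect_true(all(p$deleted[51:60] == 1L))
  expect_equal(sum(p$deleted), 10L)
})

test_that("column conservation: delta + matches + deleted = depth", {
  fx <- cached_fixture("clean", 301, locus_length = 20000, n_cassettes = 2,
                       depth = 8)
  st <- compute_read_stats(fx$records, fx$assembly)
  for (i in 1:2) {
    p <- build_pileup(st, as.list(fx$loci[i, ]))
    matches <- p$depth - p$delta - p$deleted
    expect_true(all(matches >= 0))
    expect_true(all(p$delta + matches + p$deleted == p$depth))
  }
})

test_that("coverage breaks are maximal runs at depth <= threshold", {
  p <- pileup_from_depths(c(5L, 5L, 0L, 0L, 1L, 5L))
  bk <- detect_coverage_breaks(p, break_threshold = 2L)
  expect_equal(nrow(bk), 1L)
  expect_equal(bk$start, 2L)
  expect_equal(bk$end, 5L)
  expect_equal(bk$length, 3L)
  expect_equal(bk$min_depth, 0L)

  none <- detect_coverage_breaks(pileup_from_depths(rep(3L, 10)),
                                 break_threshold = 2L)
  expect_equal(nrow(none), 0L)

  ## depth 2 is inside a break, 3 is outside
  edge <- detect_coverage_breaks(pileup_from_depths(c(3L, 2L, 3L)),
                                 break_threshold = 2L)
  expect_equal(edge$start, 1L)
  expect_equal(edge$end, 2L)
})

test_that("spanning reads are counted over the whole break", {
  p <- pileup_from_depths(c(5L, 1L, 1L, 5L), start = 100L)
  st <- data.frame(contig = "c1", start = c(90L, 101L), end = c(110L, 102L),
                   is_supplementary = FALSE)
  bk <- detect_coverage_breaks(p, st, break_threshold = 2L)
  expect_equal(bk$spanning_reads, 1L)   # only the 90-110 read spans 101-103
})

test_that("break categories follow the n_gap > contig_end > zero > low priority", {
  asm <- as_assembly(c(big = paste0(strrep("A", 20000), strrep("N", 50),
                                    strrep("C", 20000))))
  brk <- function(s, e, md) data.frame(contig = "big", start = s, end = e,
                                       length = e - s, min_depth = md)
  expect_equal(classify_break(brk(19990L, 20060L, 0L), asm), "n_gap")
  expect_equal(classify_break(brk(100L, 300L, 0L), asm), "contig_end")
  expect_equal(classify_break(brk(10000L, 10200L, 0L), asm), "zero_coverage")
  expect_equal(classify_break(brk(10000L, 10200L, 2L), asm), "low_coverage")
  ## near the far end
  expect_equal(classify_break(brk(39500L, 39800L, 0L), asm), "contig_end")
})

test_that("the printed 8 Kb break interval measures ~8 kb", {
  r <- parse_region("scaffold_8:75432695-75440919")
  expect_equal(round(r$width / 1000), 8)
})

test_that("elevated-coverage annotation marks depth above 2x median", {
  p <- annotate_high_coverage(pileup_from_depths(c(rep(10L, 20), rep(25L, 5))))
  expect_equal(sum(p$high_coverage), 5L)
  expect_equal(attr(p, "median_depth"), 10)
})

test_that("pileup columns equal a brute-force per-position recount", {
  fx <- cached_fixture("clean", 301, locus_length = 20000, n_cassettes = 2,
                       depth = 8)
  st <- compute_read_stats(fx$records, fx$assembly)
  locus <- as.list(fx$loci[1, ])
  p <- build_pileup(st, locus)
  o <- brute_pileup(fx$records, fx$assembly, locus)
  expect_equal(p$depth, o$depth)
  expect_equal(p$delta, o$delta)
  expect_equal(p$e_count, o$e_count)
  expect_equal(p$mapq60, o$mapq60)
  expect_equal(p$mapq_mid, o$mapq_mid)
  expect_equal(p$mapq0, o$mapq0)
})

test_that("mapq_min filter drops low-MAPQ reads from the pileup", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 100)))
  recs <- rbind(
    make_record("a", "c1", 0L, "100M", assembly_subseq(asm, "c1", 0L, 100L),
                mapq = 0L),
    make_record("b", "c1", 0L, "100M", assembly_subseq(asm, "c1", 0L, 100L),
                mapq = 60L))
  st <- compute_read_stats(recs, asm, method = "basewalk")
  p_all <- build_pileup(st, list(contig = "c1", start = 0L, end = 100L))
  p_flt <- build_pileup(st, list(contig = "c1", start = 0L, end = 100L),
                        mapq_min = 1L)
  expect_equal(unique(p_all$depth), 2L)
  expect_equal(unique(p_flt$depth), 1L)
  expect_equal(unique(p_all$mapq0), 1L)
})
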