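test_that("mismatch rate is substitutions over aligned length", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 100)))
  ## read identical to reference over its span
  r0 <- make_record("id", "c1", 8L, "100M",
                    assembly_subseq(asm, "c1", 8L, 108L))
  s0 <- compute_read_stats(r0, asm, method = "basewalk")
  expect_equal(s0$substitutions, 0L)
  expect_equal(s0$mismatch_rate, 0)

  ## direct-ratio example: synthetic stats row
  expect_equal(250 / 10000, 0.025)
  chars <- strsplit(assembly_subseq(asm, "c1", 0L, 200L), "")[[1]]
  chars[c(10, 50, 150)] <- c("T", "A", "G")  # ref base is C at all three
  r1 <- make_record("mm", "c1", 0L, "200M", paste(chars, collapse = ""))
  s1 <- compute_read_stats(r1, asm, method = "basewalk")
  expect_equal(s1$substitutions, 3L)
  expect_equal(s1$mismatch_rate, 3 / 200)
  expect_equal(s1$mm_pos[[1]], c(9L, 49L, 149L))
})

test_that("clips and indels are separate channels, excluded from e_r", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 100)))
  ## 20 bp soft clip + 100M + 5 bp deletion + 80M, 3 substitutions
  ref1 <- assembly_subseq(asm, "c1", 30L, 130L)
  ref2 <- assembly_subseq(asm, "c1", 135L, 215L)
  chars <- strsplit(paste0(ref1, ref2), "")[[1]]
  chars[c(5, 60, 120)] <- vapply(chars[c(5, 60, 120)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  seq <- paste0(strrep("G", 20), paste(chars, collapse = ""))
  rec <- make_record("clip", "c1", 30L, "20S100M5D80M", seq)
  s <- compute_read_stats(rec, asm, method = "basewalk")
  expect_equal(s$substitutions, 3L)
  expect_equal(s$soft_clip_bases, 20L)
  expect_equal(s$indel_events, 1L)
  expect_equal(s$aligned_length, 180L)
  expect_equal(s$mismatch_rate, 3 / 180)
  expect_equal(s$del_start[[1]], 130L)
  expect_equal(s$del_end[[1]], 135L)
  ## agrees with the character-at-a-time oracle
  o <- naive_read_compare(rec, asm)
  expect_equal(s$substitutions, o$substitutions)
  expect_equal(s$mm_pos[[1]], o$mm_pos)
  expect_equal(s$aligned_length, o$aligned)
  expect_equal(s$soft_clip_bases, o$soft)
})

test_that("substitutions at reference N positions are not counted", {
  asm <- as_assembly(c(cn = paste0(strrep("A", 10), "NNNN", strrep("A", 10))))
  rec <- make_record("n", "cn", 5L, "14M", strrep("A", 14))
  s <- compute_read_stats(rec, asm, method = "basewalk")
  expect_equal(s$substitutions, 0L)
})

test_that("MD fast path equals the base-by-base walk", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 100)))
  recs <- rbind(
    make_record("a", "c1", 0L, "200M", {
      ch <- strsplit(assembly_subseq(asm, "c1", 0L, 200L), "")[[1]]
      ch[c(3, 7)] <- c("T", "T"); paste(ch, collapse = "")
    }, md = "2G3G193", nm = 2L),
    make_record("b", "c1", 100L, "10S50M4D50M", {
      ref <- paste0(assembly_subseq(asm, "c1", 100L, 150L),
                    assembly_subseq(asm, "c1", 154L, 204L))
      paste0(strrep("T", 10), ref)
    }, md = "50^ACGT50", nm = 4L))
  bw <- compute_read_stats(recs, asm, method = "basewalk")
  md <- compute_read_stats(recs, asm, method = "md")
  expect_equal(md$substitutions, bw$substitutions)
  expect_equal(md$mm_pos, bw$mm_pos)
  expect_equal(md$mismatch_rate, bw$mismatch_rate)
})

test_that("inconsistent MD falls back to the walk in auto mode", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 50)))
  rec <- make_record("bad", "c1", 0L, "100M",
                     assembly_subseq(asm, "c1", 0L, 100L),
                     md = "42", nm = 0L)  # does not tile 100M
  s <- compute_read_stats(rec, asm, method = "auto")
  expect_equal(s$substitutions, 0L)
  expect_error(compute_read_stats(rec, asm, method = "md"), "inconsistent")
})

test_that("poorly-aligned classification uses a strict threshold", {
  st <- data.frame(mismatch_rate = c(0.02, 0.01, 0.005))
  expect_equal(classify_read(st, theta = 0.01), c(TRUE, FALSE, FALSE))
})

test_that("indel event threshold is a run length of at least 2 bp", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 100)))
  ## 1 bp deletion, 2 bp deletion, 3 bp insertion
  seq <- paste0(assembly_subseq(asm, "c1", 0L, 20L),
                assembly_subseq(asm, "c1", 21L, 41L),
                assembly_subseq(asm, "c1", 43L, 63L),
                "TTT",
                assembly_subseq(asm, "c1", 63L, 83L))
  rec <- make_record("i", "c1", 0L, "20M1D20M2D20M3I20M", seq)
  s <- compute_read_stats(rec, asm, method = "basewalk")
  expect_equal(s$indel_events, 2L)     # the 1 bp deletion does not count
  s1 <- compute_read_stats(rec, asm, method = "basewalk", indel_min_len = 1L)
  expect_equal(s1$indel_events, 3L)
})

test_that("records with CIGAR/sequence disagreement are skipped", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 100)))
  good <- make_record("g", "c1", 0L, "40M", assembly_subseq(asm, "c1", 0L, 40L))
  bad <- make_record("b", "c1", 0L, "50M", strrep("A", 40))
  expect_warning(s <- compute_read_stats(rbind(good, bad), asm,
                                         method = "basewalk"),
                 "skipped")
  expect_equal(nrow(s), 1L)
  expect_equal(attr(s, "n_skipped"), 1L)
})

test_that("adding a substitution never decreases e_r", {
  asm <- as_assembly(c(c1 = strrep("ACGT", 200)))
  set.seed(5)
  base <- strsplit(assembly_subseq(asm, "c1", 0L, 400L), "")[[1]]
  prev <- -1
  for (k in c(0, 1, 3, 8, 20)) {
    ch <- base
    idx <- sample(400, k)
    ch[idx] <- vapply(ch[idx], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], "")
    s <- compute_read_stats(
      make_record("m", "c1", 0L, "400M", paste(ch, collapse = "")),
      asm, method = "basewalk")
    expect_gte(s$mismatch_rate, prev)
    prev <- s$mismatch_rate
  }
})

test_that("read summaries recover planted cohort fractions", {
  fx <- cached_fixture("clean", 301, locus_length = 20000, n_cassettes = 2,
                       depth = 8)
  st <- compute_read_stats(fx$records, fx$assembly)
  sm <- summarize_reads(st)
  expect_equal(sm$n_reads, nrow(fx$records))
  expect_equal(sm$frac_soft_clipped, 0)        # oracle placement never clips
  expect_equal(sum(sm$mapq_hist), nrow(fx$records))
  expect_equal(unname(sm$mapq_bins["mapq60"] + sm$mapq_bins["mapq0"] +
                        sm$mapq_bins["mapq_mid"]), nrow(fx$records))
  ## mean realized per-read error rate matches the generator truth
  truth_rate <- sum(fx$reads$n_errors) / sum(fx$reads$length)
  est_rate <- sum(st$substitutions) / sum(st$aligned_length)
  expect_equal(est_rate, truth_rate, tolerance = 1e-9)

  empty <- summarize_reads(compute_read_stats(empty_records()))
  expect_equal(empty$n_reads, 0L)
  expect_equal(empty$frac_poorly_aligned, 0)
})

test_that("soft-clipped fraction counts reads with any clip", {
  st <- data.frame(mismatch_rate = rep(0, 10), mapq = rep(60L, 10),
                   soft_clip_bases = c(5L, 12L, rep(0L, 8)),
                   indel_events = 0L)
  sm <- summarize_reads(st, theta = 0.01)
  expect_equal(sm$frac_soft_clipped, 0.2)
})
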