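small_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, locus_length = 30000, n_cassettes = 3,
             depth = 10, ...)
}

test_that("generation is fully deterministic under a fixed seed", {
  g1 <- generate_diploid_locus(small_cfg())
  g2 <- generate_diploid_locus(small_cfg())
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$div_pos, g2$div_pos)
  r1 <- simulate_reads(g1$seqs, small_cfg())
  r2 <- simulate_reads(g2$seqs, small_cfg())
  expect_identical(r1$seq, r2$seq)
  g3 <- generate_diploid_locus(small_cfg(seed = 12))
  expect_false(identical(g1$seqs, g3$seqs))
})

test_that("zero divergence gives identical haplotypes", {
  g <- generate_diploid_locus(small_cfg(divergence = 0))
  expect_identical(g$seqs[["hap1"]], g$seqs[["hap2"]])
  expect_length(g$div_pos, 0)
})

test_that("measured divergence is close to the configured rate", {
  cfg <- sim_config(seed = 13, locus_length = 100000, divergence = 0.02)
  g <- generate_diploid_locus(cfg)
  a <- strsplit(g$seqs[["hap1"]], "")[[1]]
  b <- strsplit(g$seqs[["hap2"]], "")[[1]]
  measured <- mean(a != b)
  expect_lt(abs(measured - 0.02) / 0.02, 0.10)
  expect_equal(which(a != b) - 1L, g$div_pos)
})

test_that("infeasible cassette layouts are rejected", {
  expect_error(generate_diploid_locus(
    sim_config(locus_length = 10000, n_cassettes = 8,
               cassette_length = 6000)), "infeasible")
})

test_that("cassette copy-number change shortens haplotype 2 coherently", {
  g <- generate_diploid_locus(small_cfg(cassette_cnv = 1L))
  expect_equal(nchar(g$seqs[["hap2"]]),
               nchar(g$seqs[["hap1"]]) - g$config$cassette_length)
  expect_lt(g$hom_len, nchar(g$seqs[["hap1"]]))
  expect_equal(sum(g$genes$contig == "hap2"),
               sum(g$genes$contig == "hap1") - 3L)
})

test_that("error-free reads are exact substrings of their source", {
  g <- generate_diploid_locus(small_cfg())
  r <- simulate_reads(g$seqs, small_cfg(error_rate = 0))
  expect_true(all(r$n_errors == 0))
  idx <- sample(nrow(r), 25)
  for (i in idx)
    expect_identical(r$seq[i],
                     substr(g$seqs[[r$source_contig[i]]],
                            r$start[i] + 1, r$end[i]))
})

test_that("realized depth and error rate match the configuration", {
  cfg <- sim_config(seed = 17, locus_length = 100000, depth = 25)
  g <- generate_diploid_locus(cfg)
  r <- simulate_reads(g$seqs, cfg)
  for (h in c("hap1", "hap2")) {
    rh <- r[r$source_contig == h, ]
    realized <- sum(rh$length) / nchar(g$seqs[[h]])
    expect_lt(abs(realized - 25) / 25, 0.15)
  }
  rate <- sum(r$n_errors) / sum(r$length)
  expect_lt(abs(rate - cfg$error_rate) / cfg$error_rate, 0.20)
})

test_that("zero-length deletion leaves the assembly unchanged", {
  g <- generate_diploid_locus(small_cfg())
  a <- inject_missing_segment(g, "hap2", 1000L, 1000L)
  expect_identical(a$seqs, g$seqs)
  expect_identical(a$genes, g$genes)
  expect_null(a$defect)
})

test_that("deletion injection removes sequence and lifts genes", {
  g <- generate_diploid_locus(small_cfg())
  gene <- g$genes[g$genes$contig == "hap2", ][4, ]   # inside cassette 2
  a <- inject_missing_segment(g, "hap2", gene$start - 50L, gene$end + 50L)
  expect_equal(nchar(a$seqs[["hap2"]]),
               nchar(g$seqs[["hap2"]]) - (gene$end - gene$start + 100L))
  expect_false(gene$gene_id %in% a$genes$gene_id)
  ## downstream genes shifted left by the deleted width
  down <- g$genes[g$genes$contig == "hap2" &
                    g$genes$start >= gene$end + 50L, ][1, ]
  lifted <- a$genes[a$genes$gene_id == down$gene_id, ]
  expect_equal(lifted$start, down$start - (gene$end - gene$start + 100L))
  expect_error(inject_missing_segment(g, "hap2", -5L, 100L), "out of bounds")
})

test_that("inversion injection is an involution and plants the N-gap", {
  g <- generate_diploid_locus(small_cfg())
  a <- inject_inversion_with_gap(g, "hap1", 8000L, 16000L, gap_len = 8L)
  asm <- as_assembly(a$seqs)
  expect_true(overlaps_n_run(asm, "hap1", 8000L, 8008L))
  expect_equal(asm$n_runs$hap1, data.frame(start = 8000L, end = 8008L))
  ## inverting the inverted segment restores the original (gap aside)
  g2 <- g
  g2$seqs <- a$seqs
  b <- inject_inversion_with_gap(g2, "hap1", 8000L, 16000L, gap_len = 8L)
  orig <- substr(g$seqs[["hap1"]], 8009L, 16000L)
  back <- substr(b$seqs[["hap1"]], 8009L, 16000L)
  expect_identical(substr(back, 1, 7800), substr(orig, 1, 7800))
  ## genes inside are remapped with flipped strand
  inside <- g$genes$contig == "hap1" & g$genes$start >= 8000 &
    g$genes$end <= 16000
  if (any(inside)) {
    gid <- g$genes$gene_id[inside][1]
    before <- g$genes[g$genes$gene_id == gid, ]
    after <- a$genes[a$genes$gene_id == gid, ]
    expect_equal(after$end - after$start, before$end - before$start)
    expect_false(after$strand == before$strand)
  }
})

test_that("oracle placement yields self-consistent MD/NM tags", {
  fx <- cached_fixture("clean", 301, locus_length = 20000, n_cassettes = 2,
                       depth = 8)
  st_md <- compute_read_stats(fx$records, method = "md")
  st_bw <- compute_read_stats(fx$records, fx$assembly, method = "basewalk")
  expect_equal(st_md$substitutions, st_bw$substitutions)
  expect_equal(st_md$mm_pos, st_bw$mm_pos)
  expect_equal(st_bw$substitutions, fx$records$nm)
})

test_that("ambiguous reads get MAPQ 0 when haplotypes are identical", {
  cfg <- small_cfg(divergence = 0)
  g <- generate_diploid_locus(cfg)
  r <- simulate_reads(g$seqs, cfg)
  rec <- align_reads_oracle(r, g)
  expect_true(all(rec$mapq == 0L))
  cfg2 <- small_cfg()
  g2 <- generate_diploid_locus(cfg2)
  rec2 <- align_reads_oracle(simulate_reads(g2$seqs, cfg2), g2)
  expect_true(mean(rec2$mapq == 60L) > 0.99)
})

test_that("fixtures serialize to valid plain-text inputs and reload", {
  fx <- cached_fixture("deletion", 407, locus_length = 60000,
                       n_cassettes = 4, depth = 20)
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  files <- c("genome.fasta", "assembly.fasta", "reads.fastq", "genes.tsv",
             "loci.bed", "truth_defect.tsv", "truth_reads.tsv",
             "alignments.sam", "config.yaml")
  expect_true(all(file.exists(file.path(dir, files))))
  asm <- load_assembly(file.path(dir, "assembly.fasta"))
  expect_equal(asm$lengths, fx$assembly$lengths)
  loci <- load_loci(file.path(dir, "loci.bed"), asm)
  expect_equal(loci$locus, c("IGH", "IGH"))
  genes <- load_genes(file.path(dir, "genes.tsv"), asm, loci = loci)
  expect_equal(nrow(genes), nrow(fx$genes))
  truth <- read_tsv_commented(file.path(dir, "truth_defect.tsv"))
  expect_equal(truth$kind, "deleted_segment")
  expect_equal(truth$start, fx$truth$defect$start)
  ## same seed reproduces byte-identical serialized outputs
  fx2 <- make_fixture("deletion", sim_config(seed = 407,
                                             locus_length = 60000,
                                             n_cassettes = 4, depth = 20))
  dir2 <- withr::local_tempdir()
  write_fixture(fx2, dir2)
  for (f in setdiff(files, "config.yaml"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)), label = f)
})
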