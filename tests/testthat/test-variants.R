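mk_var <- function(pos, ..., sample_id = "s1", chrom = "chr1", ref = "A",
                   alt = "T", tumor_depth = 100L, tumor_alt = 20L,
                   germline_vaf = 0, consequence = "missense",
                   dbsnp = FALSE, gene = "Gene1") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, tumor_depth = tumor_depth, tumor_alt = tumor_alt,
             germline_vaf = germline_vaf, consequence = consequence,
             dbsnp = dbsnp, gene = gene, ...)
}

test_that("consensus keeps variants called by at least two tools", {
  tables <- list(Strelka2 = rbind(mk_var(100), mk_var(200)),
                 MuTect = mk_var(300),
                 VarScan = rbind(mk_var(100), mk_var(300), mk_var(400)))
  m <- consensus_merge(tables)
  expect_equal(sort(m$pos), c(100, 300))
  expect_equal(m[m$pos == 100, ]$callers, "Strelka2,VarScan")
  expect_equal(m[m$pos == 300, ]$callers, "MuTect,VarScan")
  # variant in all three survives with caller count 3
  all3 <- list(Strelka2 = mk_var(1), MuTect = mk_var(1), VarScan = mk_var(1))
  m3 <- consensus_merge(all3)
  expect_equal(m3$n_callers, 3L)
  # numeric fields follow caller priority (alphabetical by default)
  prio <- list(Strelka2 = mk_var(7, tumor_depth = 50L),
               MuTect = mk_var(7, tumor_depth = 80L))
  expect_equal(consensus_merge(prio)$tumor_depth, 80L)  # MuTect < Strelka2
  expect_equal(consensus_merge(prio,
                               caller_priority = c("Strelka2", "MuTect")
                               )$tumor_depth, 50L)
  # duplicate key within one caller is an error
  dup <- list(A = rbind(mk_var(5), mk_var(5)), B = mk_var(5))
  expect_error(consensus_merge(dup), "duplicate")
  expect_error(consensus_merge(list(A = mk_var(1))), "two caller")
})

test_that("hard filters enforce the depth/alt/VAF/dbSNP/consequence rules", {
  v <- rbind(
    mk_var(1),                                        # clean pass
    mk_var(2, tumor_depth = 25L, tumor_alt = 10L),    # depth < 30
    mk_var(3, tumor_alt = 4L),                        # alt reads < 5
    mk_var(4, tumor_depth = 200L, tumor_alt = 19L),   # VAF 9.5% < 10%
    mk_var(5, germline_vaf = 0.02),                   # gVAF > 1%
    mk_var(6, dbsnp = TRUE),
    mk_var(7, consequence = "intron"),
    mk_var(8, tumor_depth = 0L, tumor_alt = 0L)       # VAF undefined
  )
  f <- apply_hard_filters(v)
  expect_equal(f$retained$pos, 1)
  expect_equal(f$verdicts$rule,
               c(NA, "depth", "alt_reads", "tumor_vaf", "germline_vaf",
                 "dbsnp", "consequence", "depth"))
  # report partitions the input
  expect_equal(sum(f$report$n), nrow(v))
  # boundary semantics: thresholds themselves are retained
  edge <- rbind(mk_var(10, tumor_depth = 30L, tumor_alt = 5L),
                mk_var(11, tumor_depth = 50L, tumor_alt = 5L),
                mk_var(12, tumor_depth = 200L, tumor_alt = 20L),
                mk_var(13, germline_vaf = 0.01))
  fe <- apply_hard_filters(edge)
  expect_equal(nrow(fe$retained), 4L)
  # truncating classes are retained
  for (cq in c("synonymous", "stop_gained", "frameshift", "splice_region",
               "NMD_transcript"))
    expect_true(apply_hard_filters(mk_var(20, consequence = cq))$verdicts$pass)
})

test_that("filters reproduce the generator's truth labels exactly", {
  sv <- simulate_variant_tables(200, seed = 4)
  merged <- consensus_merge(sv$tables)
  f <- apply_hard_filters(merged)
  truth_key <- with(sv$truth, paste(sample_id, chrom, pos, ref, alt))
  kept_key <- with(f$retained, paste(sample_id, chrom, pos, ref, alt))
  expect_identical(truth_key %in% kept_key, sv$truth$pass)
  # boundary fixture passes case by case
  b <- boundary_variant_fixture()
  fb <- apply_hard_filters(b[b$n_callers >= 2, ])
  expect_identical(fb$verdicts$pass, b$pass[b$n_callers >= 2])
  expect_identical(fb$verdicts$rule, b$rule[b$n_callers >= 2])
  # the consensus-only failures are exactly the single-caller cases
  expect_true(all(b$rule[b$n_callers < 2] == "consensus"))
})

test_that("percent genome altered uses strict log2-ratio thresholds", {
  seg1 <- data.frame(chrom = "chr1", start = 0, end = 5e6, log2_ratio = 0.3)
  expect_equal(percent_genome_altered(seg1, 1e8),
               c(gain = 5, loss = 0))
  seg2 <- data.frame(chrom = c("chr1", "chr2"),
                     start = c(0, 0), end = c(1e7, 2e6),
                     log2_ratio = c(-0.2, 0.15))
  expect_equal(percent_genome_altered(seg2, 1e8),
               c(gain = 2, loss = 10))
  # |log2| at or below 0.1 contributes to neither
  seg3 <- data.frame(chrom = "chr1", start = 0, end = 5e6,
                     log2_ratio = 0.05)
  expect_equal(percent_genome_altered(seg3, 1e8), c(gain = 0, loss = 0))
  expect_equal(percent_genome_altered(transform(seg3, log2_ratio = 0.1), 1e8),
               c(gain = 0, loss = 0))
  # splitting a segment at the same log2 value changes nothing
  split2 <- data.frame(chrom = "chr1", start = c(0, 2e6), end = c(2e6, 5e6),
                       log2_ratio = 0.3)
  expect_equal(percent_genome_altered(split2, 1e8),
               percent_genome_altered(seg1, 1e8))
  # overlap detection
  bad <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(2e6, 3e6),
                    log2_ratio = 0.3)
  expect_error(percent_genome_altered(bad, 1e8), "overlap")
})

test_that("gene tallies count mutated samples with set semantics", {
  groups <- c(s1 = "g", s2 = "g", s3 = "g", s4 = "g")
  v <- rbind(mk_var(1, gene = "Tet2", sample_id = "s1"),
             mk_var(2, gene = "Tet2", sample_id = "s1"),  # same sample twice
             mk_var(3, gene = "Tet2", sample_id = "s2"))
  tl <- gene_mutation_tally(v, c("Tet2", "Kmt2d"), groups)
  expect_equal(tl[tl$gene == "Tet2", ]$n_mutated, 2L)
  expect_equal(tl[tl$gene == "Tet2", ]$frequency, 0.5)
  expect_equal(tl[tl$gene == "Kmt2d", ]$n_mutated, 0L)
  # empty variant set: all zero
  t0 <- gene_mutation_tally(v[0, ], c("Tet2"), groups)
  expect_equal(t0$frequency, 0)
  # unknown sample group errors
  expect_error(gene_mutation_tally(mk_var(9, sample_id = "sX"),
                                   c("Tet2"), groups), "unknown group")
})
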