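test_that("simulation is deterministic given the seed, to the byte", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 2e6, chr2 = 2e6), depth = 5000,
                    seed = 42)
  s1 <- simulate_contacts(cfg, "A")
  s2 <- simulate_contacts(cfg, "A")
  f1 <- tempfile(); f2 <- tempfile()
  write_pairs(s1$pairs, f1); write_pairs(s2$pairs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s3 <- simulate_contacts(cfg, "A", seed = 43)
  expect_false(identical(s1$pairs, s3$pairs))
})

test_that("exactly `depth` intra-chromosomal pairs are emitted", {
  cfg <- sim_config(chrom_sizes = c(chr1 = 4e6), depth = 1234, seed = 3)
  sim <- simulate_contacts(cfg, "A")
  expect_identical(nrow(sim$pairs), 1234L)
  expect_true(all(sim$pairs$chrom1 == sim$pairs$chrom2))
  expect_true(all(sim$pairs$pos1 >= 0 & sim$pairs$pos1 < 4e6))
  expect_true(all(sim$pairs$pos2 >= 0 & sim$pairs$pos2 < 4e6))
})

test_that("null config reproduces the analytic power-law decay", {
  # mean count at distance 2d over mean at d must approach 2^-alpha
  for (alpha in c(1, 1.5)) {
    cfg <- sim_config(chrom_sizes = toy_genome, depth = 4e5,
                      decay_exponent = alpha, dispersion = 0, seed = 8)
    sim <- simulate_contacts(cfg, "A")
    mat <- bin_pairs(sim$pairs, cfg$chrom_sizes, cfg$resolution, "null")
    fd <- suppressMessages(fit_diagonals(mat, 1, 60, refit = 0))
    for (d in c(5, 10, 20)) {
      ratio <- fd$mean[fd$distance == 2 * d] / fd$mean[fd$distance == d]
      expect_equal(ratio, 2^-alpha, tolerance = 0.1)
    }
  }
})

test_that("a planted loop is enriched by its factor over the diagonal mean", {
  loops <- data.frame(chrom = "chr1", bin1 = 300L, bin2 = 305L,
                      enrichment = 8)
  cfg <- sim_config(chrom_sizes = c(chr1 = 2e7), depth = 2e6,
                    planted_loops = loops, dispersion = 0, seed = 21)
  sim <- simulate_contacts(cfg, "A")
  mat <- bin_pairs(sim$pairs, cfg$chrom_sizes, cfg$resolution, "pl")
  obs <- mat$pixels[chrom == "chr1" & bin1 == 300 & bin2 == 305, count]
  # background mean at distance 5, excluding the planted pixel itself
  bg <- mat$pixels[bin2 - bin1 == 5 & !(bin1 == 300 & bin2 == 305),
                   sum(count)] / (n_bins(2e7, 2e4) - 5 - 1)
  expect_equal(obs / bg, 8, tolerance = 0.25)
  # and matches the closed-form expectation
  expect_equal(obs, expected_pixel_count(sim$truth, "chr1", 300L, 305L),
               tolerance = 0.25)
})

test_that("per-diagonal counts are overdispersed, Poisson at dispersion 0", {
  base <- list(chrom_sizes = toy_genome, depth = 6e5, seed = 14)
  vm_ratio <- function(dispersion) {
    cfg <- sim_config(chrom_sizes = base$chrom_sizes, depth = base$depth,
                      dispersion = dispersion, seed = base$seed)
    sim <- simulate_contacts(cfg, "A")
    mat <- bin_pairs(sim$pairs, cfg$chrom_sizes, cfg$resolution, "vm")
    fd <- suppressMessages(fit_diagonals(mat, 2, 6, refit = 0))
    fd$variance / fd$mean
  }
  expect_equal(mean(vm_ratio(0)), 1, tolerance = 0.1)
  expect_true(mean(vm_ratio(0.3)) > 1.5)
})

test_that("anchor outside the genome is a configuration error", {
  expect_error(sim_config(chrom_sizes = c(chr1 = 2e6),
                          planted_loops = data.frame(chrom = "chr1",
                                                     bin1 = 10, bin2 = 500,
                                                     enrichment = 4)),
               "outside")
  expect_error(sim_config(chrom_sizes = c(chr1 = 2e6),
                          planted_loops = data.frame(chrom = "chr1",
                                                     bin1 = 10, bin2 = 5,
                                                     enrichment = 4)),
               "bin1 < bin2")
})

test_that("truth files round-trip through JSON", {
  rec <- recovery_fixture()
  f <- tempfile(fileext = ".json")
  write_sim_truth(rec$sim$truth, f)
  back <- read_sim_truth(f)
  expect_equal(back$chrom_sizes, rec$sim$truth$chrom_sizes)
  expect_equal(back$labels, rec$sim$truth$labels)
  expect_equal(back$loops, rec$sim$truth$loops)
  expect_equal(back$base_total_weight, rec$sim$truth$base_total_weight)
})

test_that("simulated annotations respect bounds and cover requested loops", {
  rec <- recovery_fixture()
  ann <- simulate_annotations(rec$sim$truth, loops_covered = 1)
  for (df in ann) {
    expect_true(all(df$start >= 0))
    expect_true(all(df$start < df$end))
    expect_true(all(df$end <= toy_genome[df$chrom]))
    expect_false(is.unsorted(df$start[df$chrom == "chr1"]))
  }
  expect_error(simulate_annotations(rec$sim$truth, loops_covered = 1.2),
               "loops_covered")
  # coverage itself is asserted via classify_loops in test-annotation.R
})

test_that("variant tables are deterministic and stratified", {
  v1 <- simulate_variant_tables(120, seed = 5)
  v2 <- simulate_variant_tables(120, seed = 5)
  expect_identical(v1, v2)
  expect_false(identical(v1$truth,
                         simulate_variant_tables(120, seed = 6)$truth))
  # single-caller variants are labelled drop, and every rule is exercised
  expect_true(all(!v1$truth$pass[v1$truth$n_callers < 2]))
  expect_setequal(unique(na.omit(v1$truth$rule)),
                  c("consensus", "depth", "alt_reads", "tumor_vaf",
                    "germline_vaf", "dbsnp", "consequence"))
  expect_true(any(v1$truth$pass))
  # a clean variant passes by construction
  b <- boundary_variant_fixture()
  expect_true(b$pass[1])
})
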