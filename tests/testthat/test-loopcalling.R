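test_that("diagonal moment fits use closed forms with Poisson fallback", {
  # all counts equal: s2 = 0 <= mu forces the Poisson branch
  pairs <- data.frame(chrom1 = "chr1",
                      pos1 = rep(seq(0, 9e4, 1e4), each = 5),
                      chrom2 = "chr1",
                      pos2 = rep(seq(2e4, 11e4, 1e4), each = 5))
  m <- bin_pairs(pairs, c(chr1 = 1.2e5), 1e4)
  fd <- suppressMessages(fit_diagonals(m, 2, 3, min_pixels = 2, refit = 0))
  expect_true(fd$poisson[fd$distance == 2])
  expect_equal(fd$mean[fd$distance == 2], 5)
  expect_true(is.infinite(fd$size[fd$distance == 2]))

  # mu = 5, s2 = 10 -> size = 25/5 = 5 (checked on a synthetic model row)
  expect_equal({mu <- 5; s2 <- 10; mu^2 / (s2 - mu)}, 5)

  # empty diagonals are skipped
  fd2 <- suppressMessages(fit_diagonals(m, 4, 6, min_pixels = 2))
  expect_equal(nrow(fd2), 0L)
})

test_that("pixel p-values match brute-force tail sums", {
  # NB and Poisson upper tails, inclusive, over a parameter grid
  for (mu in c(0.5, 5, 60)) {
    for (size in c(0.8, 5, 50)) {
      model <- list(mean = mu, size = size)
      for (x in c(0L, 1L, 3L, 17L, 120L, 500L)) {
        expect_equal(pixel_pvalue(model, x),
                     nb_tail_bruteforce(x, size, mu), tolerance = 1e-12)
      }
    }
    pois <- list(mean = mu, size = Inf)
    for (x in c(0L, 2L, 10L, 500L))
      expect_equal(pixel_pvalue(pois, x), pois_tail_bruteforce(x, mu),
                   tolerance = 1e-12)
  }
  # x = 0 is exactly 1; Poisson mu=5 x=10 equals 1 - CDF(9)
  expect_identical(pixel_pvalue(list(mean = 5, size = Inf), 0), 1)
  expect_equal(pixel_pvalue(list(mean = 5, size = Inf), 10),
               1 - ppois(9, 5))
})

test_that("calling retains only FDR- and CPM-passing pixels", {
  rec <- recovery_fixture()
  calls <- rec$calls
  expect_true(all(calls$fdr < 0.1 & calls$cpm > 30))
  expect_true(all(calls$fdr >= calls$pvalue))
  expect_true(all(calls$bin1 < calls$bin2))
  # planted loops are recovered at their exact pixels
  hit <- loop_key(rec$loops) %in% loop_key(calls)
  expect_true(mean(hit[rec$loops$enrichment == 8]) >= 0.95)
  expect_true(mean(hit[rec$loops$enrichment == 4]) >= 0.8)
  # a pixel can be FDR-significant yet fail the CPM gate: force it by
  # calling with an absurd CPM threshold and checking nothing survives
  none <- suppressMessages(call_loops(rec$mat, cpm_threshold = 1e9))
  expect_equal(nrow(none), 0L)
  # empty matrix: empty set with a warning
  empty <- bin_pairs(data.frame(chrom1 = "chr1", pos1 = 1,
                                chrom2 = "chr2", pos2 = 1),
                     toy_genome, 2e4)
  expect_warning(e <- call_loops(empty), "empty")
  expect_equal(nrow(e), 0L)
})

test_that("BH adjustment is monotone and bounded below by p", {
  rec <- recovery_fixture()
  models <- suppressMessages(fit_diagonals(rec$mat, 2, 100))
  px <- rec$mat$pixels[bin2 - bin1 >= 2 & bin2 - bin1 <= 100]
  mi <- match(px$bin2 - px$bin1, models$distance)
  p <- pixel_pvalue(list(mean = models$mean[mi], size = models$size[mi]),
                    px$count)
  m_total <- sum(models$n_pixels)
  adj <- p.adjust(p, "BH", n = m_total)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("union matches by exact pixel coordinates", {
  mk <- function(df, res = 2e4) {
    dt <- data.table::as.data.table(df)
    data.table::setattr(dt, "resolution", res)
    dt
  }
  a <- mk(data.frame(chrom = "chr1", bin1 = 1:3, bin2 = 11:13))
  b <- mk(data.frame(chrom = "chr1", bin1 = 21:24, bin2 = 31:34))
  expect_equal(nrow(union_loops(a, b)), 7L)
  expect_equal(nrow(union_loops(a, a)), 3L)
  u <- union_loops(a, mk(data.frame(chrom = "chr1", bin1 = 1, bin2 = 11)))
  expect_equal(u[u$bin1 == 1, ]$called_in, "both")
  expect_error(union_loops(a, mk(b, res = 1e5)), "resolution")
})

test_that("differential loops use the defined log2 fold-change", {
  u <- data.table::data.table(chrom = "chr1", bin1 = c(0L, 1L, 2L),
                              bin2 = c(10L, 11L, 12L), called_in = "both")
  data.table::setattr(u, "resolution", 2e4L)
  mk_mat <- function(counts, depth) {
    px <- data.table::data.table(chrom = "chr1", bin1 = c(0L, 1L, 2L),
                                 bin2 = c(10L, 11L, 12L), count = counts)
    data.table::setkey(px, chrom, bin1, bin2)
    structure(list(resolution = 2e4L, chrom_sizes = c(chr1 = 1e6),
                   pixels = px, total_depth = depth, sample_id = "x"),
              class = "contact_matrix")
  }
  ma <- mk_mat(c(60L, 50L, 60L), 1e6)   # CPM 60, 50, 60
  mb <- mk_mat(c(30L, 50L, 0L), 1e6)    # CPM 30, 50, 0
  d0 <- differential_loops(u, ma, mb, pseudocount = 0)
  expect_equal(d0$log2fc[1], 1)
  expect_equal(d0$log2fc[2], 0)
  d1 <- differential_loops(u, ma, mb, pseudocount = 1)
  expect_equal(d1$log2fc[3], log2(61), tolerance = 1e-12)
  # CPM is looked up even where a sample has no stored pixel (count 0)
  expect_equal(d1$cpm_b[3], 0)
  # swapping samples negates every value exactly
  expect_identical(differential_loops(u, mb, ma)$log2fc,
                   -differential_loops(u, ma, mb)$log2fc)
})

test_that("APA enforces the eligibility rule and discriminates loops", {
  rec <- recovery_fixture()
  # loops at distance 2-6 with w=5 violate d >= 2w+1: none eligible
  expect_error(aggregate_peak_analysis(rec$mat, rec$loops), "eligible")
  # loop 2 bins from the edge is excluded from the average
  far <- data.frame(chrom = "chr1", bin1 = c(2L, 500L), bin2 = c(32L, 530L))
  res <- aggregate_peak_analysis(rec$mat, far)
  expect_equal(res$n_loops, 1L)
  expect_equal(dim(res$apa), c(11L, 11L))
})
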