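# Loop calling by a negative-binomial test per distance diagonal.
#
# Contact frequency decays with genomic distance, so the background model is
# fitted separately for each diagonal d (all pixels at |bin2 - bin1| = d,
# pooled across chromosomes). Moments are taken over ALL pixels at that
# distance, including structural zeros inside the tested range: omitting
# them would inflate the background mean. Method-of-moments NB fit
# (size r = mu^2 / (s^2 - mu)), with a Poisson fallback when s^2 <= mu.
# P-values are inclusive upper tails P(X >= x); Benjamini-Hochberg is
# applied once across all tested pixels genome-wide (per-diagonal families
# available by flag). Loops are retained when fdr < fdr_threshold AND
# CPM > cpm_threshold.

#' Fit per-diagonal background models
#'
#' Method-of-moments estimates over all pixels at each distance, structural
#' zeros included. Focal enrichments (the loops being looked for) would
#' otherwise inflate the background moments, so fitting optionally
#' iterates: pixels that are extreme outliers under the current model
#' (per-diagonal Bonferroni at `mask_alpha`) are masked and the moments
#' refitted without them. Under a loop-free matrix the masking almost
#' never triggers, leaving the null fit unbiased.
#'
#' @param matrix A `contact_matrix`.
#' @param min_dist,max_dist Tested distance range in bins (inclusive).
#' @param min_pixels Diagonals with fewer pixels are skipped.
#' @param refit Number of outlier-masking refit passes (default 2; 0
#'   disables masking).
#' @param mask_alpha Per-diagonal Bonferroni level flagging background
#'   outliers during refitting (default 0.01).
#' @return `data.frame` with one row per fitted distance: n_pixels (total,
#'   zeros included), mean, variance, NB `size` (Inf for the Poisson
#'   fallback), `poisson` flag and `n_masked`.
#' @export
fit_diagonals <- function(matrix, min_dist = 2L, max_dist = 100L,
                          min_pixels = 20L, refit = 2L, mask_alpha = 0.01) {
  stopifnot(min_dist >= 1, max_dist > min_dist)
  nb <- vapply(matrix$chrom_sizes, n_bins, integer(1),
               resolution = matrix$resolution)
  dists <- min_dist:max_dist
  # pixels per diagonal, counting structural zeros: sum over chroms of nb - d
  n_pix <- vapply(dists, function(d) sum(pmax(nb - d, 0L)), numeric(1))

  px <- matrix$pixels
  px_d <- px[, .(chrom, d = bin2 - bin1, count)][d >= min_dist & d <= max_dist]
  masked <- rep(FALSE, nrow(px_d))
  di <- match(px_d$d, dists)

  fit_once <- function(masked) {
    keep <- !masked
    sums <- px_d[keep, .(s = sum(count), ss = sum(as.numeric(count)^2)),
                 by = d]
    m <- match(dists, sums$d)
    s <- ifelse(is.na(m), 0, sums$s[m])
    ss <- ifelse(is.na(m), 0, sums$ss[m])
    n_used <- n_pix - tabulate(di[masked], nbins = length(dists))
    mu <- ifelse(n_used > 0, s / n_used, NA_real_)
    s2 <- ifelse(n_used > 1, (ss - n_used * mu^2) / (n_used - 1), NA_real_)
    poisson <- !is.na(s2) & s2 <= mu
    size <- ifelse(poisson | is.na(s2), Inf, mu^2 / (s2 - mu))
    list(mu = mu, s2 = s2, size = size, poisson = poisson)
  }

  f <- fit_once(masked)
  if (refit > 0 && nrow(px_d)) {
    for (it in seq_len(refit)) {
      p <- pnbinom(px_d$count - 1, size = f$size[di], mu = f$mu[di],
                   lower.tail = FALSE)
      pois <- is.infinite(f$size[di])
      if (any(pois))
        p[pois] <- ppois(px_d$count[pois] - 1, lambda = f$mu[di][pois],
                         lower.tail = FALSE)
      new_mask <- !masked & p < mask_alpha / n_pix[di]
      if (!any(new_mask)) break
      masked <- masked | new_mask
      f <- fit_once(masked)
    }
  }

  out <- data.frame(distance = dists, n_pixels = n_pix, mean = f$mu,
                    variance = f$s2, size = f$size, poisson = f$poisson,
                    n_masked = tabulate(di[masked], nbins = length(dists)))
  skipped <- out$n_pixels < min_pixels | !is.finite(out$mean) | out$mean <= 0
  if (any(skipped))
    message(sum(skipped), " diagonal(s) skipped (too few pixels or empty)")
  out[!skipped, , drop = FALSE]
}

#' Upper-tail pixel p-value under a diagonal background model
#'
#' Inclusive upper tail P(X >= x) under the fitted negative binomial (or
#' Poisson fallback) for that diagonal.
#'
#' @param model One row of [fit_diagonals()] output (or a list with `mean`,
#'   `size`).
#' @param count Observed pixel count(s).
#' @return P-value(s); `count = 0` gives exactly 1.
#' @export
pixel_pvalue <- function(model, count) {
  n <- max(length(count), length(model$mean), length(model$size))
  count <- rep_len(count, n)
  mu <- rep_len(model$mean, n)
  size <- rep_len(model$size, n)
  out <- numeric(n)
  pois <- is.infinite(size)
  if (any(pois))
    out[pois] <- ppois(count[pois] - 1, lambda = mu[pois],
                       lower.tail = FALSE)
  if (any(!pois))
    out[!pois] <- pnbinom(count[!pois] - 1, size = size[!pois],
                          mu = mu[!pois], lower.tail = FALSE)
  out
}

#' Call significant loops from a contact matrix
#'
#' Tests every pixel with distance in `[min_dist, max_dist]` against its
#' diagonal background, corrects across all tested pixels (structural zeros
#' included in the family size), and retains pixels with
#' `fdr < fdr_threshold` and `CPM > cpm_threshold`.
#'
#' @param matrix A `contact_matrix`.
#' @param min_dist,max_dist Distance range in bins (defaults 2 and 100,
#'   i.e. 40 kb - 2 Mb at 20 kb).
#' @param fdr_threshold Benjamini-Hochberg FDR cutoff (default 0.1).
#' @param cpm_threshold CPM cutoff (default 30).
#' @param min_pixels Minimum pixels per fitted diagonal.
#' @param bh_scope `"genome"` corrects once across all tested pixels;
#'   `"diagonal"` corrects within each diagonal separately.
#' @return A `loop_set`: `data.table` (chrom, bin1, bin2, count, cpm,
#'   pvalue, fdr) with attributes `resolution`, `chrom_sizes`, `sample_id`,
#'   `n_tested` and the thresholds used.
#' @export
call_loops <- function(matrix, min_dist = 2L, max_dist = 100L,
                       fdr_threshold = 0.1, cpm_threshold = 30,
                       min_pixels = 20L, bh_scope = c("genome", "diagonal")) {
  bh_scope <- match.arg(bh_scope)
  if (!nrow(matrix$pixels)) {
    warning("empty contact matrix: no loops called")
    return(empty_loop_set(matrix, min_dist, max_dist, fdr_threshold,
                          cpm_threshold, 0))
  }
  models <- fit_diagonals(matrix, min_dist, max_dist, min_pixels)
  if (!nrow(models))
    return(empty_loop_set(matrix, min_dist, max_dist, fdr_threshold,
                          cpm_threshold, 0))

  px <- matrix$pixels[, .(chrom, bin1, bin2, count)]
  px[, distance := bin2 - bin1]
  px <- px[distance %in% models$distance]
  mi <- match(px$distance, models$distance)
  px[, pvalue := pnbinom(count - 1, size = models$size[mi],
                         mu = models$mean[mi], lower.tail = FALSE)]
  pois <- is.infinite(models$size[mi])
  if (any(pois))
    px[pois, pvalue := ppois(count - 1, lambda = models$mean[mi][pois],
                             lower.tail = FALSE)]

  # structural zeros have p = 1 exactly; include them in the family size
  # without materializing them
  if (bh_scope == "genome") {
    m_total <- sum(models$n_pixels)
    setorder(px, pvalue, chrom, bin1, bin2)   # stable tie-break
    px[, fdr := p.adjust(pvalue, method = "BH", n = m_total)]
  } else {
    px[, fdr := {
      n_d <- models$n_pixels[match(.BY$distance, models$distance)]
      p.adjust(pvalue, method = "BH", n = n_d)
    }, by = distance]
    m_total <- sum(models$n_pixels)
  }
  px[, cpm := count * 1e6 / matrix$total_depth]
  loops <- px[fdr < fdr_threshold & cpm > cpm_threshold,
              .(chrom, bin1, bin2, count, cpm, pvalue, fdr)]
  setorder(loops, chrom, bin1, bin2)
  structure(loops,
            class = c("loop_set", class(loops)),
            resolution = matrix$resolution,
            chrom_sizes = matrix$chrom_sizes,
            sample_id = matrix$sample_id,
            n_tested = m_total,
            fdr_threshold = fdr_threshold,
            cpm_threshold = cpm_threshold,
            min_dist = min_dist, max_dist = max_dist)
}

empty_loop_set <- function(matrix, min_dist, max_dist, fdr_threshold,
                           cpm_threshold, n_tested) {
  loops <- data.table(chrom = character(), bin1 = integer(),
                      bin2 = integer(), count = integer(),
                      cpm = numeric(), pvalue = numeric(), fdr = numeric())
  structure(loops, class = c("loop_set", class(loops)),
            resolution = matrix$resolution, chrom_sizes = matrix$chrom_sizes,
            sample_id = matrix$sample_id, n_tested = n_tested,
            fdr_threshold = fdr_threshold, cpm_threshold = cpm_threshold,
            min_dist = min_dist, max_dist = max_dist)
}

#' @export
print.loop_set <- function(x, ...) {
  cat("loop_set '", attr(x, "sample_id"), "': ", nrow(x),
      " significant loop(s) at ", attr(x, "resolution"), " bp (",
      attr(x, "n_tested"), " pixels tested; FDR<",
      attr(x, "fdr_threshold"), ", CPM>", attr(x, "cpm_threshold"), ")\n",
      sep = "")
  if (nrow(x)) print(as.data.table(x), topn = 3)
  invisible(x)
}

#' Union of two loop sets across samples
#'
#' Exact pixel-coordinate matching; each union entry records which
#' sample(s) called it.
#'
#' @param set_a,set_b `loop_set`s at the same resolution.
#' @return `data.table` (chrom, bin1, bin2, called_in) where `called_in`
#'   is "a", "b" or "both"; carries the resolution attribute.
#' @export
union_loops <- function(set_a, set_b) {
  if (!identical(attr(set_a, "resolution"), attr(set_b, "resolution")))
    stop("loop sets have different resolutions")
  a <- as.data.table(set_a)[, .(chrom, bin1, bin2)]
  b <- as.data.table(set_b)[, .(chrom, bin1, bin2)]
  a[, in_a := TRUE]; b[, in_b := TRUE]
  u <- merge(a, b, by = c("chrom", "bin1", "bin2"), all = TRUE)
  u[, called_in := ifelse(!is.na(in_a) & !is.na(in_b), "both",
                          ifelse(!is.na(in_a), "a", "b"))]
  u <- u[, .(chrom, bin1, bin2, called_in)]
  setorder(u, chrom, bin1, bin2)
  setattr(u, "resolution", attr(set_a, "resolution"))
  u
}

#' Differential loop strength over a cross-sample union
#'
#' For each union loop, CPM is looked up in both matrices (also where a
#' sample did not call the loop) and the log2 fold-change
#' `log2((cpm_a + c) / (cpm_b + c))` reported with pseudocount `c`.
#'
#' @param union Output of [union_loops()].
#' @param matrix_a,matrix_b `contact_matrix` objects at the union's
#'   resolution.
#' @param pseudocount Pseudocount `c` in CPM units (default 1).
#' @return `data.table` (chrom, bin1, bin2, called_in, cpm_a, cpm_b,
#'   log2fc).
#' @export
differential_loops <- function(union, matrix_a, matrix_b, pseudocount = 1.0) {
  for (m in list(matrix_a, matrix_b))
    if (!identical(as.integer(m$resolution), as.integer(attr(union, "resolution"))))
      stop("matrix resolution differs from the union's")
  u <- as.data.table(union)
  lookup <- function(m) {
    cnt <- m$pixels[u, on = c("chrom", "bin1", "bin2"), x.count]
    fifelse(is.na(cnt), 0, as.numeric(cnt)) * 1e6 / m$total_depth
  }
  out <- copy(u)
  out[, cpm_a := lookup(matrix_a)]
  out[, cpm_b := lookup(matrix_b)]
  # difference of logs, not log of ratio: exactly antisymmetric under swap
  out[, log2fc := log2(cpm_a + pseudocount) - log2(cpm_b + pseudocount)]
  out[]
}

#' Aggregate peak analysis
#'
#' Averages distance-normalized (observed / diagonal mean) submatrices of
#' half-width `half_window` centered on each loop, and scores focal
#' enrichment as the center value over the mean of the `w x w` lower-left
#' corner (the shorter-distance background). Loops closer than
#' `half_window` bins to a matrix edge, closer than `half_window` to the
#' minimum tested distance, or at distance < `2*half_window + 1` (so the
#' background corner stays off-diagonal) are excluded.
#'
#' @param matrix A `contact_matrix`.
#' @param loops `loop_set` or `data.frame` with chrom, bin1, bin2 at the
#'   matrix resolution.
#' @param half_window Half-width w in bins (default 5).
#' @param min_dist Minimum tested distance in bins (default 2).
#' @return List with `apa` (the mean (2w+1)^2 matrix), `score` and
#'   `n_loops` used.
#' @export
aggregate_peak_analysis <- function(matrix, loops, half_window = 5L,
                                    min_dist = 2L) {
  w <- as.integer(half_window)
  loops <- as.data.table(loops)[, .(chrom, bin1, bin2)]
  nb <- vapply(matrix$chrom_sizes, n_bins, integer(1),
               resolution = matrix$resolution)
  d <- loops$bin2 - loops$bin1
  ok <- loops$bin1 - w >= 0 & loops$bin2 + w <= nb[loops$chrom] - 1L &
    d - w >= min_dist & d >= 2L * w + 1L
  loops <- loops[ok]
  if (!nrow(loops)) stop("no loops eligible for APA at this window size")

  dmax <- max(loops$bin2 - loops$bin1) + 2L * w
  # empirical diagonal means pooled across chromosomes (zeros included)
  n_pix <- vapply(seq_len(dmax), function(dd) sum(pmax(nb - dd, 0L)), numeric(1))
  px <- matrix$pixels
  sums <- px[, .(d = bin2 - bin1, count)][d >= 1 & d <= dmax,
                                          .(s = sum(count)), by = d]
  diag_mean <- numeric(dmax)
  diag_mean[sums$d] <- sums$s
  diag_mean <- ifelse(n_pix > 0, diag_mean / n_pix, NA_real_)

  size <- 2L * w + 1L
  acc <- base::matrix(0, size, size)
  nmat <- base::matrix(0, size, size)
  for (ch in unique(loops$chrom)) {
    dm <- dense_chrom(matrix, ch)
    for (r in which(loops$chrom == ch)) {
      i <- loops$bin1[r]; j <- loops$bin2[r]
      sub <- dm[(i - w):(i + w) + 1L, (j - w):(j + w) + 1L]
      dd <- outer((i - w):(i + w), (j - w):(j + w), function(a, b) b - a)
      oe <- sub / diag_mean[dd]
      valid <- is.finite(oe)
      acc[valid] <- acc[valid] + oe[valid]
      nmat <- nmat + valid
    }
  }
  apa <- acc / nmat
  corner <- apa[(w + 2L):(2L * w + 1L), 1:w]
  score <- apa[w + 1L, w + 1L] / mean(corner, na.rm = TRUE)
  list(apa = apa, score = score, n_loops = nrow(loops))
}

#' Write loops as BEDPE
#'
#' Standard 10 BEDPE columns followed by count, cpm, pvalue, fdr (and any
#' further columns present, e.g. cpm_a/cpm_b/log2fc for differential sets).
#'
#' @param loops `loop_set` or differential-loop `data.table`.
#' @param path Output path.
#' @param resolution Bin size (taken from the attribute when absent).
#' @export
write_bedpe <- function(loops, path, resolution = attr(loops, "resolution")) {
  if (is.null(resolution)) stop("resolution required to write BEDPE")
  dt <- as.data.table(loops)
  extra <- setdiff(names(dt), c("chrom", "bin1", "bin2"))
  out <- data.table(chrom1 = dt$chrom, start1 = dt$bin1 * resolution,
                    end1 = (dt$bin1 + 1) * resolution,
                    chrom2 = dt$chrom, start2 = dt$bin2 * resolution,
                    end2 = (dt$bin2 + 1) * resolution,
                    name = paste0("loop", seq_len(nrow(dt))),
                    score = if ("fdr" %in% extra) -log10(pmax(dt$fdr, 1e-300)) else 0,
                    strand1 = ".", strand2 = ".")
  fwrite(cbind(out, dt[, extra, with = FALSE]), path, sep = "\t")
  invisible(path)
}
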