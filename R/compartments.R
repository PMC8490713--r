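# A/B compartment scoring at 100 kb.
#
# Per chromosome: observed/expected transform by diagonal means, a light
# box smoothing of the O/E matrix (compartments are megabase-scale, so
# +/-2 bins of pooling suppresses pixel shot noise without blurring
# blocks), Pearson correlation matrix over unmasked bins, then the leading
# eigenvector of the correlation of that correlation matrix (PCA on the
# correlation matrix, as checkerboards are sharpest there), rescaled by
# its maximum absolute entry into [-1, 1]. The eigenvector's sign is
# arbitrary; it is oriented so that bins in the top quartile of an
# H3K27ac-like reference signal average positive (A = active). Bins with
# zero marginal counts are masked (NA) before the correlation step.
# Downstream comparisons (delta scores, correlation plots, A/B by
# reference signal) depend only on a signed per-bin score.

# running-mean operator over +/- hw positions (edges renormalized)
box_operator <- function(n, hw) {
  A <- base::matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- max(1, i - hw):min(n, i + hw)
    A[i, w] <- 1 / length(w)
  }
  A
}

#' Count reference peaks per genomic bin
#'
#' Maps a peak interval track (e.g. H3K27ac) to a per-bin signal by
#' counting overlapping peaks.
#'
#' @param peaks `data.frame` with chrom, start, end (0-based half-open).
#' @param chrom_sizes Named chromosome lengths.
#' @param resolution Bin size in bp.
#' @return `data.table` (chrom, bin, signal) covering every bin.
#' @export
bin_reference_peaks <- function(peaks, chrom_sizes, resolution) {
  out <- lapply(names(chrom_sizes), function(ch) {
    nb <- n_bins(chrom_sizes[[ch]], resolution)
    sig <- numeric(nb)
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk)) {
      b1 <- pmax(0L, as.integer(pk$start %/% resolution))
      b2 <- pmin(nb - 1L, as.integer((pk$end - 1) %/% resolution))
      for (k in seq_along(b1)) {
        rng <- b1[k]:b2[k]
        sig[rng + 1L] <- sig[rng + 1L] + 1
      }
    }
    data.table(chrom = ch, bin = seq_len(nb) - 1L, signal = sig)
  })
  rbindlist(out)
}

#' Compartment score track from a contact matrix
#'
#' @param matrix A `contact_matrix` (typically at 100 kb).
#' @param reference `data.table`/data.frame (chrom, bin, signal) used to
#'   orient the eigenvector (A = high signal), e.g. from
#'   [bin_reference_peaks()].
#' @param min_bins Chromosomes with fewer unmasked bins are fully masked
#'   with a warning (default 10).
#' @param oe_smooth Half-width in bins of the box smoothing applied to the
#'   O/E matrix before correlation (default 2; 0 disables).
#' @param second_order When `TRUE` (default) the eigenvector is taken from
#'   the correlation of the bin-bin correlation matrix, where the
#'   compartment checkerboard is sharpest.
#' @return A `compartment_track`: `data.table` (chrom, bin, start, end,
#'   score, label) with score in [-1, 1], label "A" (score > 0), "B"
#'   (score < 0) or NA for masked bins.
#' @export
compute_cscore <- function(matrix, reference, min_bins = 10L,
                           oe_smooth = 2L, second_order = TRUE) {
  ref <- as.data.table(reference)
  stopifnot(all(c("chrom", "bin", "signal") %in% names(ref)))
  res <- matrix$resolution
  out <- lapply(names(matrix$chrom_sizes), function(ch) {
    nb <- n_bins(matrix$chrom_sizes[[ch]], res)
    score <- rep(NA_real_, nb)
    m <- dense_chrom(matrix, ch)
    marg <- rowSums(m)
    unmasked <- marg > 0
    # O/E on the full matrix using original distances
    if (sum(unmasked) >= min_bins) {
      dmat <- abs(outer(seq_len(nb), seq_len(nb), "-"))
      oe <- m
      for (d in 0:(nb - 1)) {
        sel <- dmat == d & outer(unmasked, unmasked, "&")
        mu <- mean(m[sel])
        oe[dmat == d] <- if (is.finite(mu) && mu > 0) m[dmat == d] / mu else 0
      }
      if (oe_smooth > 0) {
        A <- box_operator(nb, oe_smooth)
        oe <- A %*% oe %*% t(A)
      }
      sub <- oe[unmasked, unmasked, drop = FALSE]
      sds <- apply(sub, 2, sd)
      ok <- sds > 0
      unm_idx <- which(unmasked)[ok]
      if (length(unm_idx) >= min_bins) {
        cc <- cor(sub[ok, ok, drop = FALSE])
        if (second_order) cc <- cor(cc)
        ev <- eigen(cc, symmetric = TRUE)
        v <- ev$vectors[, 1]
        v <- v / max(abs(v))
        rsig <- ref[ref$chrom == ch][match(unm_idx - 1L, bin), signal]
        topq <- rsig >= quantile(rsig, 0.75)
        if (any(topq) && mean(v[topq]) < 0) v <- -v
        score[unm_idx] <- v
      } else {
        warning("chromosome ", ch, " fully masked (<", min_bins,
                " usable bins)")
      }
    } else {
      warning("chromosome ", ch, " fully masked (<", min_bins,
              " usable bins)")
    }
    data.table(chrom = ch, bin = seq_len(nb) - 1L,
               start = (seq_len(nb) - 1L) * res,
               end = pmin(seq_len(nb) * res, matrix$chrom_sizes[[ch]]),
               score = score,
               label = fifelse(is.na(score), NA_character_,
                               fifelse(score > 0, "A", "B")))
  })
  track <- rbindlist(out)
  structure(track, class = c("compartment_track", class(track)),
            resolution = res, sample_id = matrix$sample_id)
}

#' @export
print.compartment_track <- function(x, ...) {
  cat("compartment_track '", attr(x, "sample_id"), "' at ",
      attr(x, "resolution"), " bp: ", nrow(x), " bins (",
      sum(!is.na(x$score)), " scored; ", sum(x$label == "A", na.rm = TRUE),
      " A / ", sum(x$label == "B", na.rm = TRUE), " B)\n", sep = "")
  invisible(x)
}

#' Delta c-score between two compartment tracks
#'
#' Per-bin difference `a - b`, defined only where both tracks are scored.
#'
#' @param track_a,track_b `compartment_track`s on the same bin grid.
#' @return `data.table` (chrom, bin, start, end, delta).
#' @export
delta_cscore <- function(track_a, track_b) {
  if (!identical(track_a$chrom, track_b$chrom) ||
      !identical(track_a$bin, track_b$bin))
    stop("compartment tracks are on different bin grids")
  data.table(chrom = track_a$chrom, bin = track_a$bin,
             start = track_a$start, end = track_a$end,
             delta = track_a$score - track_b$score)
}

score_column <- function(x) {
  for (nm in c("score", "delta")) if (nm %in% names(x)) return(x[[nm]])
  stop("no score or delta column found")
}

#' Pearson correlation between two score tracks
#'
#' Works for compartment tracks and for delta tracks; uses jointly
#' non-missing bins.
#'
#' @param track_a,track_b Tracks with a `score` or `delta` column on the
#'   same bin grid.
#' @return Pearson correlation coefficient.
#' @export
track_correlation <- function(track_a, track_b) {
  a <- score_column(track_a); b <- score_column(track_b)
  if (length(a) != length(b)) stop("tracks have different lengths")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 jointly scored bins")
  cor(a[ok], b[ok])
}
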