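# Base-graphics views of the main track objects.

#' @export
plot.v4c_track <- function(x, ..., col = "steelblue") {
  vp <- attr(x, "viewpoint")
  mid <- (x$start + x$end) / 2
  graphics::plot(mid / 1e6, x$cpm, type = "l", col = col,
                 xlab = paste0(x$chrom[1], " position (Mb)"),
                 ylab = "CPM",
                 main = sprintf("virtual 4C: %s:%s", vp$chrom,
                                format(vp$pos + 1, big.mark = ",")), ...)
  graphics::abline(v = (vp$pos + 1) / 1e6, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
plot.compartment_track <- function(x, chrom = x$chrom[1], ...) {
  sub <- x[x$chrom == chrom]
  col <- ifelse(is.na(sub$score), "grey80",
                ifelse(sub$score > 0, "firebrick", "navy"))
  graphics::barplot(ifelse(is.na(sub$score), 0, sub$score), col = col,
                    border = NA, space = 0,
                    xlab = paste0(chrom, " (", attr(x, "resolution") / 1e3,
                                  " kb bins)"),
                    ylab = "compartment score", ylim = c(-1, 1), ...)
  invisible(x)
}

#' Plot an aggregate peak analysis matrix
#'
#' @param apa Result of [aggregate_peak_analysis()].
#' @param ... Passed to [graphics::image()].
#' @export
plot_apa <- function(apa, ...) {
  m <- apa$apa
  w <- (nrow(m) - 1) / 2
  graphics::image(-w:w, -w:w, t(m[nrow(m):1, ]),
                  xlab = "offset from anchor 2 (bins)",
                  ylab = "offset from anchor 1 (bins)",
                  main = sprintf("APA score %.2f (n=%d loops)", apa$score,
                                 apa$n_loops), ...)
  invisible(apa)
}
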