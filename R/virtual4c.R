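# Virtual 4C: viewpoint-anchored interaction tracks from read pairs.
#
# A pair qualifies iff exactly one mate lies within viewpoint +/- flank;
# the distal mate adds a count to every overlapping window. Windows tile
# the viewpoint's chromosome from coordinate 0 with the given step (default
# 20 kb windows stepping 1 kb, i.e. adjacent windows overlap by 95% of
# their length); the final partial window is clipped. Pairs with both
# mates inside the viewpoint interval are excluded (no distal information).

#' Parse a viewpoint string
#'
#' Accepts "chr3:133544706" with a 1-based position as printed in genome
#' browsers and converts it to the 0-based position used internally.
#'
#' @param x String "chrom:pos" (commas allowed).
#' @param flank Half-width of the viewpoint interval in bp (default 10000).
#' @return List with `chrom`, `pos` (0-based) and `flank`.
#' @export
parse_viewpoint <- function(x, flank = 10000) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("viewpoint must be 'chrom:pos'")
  pos <- as.numeric(gsub(",", "", parts[2], fixed = TRUE))
  if (!is.finite(pos) || pos < 1) stop("invalid viewpoint position")
  viewpoint(parts[1], pos - 1, flank)
}

#' Construct a viewpoint
#'
#' @param chrom Chromosome name.
#' @param pos 0-based position in bp.
#' @param flank Half-width in bp (> 0).
#' @return List with `chrom`, `pos`, `flank`.
#' @export
viewpoint <- function(chrom, pos, flank = 10000) {
  stopifnot(flank > 0, pos >= 0)
  list(chrom = chrom, pos = pos, flank = flank)
}

#' Virtual 4C track around a viewpoint
#'
#' @param pairs `data.table`/data.frame of read pairs (chrom1, pos1,
#'   chrom2, pos2; 0-based bp).
#' @param chrom_sizes Named chromosome lengths.
#' @param viewpoint A [viewpoint()] (or [parse_viewpoint()] result).
#' @param window_size Window width in bp (default 20000).
#' @param step Window step in bp (default 1000).
#' @param total_depth Depth used for CPM; defaults to `nrow(pairs)` (the
#'   total sequencing depth of the sample).
#' @return A `v4c_track`: `data.table` (chrom, start, end, count, cpm), one
#'   row per window, with viewpoint/window attributes.
#' @export
virtual_4c <- function(pairs, chrom_sizes, viewpoint,
                       window_size = 20000, step = 1000,
                       total_depth = nrow(pairs)) {
  stopifnot(window_size > 0, step > 0, total_depth > 0)
  vp <- viewpoint
  if (!vp$chrom %in% names(chrom_sizes)) stop("viewpoint chromosome unknown")
  L <- chrom_sizes[[vp$chrom]]
  if (vp$pos >= L) stop("viewpoint position outside chromosome")
  pairs <- as.data.table(pairs)
  lo <- vp$pos - vp$flank; hi <- vp$pos + vp$flank
  in1 <- pairs$chrom1 == vp$chrom & pairs$pos1 >= lo & pairs$pos1 <= hi
  in2 <- pairs$chrom2 == vp$chrom & pairs$pos2 >= lo & pairs$pos2 <= hi
  qual <- xor(in1, in2)
  distal_chrom <- ifelse(in1, pairs$chrom2, pairs$chrom1)
  distal_pos <- ifelse(in1, pairs$pos2, pairs$pos1)
  use <- qual & distal_chrom == vp$chrom
  p <- distal_pos[use]

  starts <- seq(0, L - 1, by = step)
  nwin <- length(starts)
  counts <- numeric(nwin)
  if (length(p)) {
    first <- pmax(0, floor((p - window_size) / step) + 1)
    last <- pmin(nwin - 1, floor(p / step))
    keep <- last >= first
    first <- first[keep]; last <- last[keep]
    idx <- sequence(last - first + 1, from = first + 1)   # 1-based windows
    counts <- tabulate(idx, nbins = nwin)
  }
  if (sum(counts) == 0)
    warning("no qualifying read pairs for this viewpoint")
  track <- data.table(chrom = vp$chrom, start = starts,
                      end = pmin(starts + window_size, L),
                      count = as.numeric(counts),
                      cpm = counts * 1e6 / total_depth)
  structure(track, class = c("v4c_track", class(track)),
            viewpoint = vp, window_size = window_size, step = step,
            total_depth = total_depth,
            n_qualifying = length(p))
}

#' @export
print.v4c_track <- function(x, ...) {
  vp <- attr(x, "viewpoint")
  cat("v4c_track: viewpoint ", vp$chrom, ":", vp$pos + 1, " +/-", vp$flank,
      " bp; ", nrow(x), " windows (", attr(x, "window_size"), "/",
      attr(x, "step"), " bp); ", attr(x, "n_qualifying"),
      " qualifying pairs\n", sep = "")
  invisible(x)
}

#' Per-window log2 fold-change between two virtual 4C tracks
#'
#' @param track_a,track_b `v4c_track`s on identical window grids.
#' @param pseudocount Pseudocount in CPM units (default 1).
#' @return `data.table` (chrom, start, end, log2fc).
#' @export
v4c_log2fc <- function(track_a, track_b, pseudocount = 1.0) {
  if (!identical(track_a$start, track_b$start) ||
      !identical(track_a$chrom[1], track_b$chrom[1]))
    stop("window grids differ between tracks")
  data.table(chrom = track_a$chrom, start = track_a$start,
             end = track_a$end,
             log2fc = log2(track_a$cpm + pseudocount) -
               log2(track_b$cpm + pseudocount))
}

#' Write a track as bedGraph
#'
#' @param track `data.table` with chrom, start, end and a value column.
#' @param path Output path.
#' @param value Name of the value column (default "cpm").
#' @export
write_bedgraph <- function(track, path, value = "cpm") {
  fwrite(data.table(track$chrom, as.integer(track$start),
                    as.integer(track$end), track[[value]]),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
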