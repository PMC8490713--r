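# Loop classification by anchor overlap with promoter/enhancer intervals.
#
# An anchor "holds" a feature iff the feature interval overlaps the 1-bin
# anchor interval by >= 1 bp (0-based half-open on both sides). Ambiguous
# anchors (carrying both feature types) resolve by the precedence
# P-E > P-P > E-E > P-other > E-other > other.

LOOP_CLASSES <- c("P-E", "P-P", "E-E", "P-other", "E-other", "other")

anchors_gr <- function(loops, resolution, chrom_sizes) {
  GenomicRanges::GRanges(
    loops$chrom,
    IRanges::IRanges(start = loops$bin * resolution + 1,
                     end = pmin((loops$bin + 1) * resolution,
                                chrom_sizes[loops$chrom])))
}

features_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# which anchors (rows of data.frame with chrom, bin) overlap >=1 feature;
# also returns a list of feature names per anchor
anchor_hits <- function(anchor_df, features, resolution, chrom_sizes) {
  n <- nrow(anchor_df)
  if (!nrow(features) || !n)
    return(list(hit = logical(n), names = rep(list(character()), n)))
  a <- anchors_gr(anchor_df, resolution, chrom_sizes)
  f <- features_gr(features)
  ov <- GenomicRanges::findOverlaps(a, f, minoverlap = 1L)
  hit <- logical(n)
  hit[unique(S4Vectors::queryHits(ov))] <- TRUE
  nm <- rep(list(character()), n)
  if (length(ov) && "name" %in% names(features)) {
    sp <- split(features$name[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
    nm[as.integer(names(sp))] <- lapply(sp, unique)
  }
  list(hit = hit, names = nm)
}

#' Classify loops by promoter/enhancer anchor content
#'
#' A loop is promoter-enhancer (P-E) iff one anchor overlaps at least one
#' protein-coding gene promoter and the other anchor overlaps at least one
#' enhancer, in either orientation.
#'
#' @param loops `loop_set` or `data.frame` with chrom, bin1, bin2.
#' @param promoters BED-like `data.frame` (chrom, start, end, name = gene
#'   symbol), 0-based half-open.
#' @param enhancers BED-like `data.frame` (chrom, start, end), e.g.
#'   H3K27ac peaks.
#' @param resolution Bin size (taken from the `loop_set` attribute when
#'   absent).
#' @param chrom_sizes Named lengths (taken from the attribute when absent).
#' @return `data.table`: the input loops plus `class` (one of P-E, P-P,
#'   E-E, P-other, E-other, other) and `genes` (comma-separated promoter
#'   gene symbols on either anchor).
#' @export
classify_loops <- function(loops, promoters, enhancers,
                           resolution = attr(loops, "resolution"),
                           chrom_sizes = attr(loops, "chrom_sizes")) {
  if (is.null(resolution) || is.null(chrom_sizes))
    stop("resolution and chrom_sizes are required")
  dt <- as.data.table(loops)
  out <- copy(dt)
  if (!nrow(dt)) {
    out[, `:=`(class = character(), genes = character())]
    return(out[])
  }
  drop_unknown <- function(features) {
    unknown <- setdiff(unique(features$chrom), names(chrom_sizes))
    if (length(unknown)) {
      warning("annotation features on unknown chromosome(s) ignored: ",
              paste(unknown, collapse = ", "))
      features <- features[features$chrom %in% names(chrom_sizes), ,
                           drop = FALSE]
    }
    features
  }
  promoters <- drop_unknown(promoters)
  enhancers <- drop_unknown(enhancers)
  a1 <- data.frame(chrom = dt$chrom, bin = dt$bin1)
  a2 <- data.frame(chrom = dt$chrom, bin = dt$bin2)
  p1 <- anchor_hits(a1, promoters, resolution, chrom_sizes)
  p2 <- anchor_hits(a2, promoters, resolution, chrom_sizes)
  e1 <- anchor_hits(a1, enhancers, resolution, chrom_sizes)
  e2 <- anchor_hits(a2, enhancers, resolution, chrom_sizes)
  cls <- rep("other", nrow(dt))
  cls[(p1$hit | p2$hit)] <- "P-other"
  cls[(e1$hit | e2$hit) & !(p1$hit | p2$hit)] <- "E-other"
  cls[e1$hit & e2$hit & !(p1$hit | p2$hit)] <- "E-E"
  cls[p1$hit & p2$hit] <- "P-P"
  cls[(p1$hit & e2$hit) | (e1$hit & p2$hit)] <- "P-E"
  genes <- mapply(function(g1, g2) paste(unique(c(g1, g2)), collapse = ","),
                  p1$names, p2$names)
  out[, class := cls]
  out[, genes := genes]
  out[]
}

#' Per-class loop counts
#'
#' @param loops Annotated loops from [classify_loops()] (or raw loops plus
#'   `promoters`/`enhancers` passed through `...`).
#' @param ... Forwarded to [classify_loops()] when `loops` lacks a `class`
#'   column.
#' @return Named integer vector over all classes (P-E, P-P, E-E, P-other,
#'   E-other, other); counts sum to the number of loops.
#' @export
classify_set <- function(loops, ...) {
  if (!"class" %in% names(loops)) loops <- classify_loops(loops, ...)
  counts <- table(factor(loops$class, levels = LOOP_CLASSES))
  setNames(as.integer(counts), LOOP_CLASSES)
}
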