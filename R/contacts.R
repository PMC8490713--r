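# Contact-matrix construction from filtered Hi-C read pairs.
#
# Coordinates are 0-based bp throughout; bin k at resolution r covers
# [k*r, (k+1)*r) clipped to the chromosome end. Matrices are stored sparse
# and upper-triangular (bin1 <= bin2); inter-chromosomal pairs contribute to
# total_depth but are not stored, since all downstream analyses are cis.

#' Read a chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome in ", path)
  setNames(df$length, df$chrom)
}

#' Write a chrom.sizes file
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(chrom = names(chrom_sizes),
                         length = as.integer(chrom_sizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read filtered Hi-C read pairs
#'
#' Four tab-separated columns: chrom1, pos1, chrom2, pos2 (positions 0-based
#' bp). Malformed lines raise an error identifying the line number.
#'
#' @param path Path to the pairs TSV.
#' @return A `data.table` with columns chrom1, pos1, chrom2, pos2.
#' @export
read_pairs <- function(path) {
  dt <- tryCatch(
    suppressWarnings(
      fread(path, sep = "\t", header = FALSE,
            col.names = c("chrom1", "pos1", "chrom2", "pos2"),
            colClasses = list(character = c(1L, 3L), numeric = c(2L, 4L)))),
    error = function(e) stop("malformed pairs file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  bad <- which(!is.finite(dt$pos1) | !is.finite(dt$pos2))
  if (length(bad))
    stop("malformed pairs file ", path, ": non-numeric position at line ",
         bad[1], call. = FALSE)
  dt
}

#' Write read pairs as a 4-column TSV
#'
#' @param pairs `data.table`/data.frame with chrom1, pos1, chrom2, pos2.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  fwrite(as.data.table(pairs)[, .(chrom1, pos1 = as.integer(pos1),
                                  chrom2, pos2 = as.integer(pos2))],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

n_bins <- function(chrom_len, resolution) as.integer(ceiling(chrom_len / resolution))

#' Bin read pairs into a sparse contact matrix
#'
#' Each intra-chromosomal pair increments exactly one pixel
#' (`floor(pos/resolution)` per mate, anchors ordered `bin1 <= bin2`).
#' Inter-chromosomal pairs are counted into `total_depth` but not stored.
#'
#' @param pairs `data.table`/data.frame with chrom1, pos1, chrom2, pos2
#'   (0-based bp).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param resolution Bin size in bp.
#' @param sample_id Identifier recorded on the matrix.
#' @return A `contact_matrix`: list with `resolution`, `chrom_sizes`,
#'   `pixels` (chrom, bin1, bin2, count), `total_depth`, `sample_id`.
#' @export
bin_pairs <- function(pairs, chrom_sizes, resolution, sample_id = "sample") {
  stopifnot(resolution > 0)
  pairs <- as.data.table(pairs)
  known <- names(chrom_sizes)
  bad <- setdiff(unique(c(pairs$chrom1, pairs$chrom2)), known)
  if (length(bad)) stop("unknown chromosome in pairs: ", paste(bad, collapse = ", "))
  if (nrow(pairs)) {
    len1 <- chrom_sizes[pairs$chrom1]; len2 <- chrom_sizes[pairs$chrom2]
    if (any(pairs$pos1 < 0 | pairs$pos1 >= len1 | pairs$pos2 < 0 | pairs$pos2 >= len2))
      stop("pair coordinate outside chromosome bounds")
  }
  intra <- pairs[chrom1 == chrom2]
  if (nrow(intra)) {
    i <- as.integer(intra$pos1 %/% resolution)
    j <- as.integer(intra$pos2 %/% resolution)
    px <- data.table(chrom = intra$chrom1, bin1 = pmin(i, j), bin2 = pmax(i, j))
    px <- px[, .(count = .N), by = .(chrom, bin1, bin2)]
    setkey(px, chrom, bin1, bin2)
  } else {
    px <- data.table(chrom = character(), bin1 = integer(),
                     bin2 = integer(), count = integer())
  }
  structure(list(resolution = as.integer(resolution),
                 chrom_sizes = chrom_sizes,
                 pixels = px,
                 total_depth = nrow(pairs),
                 sample_id = sample_id),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix '", x$sample_id, "': ", length(x$chrom_sizes),
      " chromosome(s) at ", x$resolution, " bp\n", sep = "")
  cat("  stored pixels: ", nrow(x$pixels),
      "; intra-chromosomal pairs: ", sum(x$pixels$count),
      "; total depth: ", x$total_depth, "\n", sep = "")
  invisible(x)
}

#' Counts-per-million normalization
#'
#' CPM = count * 1e6 / total sequencing depth of the sample.
#'
#' @param matrix A `contact_matrix` (supplies the depth).
#' @param count Raw count(s) to normalize; defaults to all stored pixel
#'   counts.
#' @return Numeric CPM value(s).
#' @export
cpm <- function(matrix, count = matrix$pixels$count) {
  if (is.null(matrix$total_depth) || matrix$total_depth <= 0)
    stop("total_depth must be positive for CPM normalization")
  count * 1e6 / matrix$total_depth
}

#' Extract one chromosome as a dense symmetric matrix
#'
#' @param matrix A `contact_matrix`.
#' @param chrom Chromosome name.
#' @return Dense symmetric numeric matrix (bins x bins).
#' @export
dense_chrom <- function(matrix, chrom) {
  nb <- n_bins(matrix$chrom_sizes[[chrom]], matrix$resolution)
  m <- base::matrix(0, nb, nb)
  px <- matrix$pixels[matrix$pixels$chrom == chrom]
  if (nrow(px)) {
    m[cbind(px$bin1 + 1L, px$bin2 + 1L)] <- px$count
    m[cbind(px$bin2 + 1L, px$bin1 + 1L)] <- px$count
  }
  m
}

#' Write a contact matrix to a directory
#'
#' One 3-column TSV per chromosome (bin1, bin2, count) plus a JSON sidecar
#' with resolution, chromosome sizes, depth and sample id.
#'
#' @param matrix A `contact_matrix`.
#' @param dir Output directory (created if absent).
#' @export
write_contact_matrix <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(matrix$chrom_sizes)) {
    px <- matrix$pixels[chrom == ch, .(bin1, bin2, count)]
    fwrite(px, file.path(dir, paste0(ch, ".matrix.tsv")), sep = "\t")
  }
  jsonlite::write_json(
    list(resolution = matrix$resolution,
         chrom_sizes = as.list(matrix$chrom_sizes),
         total_depth = matrix$total_depth,
         sample_id = matrix$sample_id),
    file.path(dir, "matrix.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a contact matrix written by [write_contact_matrix()]
#'
#' @param dir Directory containing per-chromosome TSVs and matrix.json.
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "matrix.json"), simplifyVector = TRUE)
  sizes <- unlist(meta$chrom_sizes)
  px <- rbindlist(lapply(names(sizes), function(ch) {
    f <- file.path(dir, paste0(ch, ".matrix.tsv"))
    dt <- fread(f, sep = "\t")
    if (nrow(dt)) dt[, chrom := ch] else dt[, chrom := character(0)]
    dt[, .(chrom, bin1 = as.integer(bin1), bin2 = as.integer(bin2),
           count = as.integer(count))]
  }))
  setkey(px, chrom, bin1, bin2)
  structure(list(resolution = as.integer(meta$resolution),
                 chrom_sizes = sizes,
                 pixels = px,
                 total_depth = as.numeric(meta$total_depth),
                 sample_id = meta$sample_id),
            class = "contact_matrix")
}
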