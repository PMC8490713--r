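# Seeded synthetic-data generator with known ground truth.
#
# Read pairs are drawn by inverse-CDF sampling over the intra-chromosomal
# pixel universe (1 <= distance <= n_bins-1) with unnormalized weight
#   d^(-alpha) * checkerboard factor * loop enrichment,
# then scattered uniformly within each bin. This gives closed-form expected
# pixel means (depth * weight / total weight) for recovery tests.
# Overdispersion enters through gamma-distributed per-pixel rate multipliers
# (mean 1, variance = dispersion), matching the negative-binomial background
# the loop caller assumes. Diagonal (d = 0) pixels are not emitted: real
# input pairs have self-ligation products removed upstream.

#' Build a simulation configuration
#'
#' @param chrom_sizes Named numeric vector: chromosome name -> length (bp).
#'   Default: two 20 Mb chromosomes.
#' @param resolution Bin size in bp (default 20000).
#' @param depth Total number of read pairs to emit.
#' @param decay_exponent Power-law slope alpha of contact decay with distance
#'   (expected intensity proportional to d^-alpha); default 1, the canonical
#'   Hi-C regime.
#' @param planted_loops `data.frame` with columns chrom, bin1, bin2 and one
#'   or more enrichment columns: either a single `enrichment` column applied
#'   to every condition, or one column per condition name. Enrichment factors
#'   must be >= 1 and bin1 < bin2.
#' @param compartment_blocks `data.frame` with columns chrom, start_bin,
#'   end_bin (0-based, end exclusive), label ("A" or "B"). Blocks must tile
#'   each listed chromosome without overlap. `NULL` disables checkerboard
#'   structure (all bins labelled "A").
#' @param checkerboard_strength Multiplicative boost (>= 1) for contacts
#'   between two bins with the same compartment label.
#' @param dispersion Variance of the gamma per-pixel rate multipliers; 0
#'   gives (conditionally) Poisson-like sampling. Default 0.05.
#' @param peak_prob_A,peak_prob_B Per-bin probability of emitting an
#'   H3K27ac-like reference peak in A and B bins.
#' @param seed Integer seed; all stochastic operations derive from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(chrom_sizes = c(chr1 = 2e7, chr2 = 2e7),
                       resolution = 20000,
                       depth = 2e5,
                       decay_exponent = 1,
                       planted_loops = NULL,
                       compartment_blocks = NULL,
                       checkerboard_strength = 1,
                       dispersion = 0.05,
                       peak_prob_A = 0.6,
                       peak_prob_B = 0.05,
                       seed = 1L) {
  stopifnot(resolution > 0, depth > 0, decay_exponent > 0,
            checkerboard_strength >= 1, dispersion >= 0)
  nb <- vapply(chrom_sizes, n_bins, integer(1), resolution = resolution)
  if (!is.null(planted_loops)) {
    planted_loops <- as.data.frame(planted_loops)
    req <- c("chrom", "bin1", "bin2")
    if (!all(req %in% names(planted_loops)))
      stop("planted_loops needs columns chrom, bin1, bin2")
    if (!all(planted_loops$chrom %in% names(chrom_sizes)))
      stop("planted loop on unknown chromosome")
    if (any(planted_loops$bin1 >= planted_loops$bin2))
      stop("planted loops require bin1 < bin2")
    if (any(planted_loops$bin1 < 0) ||
        any(planted_loops$bin2 >= nb[planted_loops$chrom]))
      stop("planted loop anchor outside the simulated genome")
    enr_cols <- setdiff(names(planted_loops), req)
    if (!length(enr_cols)) stop("planted_loops needs at least one enrichment column")
    if (any(as.matrix(planted_loops[enr_cols]) < 1))
      stop("loop enrichment factors must be >= 1")
  }
  if (!is.null(compartment_blocks)) {
    compartment_blocks <- as.data.frame(compartment_blocks)
    stopifnot(all(c("chrom", "start_bin", "end_bin", "label") %in%
                    names(compartment_blocks)))
    if (!all(compartment_blocks$label %in% c("A", "B")))
      stop("block labels must be 'A' or 'B'")
    for (ch in unique(compartment_blocks$chrom)) {
      b <- compartment_blocks[compartment_blocks$chrom == ch, ]
      b <- b[order(b$start_bin), ]
      if (b$start_bin[1] != 0 || b$end_bin[nrow(b)] != nb[[ch]] ||
          (nrow(b) > 1 && any(b$start_bin[-1] != b$end_bin[-nrow(b)])))
        stop("compartment blocks must tile chromosome ", ch, " without overlap")
    }
  }
  structure(list(chrom_sizes = chrom_sizes, resolution = resolution,
                 depth = as.integer(depth), decay_exponent = decay_exponent,
                 planted_loops = planted_loops,
                 compartment_blocks = compartment_blocks,
                 checkerboard_strength = checkerboard_strength,
                 dispersion = dispersion,
                 peak_prob_A = peak_prob_A, peak_prob_B = peak_prob_B,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Alternating compartment blocks for a toy genome
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param resolution Bin size in bp.
#' @param block_bins Bins per block.
#' @return `data.frame` of alternating A/B blocks tiling each chromosome.
#' @export
alternating_blocks <- function(chrom_sizes, resolution, block_bins) {
  out <- lapply(names(chrom_sizes), function(ch) {
    nb <- n_bins(chrom_sizes[[ch]], resolution)
    starts <- seq(0L, nb - 1L, by = block_bins)
    data.frame(chrom = ch, start_bin = starts,
               end_bin = pmin(starts + block_bins, nb),
               label = rep_len(c("A", "B"), length(starts)))
  })
  do.call(rbind, out)
}

# Per-chromosome bin labels from the block table ("A" everywhere if NULL).
block_labels <- function(config) {
  lapply(names(config$chrom_sizes), function(ch) {
    nb <- n_bins(config$chrom_sizes[[ch]], config$resolution)
    lab <- rep("A", nb)
    cb <- config$compartment_blocks
    if (!is.null(cb)) {
      b <- cb[cb$chrom == ch, ]
      for (k in seq_len(nrow(b)))
        lab[(b$start_bin[k] + 1L):b$end_bin[k]] <- b$label[k]
    }
    lab
  }) |> setNames(names(config$chrom_sizes))
}

loop_enrichment_col <- function(planted_loops, condition) {
  if (is.null(planted_loops)) return(NULL)
  if (condition %in% names(planted_loops)) planted_loops[[condition]]
  else if ("enrichment" %in% names(planted_loops)) planted_loops$enrichment
  else stop("no enrichment column for condition '", condition, "'")
}

#' Simulate Hi-C read pairs with known ground truth
#'
#' Emits exactly `config$depth` intra-chromosomal pairs. Expected pixel
#' intensity is proportional to `d^-alpha` times the checkerboard factor
#' times the loop enrichment at planted pixels; deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param condition Condition identifier selecting the loop-enrichment
#'   column (falls back to the `enrichment` column).
#' @param seed Overrides `config$seed` when given.
#' @return List with `pairs` (data.table chrom1, pos1, chrom2, pos2) and
#'   `truth` (a `sim_truth`: loop registry with this condition's enrichment,
#'   per-bin compartment labels, H3K27ac-like reference peaks, and the
#'   closed-form expected background mean per diagonal).
#' @export
simulate_contacts <- function(config, condition = "A", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  res <- config$resolution
  labels <- block_labels(config)
  enr <- loop_enrichment_col(config$planted_loops, condition)

  per_chrom <- lapply(names(config$chrom_sizes), function(ch) {
    nb <- n_bins(config$chrom_sizes[[ch]], res)
    d <- rep(seq_len(nb - 1L), times = nb - seq_len(nb - 1L)) # diagonal-major
    i <- sequence(nb - seq_len(nb - 1L), from = 0L) # 0..nb-1-d for each d
    j <- i + d
    w <- d^(-config$decay_exponent)
    lab <- labels[[ch]]
    if (config$checkerboard_strength > 1) {
      same <- lab[i + 1L] == lab[j + 1L]
      w[same] <- w[same] * config$checkerboard_strength
    }
    pl <- config$planted_loops
    if (!is.null(pl)) {
      sel <- pl$chrom == ch
      if (any(sel)) {
        # pixels are laid out diagonal-major: offset(d) + i + 1
        off <- cumsum(c(0L, nb - seq_len(nb - 1L)))
        idx <- off[pl$bin2[sel] - pl$bin1[sel]] + pl$bin1[sel] + 1L
        w[idx] <- w[idx] * enr[sel]
      }
    }
    list(chrom = ch, nb = nb, i = i, j = j, w = w)
  })

  base_total <- sum(vapply(per_chrom, function(x) sum(x$w), numeric(1)))

  # gamma rate multipliers (mean 1, var = dispersion)
  w_all <- unlist(lapply(per_chrom, `[[`, "w"), use.names = FALSE)
  if (config$dispersion > 0) {
    shp <- 1 / config$dispersion
    w_all <- w_all * rgamma(length(w_all), shape = shp, rate = shp)
  }
  cw <- cumsum(w_all)
  u <- runif(config$depth) * cw[length(cw)]
  pick <- findInterval(u, cw) + 1L

  n_per <- vapply(per_chrom, function(x) length(x$w), integer(1))
  chrom_of <- rep(seq_along(per_chrom), n_per)
  i_all <- unlist(lapply(per_chrom, `[[`, "i"), use.names = FALSE)
  j_all <- unlist(lapply(per_chrom, `[[`, "j"), use.names = FALSE)
  ch_names <- vapply(per_chrom, `[[`, character(1), "chrom")

  ch <- ch_names[chrom_of[pick]]
  bi <- i_all[pick]; bj <- j_all[pick]
  len <- config$chrom_sizes[ch]
  pos1 <- bi * res + floor(runif(length(bi)) * pmin(res, len - bi * res))
  pos2 <- bj * res + floor(runif(length(bj)) * pmin(res, len - bj * res))
  pairs <- data.table(chrom1 = ch, pos1 = as.numeric(pos1),
                      chrom2 = ch, pos2 = as.numeric(pos2))

  peaks <- simulate_reference_peaks(config, labels)

  loops <- config$planted_loops
  if (!is.null(loops)) {
    loops <- data.frame(chrom = loops$chrom, bin1 = loops$bin1,
                        bin2 = loops$bin2, enrichment = enr)
  }
  truth <- structure(list(
    chrom_sizes = config$chrom_sizes, resolution = res,
    depth = config$depth, decay_exponent = config$decay_exponent,
    checkerboard_strength = config$checkerboard_strength,
    labels = labels, loops = loops, peaks = peaks,
    base_total_weight = base_total, condition = condition,
    seed = seed), class = "sim_truth")
  list(pairs = pairs, truth = truth)
}

# H3K27ac-like 1 kb peaks, enriched in A bins.
simulate_reference_peaks <- function(config, labels) {
  res <- config$resolution
  out <- lapply(names(labels), function(ch) {
    lab <- labels[[ch]]
    p <- ifelse(lab == "A", config$peak_prob_A, config$peak_prob_B)
    hit <- runif(length(lab)) < p
    if (!any(hit)) return(NULL)
    bins <- which(hit) - 1L
    start <- bins * res + res %/% 2 - 500L
    data.frame(chrom = ch, start = pmax(start, 0L),
               end = pmax(start, 0L) + 1000L)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
  out
}

#' Closed-form expected count at a pixel of a simulated matrix
#'
#' `depth * d^-alpha * checkerboard factor * loop enrichment / total weight`,
#' marginalized over the gamma multipliers (which have mean 1).
#'
#' @param truth A `sim_truth` from [simulate_contacts()].
#' @param chrom,bin1,bin2 Pixel coordinates (vectors recycled).
#' @return Expected count(s).
#' @export
expected_pixel_count <- function(truth, chrom, bin1, bin2) {
  d <- bin2 - bin1
  stopifnot(all(d >= 1))
  w <- d^(-truth$decay_exponent)
  lab1 <- mapply(function(ch, b) truth$labels[[ch]][b + 1L], chrom, bin1)
  lab2 <- mapply(function(ch, b) truth$labels[[ch]][b + 1L], chrom, bin2)
  w <- w * ifelse(lab1 == lab2, truth$checkerboard_strength, 1)
  if (!is.null(truth$loops) && nrow(truth$loops)) {
    key <- paste(chrom, bin1, bin2)
    lkey <- paste(truth$loops$chrom, truth$loops$bin1, truth$loops$bin2)
    m <- match(key, lkey)
    w <- w * ifelse(is.na(m), 1, truth$loops$enrichment[m])
  }
  unname(truth$depth * w / truth$base_total_weight)
}

#' Write / read simulation truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param path JSON path.
#' @return `read_sim_truth` returns the `sim_truth`.
#' @export
write_sim_truth <- function(truth, path) {
  x <- unclass(truth)
  x$chrom_sizes <- as.list(x$chrom_sizes)   # keep names through JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$chrom_sizes <- unlist(x$chrom_sizes)
  x$labels <- lapply(x$labels, as.character)
  if (!is.null(x$loops)) x$loops <- as.data.frame(x$loops)
  if (!is.null(x$peaks)) x$peaks <- as.data.frame(x$peaks)
  structure(x, class = "sim_truth")
}

#' Simulate promoter and enhancer annotations for planted loops
#'
#' A requested fraction of the planted loops receives a promoter interval
#' inside one anchor and an enhancer inside the other; the remaining
#' intervals are placed uniformly at random. All intervals are sorted,
#' non-negative and within chromosome bounds.
#'
#' @param truth A `sim_truth` with a loop registry.
#' @param loops_covered Fraction in [0,1] of planted loops to cover with a
#'   promoter-enhancer pair.
#' @param n_random Extra randomly placed promoters and enhancers (each).
#' @param feature_width Width in bp of emitted intervals.
#' @param seed Integer seed.
#' @return List with `promoters` and `enhancers`: BED-like `data.frame`s
#'   (chrom, start, end, name, score, strand); promoter names are gene
#'   symbols.
#' @export
simulate_annotations <- function(truth, loops_covered = 1, n_random = 20,
                                 feature_width = 2000, seed = truth$seed) {
  if (loops_covered < 0 || loops_covered > 1)
    stop("loops_covered must be in [0, 1]")
  set.seed(seed + 1L)
  res <- truth$resolution
  loops <- truth$loops
  prom <- enh <- list()
  if (!is.null(loops) && nrow(loops) && loops_covered > 0) {
    n_cov <- round(loops_covered * nrow(loops))
    idx <- if (n_cov >= nrow(loops)) seq_len(nrow(loops)) else
      sort(sample.int(nrow(loops), n_cov))
    anchor_feature <- function(ch, bin) {
      lo <- bin * res
      hi <- pmin((bin + 1) * res, truth$chrom_sizes[ch]) - feature_width
      s <- floor(lo + runif(length(bin)) * pmax(hi - lo, 1))
      cbind(s, s + feature_width)
    }
    pf <- anchor_feature(loops$chrom[idx], loops$bin1[idx])
    ef <- anchor_feature(loops$chrom[idx], loops$bin2[idx])
    prom <- list(data.frame(chrom = loops$chrom[idx], start = pf[, 1],
                            end = pf[, 2],
                            name = paste0("gene", idx)))
    enh <- list(data.frame(chrom = loops$chrom[idx], start = ef[, 1],
                           end = ef[, 2],
                           name = paste0("enh", idx)))
  }
  random_features <- function(n, prefix) {
    ch <- sample(names(truth$chrom_sizes), n, replace = TRUE)
    s <- floor(runif(n) * (truth$chrom_sizes[ch] - feature_width))
    data.frame(chrom = ch, start = s, end = s + feature_width,
               name = paste0(prefix, "rand", seq_len(n)))
  }
  if (n_random > 0) {
    prom <- c(prom, list(random_features(n_random, "gene_")))
    enh <- c(enh, list(random_features(n_random, "enh_")))
  }
  finish <- function(lst) {
    df <- if (length(lst)) do.call(rbind, lst) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 name = character())
    df <- df[order(df$chrom, df$start), ]
    df$score <- 0L; df$strand <- "."
    rownames(df) <- NULL
    df
  }
  list(promoters = finish(prom), enhancers = finish(enh))
}

#' Write a BED6 file
#'
#' @param df `data.frame` with chrom, start, end and optional name, score,
#'   strand.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = as.integer(df$start),
                    end = as.integer(df$end),
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0L,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 (or BED3/BED4) file
#'
#' @param path BED path.
#' @return `data.frame` with chrom, start, end and any of name, score,
#'   strand present in the file.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(df))]
  df$chrom <- as.character(df$chrom)
  df
}
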