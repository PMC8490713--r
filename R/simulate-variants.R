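# Stratified synthetic somatic-variant tables with known pass/fail truth.
#
# Variants are drawn to straddle every retention rule: caller support
# (1/2/3 tools), total depth around 30, alt reads around 5, tumor VAF
# around 10%, germline VAF around 1%, dbSNP membership, and consequence
# class. Truth labels encode the expected verdict under consensus (>= 2
# callers) plus the hard filters.

CALLERS <- c("MuTect", "Strelka2", "VarScan")

RETAINED_CONSEQUENCES <- c("missense", "synonymous", "stop_gained",
                           "frameshift", "splice_region", "NMD_transcript")

DROPPED_CONSEQUENCES <- c("intron", "intergenic", "upstream", "3_prime_UTR")

#' Simulate per-caller somatic variant tables with truth labels
#'
#' @param n_variants Number of variants to emit (> 0). The first variants
#'   deterministically cover each filter dimension at, above and below its
#'   threshold; the remainder are drawn at random across all dimensions.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param samples Sample identifiers to distribute variants over.
#' @return List with `tables` (named list of per-caller `data.frame`s:
#'   sample_id, chrom, pos, ref, alt, tumor_depth, tumor_alt, germline_vaf,
#'   consequence, dbsnp, gene) and `truth` (`data.frame` keyed like the
#'   tables with logical `pass` and the first failing `rule`).
#' @export
simulate_variant_tables <- function(n_variants, seed = 1L,
                                    samples = c("s1", "s2")) {
  stopifnot(n_variants > 0)
  set.seed(seed + 2L)

  fixed <- boundary_variant_grid()
  n_fixed <- min(nrow(fixed), n_variants)
  fixed <- fixed[seq_len(n_fixed), ]

  n_rand <- n_variants - n_fixed
  if (n_rand > 0) {
    rand <- data.frame(
      n_callers = sample(1:3, n_rand, replace = TRUE, prob = c(.25, .35, .4)),
      tumor_depth = sample(c(20:40, 60, 100, 200), n_rand, replace = TRUE),
      tumor_alt = sample(c(2:8, 12, 20, 40), n_rand, replace = TRUE),
      germline_vaf = sample(c(0, 0.005, 0.01, 0.012, 0.05), n_rand,
                            replace = TRUE),
      dbsnp = sample(c(TRUE, FALSE), n_rand, replace = TRUE, prob = c(.2, .8)),
      consequence = sample(c(RETAINED_CONSEQUENCES, DROPPED_CONSEQUENCES),
                           n_rand, replace = TRUE)
    )
    rand$tumor_alt <- pmin(rand$tumor_alt, rand$tumor_depth)
    vars <- rbind(fixed, rand)
  } else {
    vars <- fixed
  }

  n <- nrow(vars)
  vars$sample_id <- sample(samples, n, replace = TRUE)
  vars$chrom <- sample(c("chr1", "chr2", "chr3"), n, replace = TRUE)
  vars$pos <- sample.int(1e6, n)                      # unique site per variant
  bases <- c("A", "C", "G", "T")
  vars$ref <- sample(bases, n, replace = TRUE)
  vars$alt <- vapply(vars$ref, function(r) sample(setdiff(bases, r), 1), "")
  vars$gene <- paste0("Gene", sample.int(30, n, replace = TRUE))

  verdict <- variant_truth(vars)
  vars$pass <- verdict$pass
  vars$rule <- verdict$rule

  caller_sets <- lapply(vars$n_callers, function(k) sort(sample(CALLERS, k)))
  tables <- lapply(CALLERS, function(cl) {
    keep <- vapply(caller_sets, function(s) cl %in% s, logical(1))
    out <- vars[keep, c("sample_id", "chrom", "pos", "ref", "alt",
                        "tumor_depth", "tumor_alt", "germline_vaf",
                        "consequence", "dbsnp", "gene")]
    rownames(out) <- NULL
    out
  })
  names(tables) <- CALLERS

  truth <- vars[, c("sample_id", "chrom", "pos", "ref", "alt", "n_callers",
                    "pass", "rule")]
  list(tables = tables, truth = truth)
}

# One row per boundary case: each rule exercised at, just below and just
# above its threshold, on an otherwise-passing background variant.
boundary_variant_grid <- function() {
  base <- data.frame(n_callers = 3L, tumor_depth = 100L, tumor_alt = 20L,
                     germline_vaf = 0, dbsnp = FALSE, consequence = "missense")
  rows <- list(
    base,                                                      # clean pass
    transform(base, n_callers = 1L),                           # consensus fail
    transform(base, n_callers = 2L),                           # consensus edge
    transform(base, tumor_depth = 29L, tumor_alt = 10L),       # depth < 30
    transform(base, tumor_depth = 30L, tumor_alt = 10L),       # depth == 30
    transform(base, tumor_alt = 4L),                           # alt < 5
    transform(base, tumor_alt = 5L),                           # alt == 5
    transform(base, tumor_depth = 200L, tumor_alt = 19L),      # tVAF 9.5%
    transform(base, tumor_depth = 200L, tumor_alt = 20L),      # tVAF == 10%
    transform(base, germline_vaf = 0.011),                     # gVAF > 1%
    transform(base, germline_vaf = 0.01),                      # gVAF == 1%
    transform(base, dbsnp = TRUE),                             # dbSNP
    transform(base, consequence = "intron")                    # consequence
  )
  do.call(rbind, rows)
}

#' Boundary fixture for the somatic hard filters
#'
#' A small deterministic variant set exercising every retention rule at,
#' just below and just above its threshold, with expected verdicts.
#'
#' @return `data.frame` of variants with `pass` and first failing `rule`.
#' @export
boundary_variant_fixture <- function() {
  g <- boundary_variant_grid()
  n <- nrow(g)
  g$sample_id <- "s1"; g$chrom <- "chr1"; g$pos <- seq_len(n) * 1000L
  g$ref <- "A"; g$alt <- "G"; g$gene <- paste0("Gene", seq_len(n))
  v <- variant_truth(g)
  g$pass <- v$pass; g$rule <- v$rule
  g
}

# Expected verdict under consensus + hard filters, in the fixed rule order.
variant_truth <- function(v) {
  tvaf <- ifelse(v$tumor_depth > 0, v$tumor_alt / v$tumor_depth, NA_real_)
  rule <- rep(NA_character_, nrow(v))
  rule[is.na(rule) & v$n_callers < 2] <- "consensus"
  rule[is.na(rule) & v$tumor_depth < 30] <- "depth"
  rule[is.na(rule) & v$tumor_alt < 5] <- "alt_reads"
  rule[is.na(rule) & (is.na(tvaf) | tvaf < 0.10)] <- "tumor_vaf"
  rule[is.na(rule) & v$germline_vaf > 0.01] <- "germline_vaf"
  rule[is.na(rule) & v$dbsnp] <- "dbsnp"
  rule[is.na(rule) & !(v$consequence %in% RETAINED_CONSEQUENCES)] <- "consequence"
  list(pass = is.na(rule), rule = rule)
}

#' Write / read a variant table as TSV
#'
#' @param df Variant `data.frame`.
#' @param path TSV path.
#' @export
write_variant_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df
}
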