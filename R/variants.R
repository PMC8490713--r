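# Consensus somatic-variant filtering, percent genome altered, and
# per-gene mutation tallies.
#
# Retention thresholds mirror the exclusion rules "depth < 30, supporting
# reads < 5, tumor VAF < 10%, germline VAF > 1%" read strictly, so the
# boundary itself is retained (depth >= 30, alt >= 5, VAF >= 0.10,
# gVAF <= 0.01), plus dbSNP removal and a consequence whitelist
# (missense, silent and truncating classes).

variant_key <- function(df) {
  paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt, sep = "\r")
}

#' Merge per-caller variant tables by consensus
#'
#' Variants are keyed by (sample, chrom, pos, ref, alt); only keys reported
#' by at least `min_callers` tools survive. Numeric fields are taken from
#' the first caller, in `caller_priority` order, that reported the variant.
#'
#' @param tables Named list of per-caller `data.frame`s (sample_id, chrom,
#'   pos, ref, alt, tumor_depth, tumor_alt, germline_vaf, consequence,
#'   dbsnp, gene).
#' @param min_callers Minimum supporting callers (default 2).
#' @param caller_priority Order for numeric-field precedence; default
#'   alphabetical over the supplied caller names.
#' @return `data.table` of merged variants with a `callers`
#'   (comma-separated) and `n_callers` column.
#' @export
consensus_merge <- function(tables, min_callers = 2L,
                            caller_priority = sort(names(tables))) {
  if (length(tables) < 2) stop("need at least two caller tables")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("caller tables must be named")
  for (cl in names(tables)) {
    k <- variant_key(tables[[cl]])
    if (anyDuplicated(k))
      stop("duplicate variant key within caller table '", cl, "'")
  }
  long <- rbindlist(lapply(names(tables), function(cl) {
    dt <- as.data.table(tables[[cl]])
    dt[, caller := cl]
    dt
  }), use.names = TRUE, fill = TRUE)
  long[, caller := factor(caller, levels = caller_priority)]
  setorder(long, caller)
  key_cols <- c("sample_id", "chrom", "pos", "ref", "alt")
  merged <- long[, c(.SD[1],
                     .(callers = paste(sort(as.character(caller)),
                                       collapse = ","),
                       n_callers = .N)),
                 by = key_cols,
                 .SDcols = setdiff(names(long), c(key_cols, "caller"))]
  merged <- merged[n_callers >= min_callers]
  setorder(merged, sample_id, chrom, pos)
  merged[]
}

#' Apply the hard somatic-variant filters
#'
#' Rules, evaluated in order for the report: total depth >= 30, supporting
#' reads >= 5, tumor VAF >= 10%, germline VAF <= 1%, not a known dbSNP,
#' consequence in the retained set. A variant's verdict records the first
#' failing rule; zero depth makes the tumor VAF undefined and fails
#' "depth".
#'
#' @param variants Consensus-merged variants (see [consensus_merge()]).
#' @param min_depth,min_alt,min_tumor_vaf,max_germline_vaf Thresholds
#'   (defaults 30, 5, 0.10, 0.01).
#' @param retained_consequences Consequence whitelist; defaults to
#'   missense, synonymous and the truncating classes (stop gained,
#'   frameshift, splice region, NMD transcript).
#' @return List: `retained` (passing variants), `report` (`data.table`
#'   rule/n, including "retained"; counts partition the input), `verdicts`
#'   (per-variant pass + first failing rule).
#' @export
apply_hard_filters <- function(variants,
                               min_depth = 30, min_alt = 5,
                               min_tumor_vaf = 0.10,
                               max_germline_vaf = 0.01,
                               retained_consequences = RETAINED_CONSEQUENCES) {
  v <- as.data.table(variants)
  tvaf <- ifelse(v$tumor_depth > 0, v$tumor_alt / v$tumor_depth, NA_real_)
  rule <- rep(NA_character_, nrow(v))
  rule[is.na(rule) & (v$tumor_depth < min_depth | v$tumor_depth <= 0)] <- "depth"
  rule[is.na(rule) & v$tumor_alt < min_alt] <- "alt_reads"
  rule[is.na(rule) & (is.na(tvaf) | tvaf < min_tumor_vaf)] <- "tumor_vaf"
  rule[is.na(rule) & v$germline_vaf > max_germline_vaf] <- "germline_vaf"
  rule[is.na(rule) & v$dbsnp] <- "dbsnp"
  rule[is.na(rule) & !(v$consequence %in% retained_consequences)] <- "consequence"
  pass <- is.na(rule)
  rules <- c("depth", "alt_reads", "tumor_vaf", "germline_vaf", "dbsnp",
             "consequence")
  report <- data.table(rule = c(rules, "retained"),
                       n = c(vapply(rules, function(r) sum(rule == r,
                                                           na.rm = TRUE),
                                    integer(1)),
                             sum(pass)))
  verdicts <- data.table(v[, .(sample_id, chrom, pos, ref, alt)],
                         pass = pass, rule = rule)
  list(retained = v[pass], report = report, verdicts = verdicts)
}

#' Percent genome altered from copy-number segments
#'
#' Gains are segments with log2 ratio above `threshold`, losses below
#' `-threshold`; each percentage is total altered length over the genome
#' size.
#'
#' @param segments `data.frame` (chrom, start, end, log2_ratio) for one
#'   sample; segments must not overlap.
#' @param genome_size Genome size in bp.
#' @param threshold Log2-ratio magnitude defining an alteration
#'   (default 0.1, strict inequality).
#' @return Named numeric vector `c(gain = %, loss = %)`.
#' @export
percent_genome_altered <- function(segments, genome_size, threshold = 0.1) {
  stopifnot(genome_size > 0)
  seg <- as.data.table(segments)
  stopifnot(all(seg$start < seg$end))
  setorder(seg, chrom, start)
  if (nrow(seg) > 1) {
    same <- seg$chrom[-1] == seg$chrom[-nrow(seg)]
    if (any(same & seg$start[-1] < seg$end[-nrow(seg)]))
      stop("overlapping copy-number segments")
  }
  len <- seg$end - seg$start
  c(gain = 100 * sum(len[seg$log2_ratio > threshold]) / genome_size,
    loss = 100 * sum(len[seg$log2_ratio < -threshold]) / genome_size)
}

#' Per-gene mutation tallies across a cohort
#'
#' A gene counts as mutated in a sample iff the sample carries at least one
#' retained variant in it (set semantics: multiple variants count once).
#'
#' @param variants Retained variants with `gene` and `sample_id` columns.
#' @param gene_panel Character vector of genes to report (non-empty).
#' @param groups Named character vector or `data.frame`
#'   (sample_id, group) mapping every sample to its cohort group.
#' @return `data.table` (gene, group, n_mutated, group_size, frequency) in
#'   long, oncoprint-ready format; genes absent from all samples are
#'   reported with 0.
#' @export
gene_mutation_tally <- function(variants, gene_panel, groups) {
  if (!length(gene_panel)) stop("gene panel is empty")
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample_id)
  v <- as.data.table(variants)
  unknown <- setdiff(unique(v$sample_id), names(groups))
  if (length(unknown))
    stop("sample(s) with unknown group: ", paste(unknown, collapse = ", "))
  group_sizes <- table(groups)
  grid <- CJ(gene = gene_panel, group = names(group_sizes), unique = TRUE)
  hits <- unique(v[gene %in% gene_panel, .(gene, sample_id)])
  hits[, group := groups[sample_id]]
  cnt <- hits[, .(n_mutated = uniqueN(sample_id)), by = .(gene, group)]
  out <- merge(grid, cnt, by = c("gene", "group"), all.x = TRUE)
  out[is.na(n_mutated), n_mutated := 0L]
  out[, group_size := as.integer(group_sizes[group])]
  out[, frequency := n_mutated / group_size]
  setorder(out, gene, group)
  out[]
}
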