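# Shared fixtures, built in code and cached per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

toy_genome <- c(chr1 = 2e7, chr2 = 2e7)

# 50 loops at short distances (2-6 bins) so expected loop CPM clears the
# CPM>30 gate; enrichment alternates 4 and 8
recovery_loops <- function(seed = 1) {
  set.seed(seed)
  loops <- data.frame(chrom = rep(c("chr1", "chr2"), each = 25),
                      bin1 = round(rep(seq(40, 960, length.out = 25), 2)),
                      enrichment = rep(c(4, 8), 25))
  loops$bin2 <- loops$bin1 + sample(2:6, 50, replace = TRUE)
  loops[, c("chrom", "bin1", "bin2", "enrichment")]
}

# a pooled simulated matrix with planted loops, reused across test files
recovery_fixture <- function() {
  fixture("recovery", {
    loops <- recovery_loops()
    cfg <- sim_config(chrom_sizes = toy_genome, depth = 1e6,
                      planted_loops = loops, seed = 11)
    sim <- simulate_contacts(cfg, "A")
    mat <- bin_pairs(sim$pairs, cfg$chrom_sizes, cfg$resolution, "rec")
    list(cfg = cfg, loops = loops, sim = sim, mat = mat,
         calls = suppressMessages(call_loops(mat)))
  })
}

loop_key <- function(df) paste(df$chrom, df$bin1, df$bin2)

# checkerboard fixture at 100 kb (alternating 2 Mb A/B blocks, 1.5x boost)
compartment_fixture <- function() {
  fixture("compartment", {
    blocks <- alternating_blocks(toy_genome, 1e5, 20)
    cfg <- sim_config(chrom_sizes = toy_genome, resolution = 1e5,
                      depth = 5e5, compartment_blocks = blocks,
                      checkerboard_strength = 1.5, seed = 5)
    sim <- simulate_contacts(cfg, "A")
    mat <- bin_pairs(sim$pairs, cfg$chrom_sizes, cfg$resolution, "compA")
    ref <- bin_reference_peaks(sim$truth$peaks, cfg$chrom_sizes, 1e5)
    list(cfg = cfg, sim = sim, mat = mat, ref = ref,
         track = compute_cscore(mat, ref))
  })
}

# brute-force upper-tail oracles, independent of pixel_pvalue
nb_tail_bruteforce <- function(x, size, mu, kmax = 20000) {
  if (x <= 0) return(1)
  sum(dnbinom(x:kmax, size = size, mu = mu))
}

pois_tail_bruteforce <- function(x, lambda, kmax = 20000) {
  if (x <= 0) return(1)
  sum(dpois(x:kmax, lambda = lambda))
}
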