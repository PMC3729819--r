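# Shared fixtures: small generator configs, a hand-rolled fragment builder,
# and naive oracles kept independent of the implementation under test.

tiny_sim <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(chrom_lengths = c(chr1 = 2e6, chrX = 1e6), n_hotspots = 15,
         gal4_fraction = 0.2, seed = seed),
    list(...))
  do.call(sim_config, args)
}

frag <- function(chrom = "chr1", start = 1000, end = 1300, strand = "+",
                 q1 = 40, q2 = 40, replicate_id = "r1") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             q1 = q1, q2 = q2, replicate_id = replicate_id,
             stringsAsFactors = FALSE)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# regex-lookahead oracle for the Gal4 consensus: 0-based match starts,
# overlapping occurrences included
oracle_gal4_starts <- function(s) {
  m <- gregexpr("(?=CGG[ACGT]{11}CCG)", toupper(s), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# quadratic all-pairs interval intersection oracle on 0-based half-open
# intervals; counts set-A elements hitting any B element
oracle_overlap_count <- function(a, b) {
  hits <- 0L
  for (i in seq_len(nrow(a))) {
    found <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) found <- TRUE
    }
    hits <- hits + found
  }
  hits
}

# truth hotspot centers as 1-bp intervals, for recovery bookkeeping
truth_points <- function(truth) {
  data.frame(chrom = truth$hotspots$chrom,
             start = truth$hotspots$center,
             end = truth$hotspots$center + 1L,
             stringsAsFactors = FALSE)
}
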