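# Synthetic SSDS generator: determinism, planted-signal recovery,
# bookkeeping conservation, and the fragment sampling model.

test_that("genome generation is deterministic and plants recoverable motifs", {
  cfg <- tiny_sim(chrom_lengths = c(chr1 = 5e5, chrX = 4e5), n_hotspots = 8,
                  gal4_fraction = 0.5)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$hotspots, g2$truth$hotspots)
  expect_identical(unname(Biostrings::width(g1$genome)),
                   unname(as.integer(cfg$chrom_lengths)))

  sites <- scan_consensus(g1$genome)
  planted <- g1$truth$motif_sites
  expect_gte(nrow(planted), 5)
  found <- merge(planted, sites, by = c("chrom", "start"))
  expect_equal(nrow(found), nrow(planted))

  # every planted hotspot center within its chromosome
  hs <- g1$truth$hotspots
  expect_true(all(hs$center >= 0 & hs$center < cfg$chrom_lengths[hs$chrom]))
  # flagged hotspots have a site whose midpoint equals the center
  mid <- (planted$start + planted$end) %/% 2
  ctr <- hs$center[match(planted$hotspot_id, hs$id)]
  expect_equal(mid, ctr)
})

test_that("central-window scrubbing removes accidental consensus matches", {
  cfg <- tiny_sim(chrom_lengths = c(chr1 = 1e6), n_hotspots = 20,
                  gal4_fraction = 0, scrub_hotspot_windows = TRUE,
                  scrub_halfwidth = 1000, par = list(n_hotspots = 0,
                                                     fraction = 0))
  g <- generate_genome(cfg)
  sites <- scan_consensus(g$genome)
  win <- central_window(truth_points(g$truth), 2000, cfg$chrom_lengths)
  ov <- overlap_fraction(win, sites, window_a = 0, window_b = 0)
  expect_identical(ov$n_overlapping, 0L)
})

test_that("fragment counts follow the planted truth", {
  cfg <- tiny_sim(chrom_lengths = c(chr1 = 2e6), n_hotspots = 1,
                  background_per_mb = 0, duplicate_rate = 0,
                  par = list(n_hotspots = 0, fraction = 0), gal4_fraction = 0)
  truth <- generate_truth(cfg)
  truth$hotspots$strength <- 1000

  # Poisson sampling: mean observed count over 10 seeds near the mean
  counts <- vapply(1:10, function(s)
    nrow(simulate_fragments(truth, condition_params(), seed = s)),
    numeric(1))
  expect_gte(mean(counts), 900)
  expect_lte(mean(counts), 1100)

  # zero signal multiplier leaves only background (here: none)
  none <- simulate_fragments(truth, condition_params(signal = 0), seed = 1)
  expect_identical(nrow(none), 0L)

  # with background, zero signal emits background only
  cfg2 <- tiny_sim(chrom_lengths = c(chr1 = 2e6), n_hotspots = 5,
                   background_per_mb = 100, duplicate_rate = 0,
                   par = list(n_hotspots = 0, fraction = 0))
  t2 <- generate_truth(cfg2)
  bg <- simulate_fragments(t2, condition_params(signal = 0), seed = 1)
  bk <- attr(bg, "bookkeeping")
  expect_identical(sum(bk$per_hotspot), 0L)
  expect_identical(nrow(bg), bk$n_background)
})

test_that("bookkeeping conserves fragment counts and duplicates behave", {
  cfg <- tiny_sim(duplicate_rate = 0.5)
  truth <- generate_truth(cfg)
  fr <- simulate_fragments(truth, condition_params(depth = 2), seed = 9)
  bk <- attr(fr, "bookkeeping")
  expect_identical(bk$n_distinct,
                   sum(bk$per_hotspot) + bk$n_background)
  expect_identical(nrow(fr), bk$n_total)
  expect_gte(bk$n_total, bk$n_distinct)

  # duplicate rate 0: all (chrom, start, end, strand) tuples unique
  cfg0 <- tiny_sim(duplicate_rate = 0)
  fr0 <- simulate_fragments(generate_truth(cfg0), condition_params(),
                            seed = 9)
  key <- paste(fr0$chrom, fr0$start, fr0$end, fr0$strand)
  expect_identical(anyDuplicated(key), 0L)

  # same seed, same condition: identical output
  fr0b <- simulate_fragments(generate_truth(cfg0), condition_params(),
                             seed = 9)
  expect_identical(fr0, fr0b)
})

test_that("condition multipliers act on the intended hotspot classes", {
  cfg <- tiny_sim(chrom_lengths = c(chr1 = 4e6, chrX = 3e6),
                  n_hotspots = 40, gal4_fraction = 0.25,
                  background_per_mb = 0, duplicate_rate = 0,
                  end_width = 1e6)
  truth <- generate_truth(cfg)
  hs <- truth$hotspots
  # no Gal4 targeting: flagged hotspots silent
  off <- simulate_fragments(truth, condition_params(gal4 = 0), seed = 2)
  flagged <- hs[hs$has_gal4, ]
  w <- central_window(truth_points(truth)[hs$has_gal4, ], 2000,
                      cfg$chrom_lengths)
  ovl <- overlap_fraction(w, off, window_a = 0, window_b = 0)
  expect_identical(ovl$n_overlapping, 0L)
  # with targeting on, flagged hotspots emit
  on <- simulate_fragments(truth, condition_params(gal4 = 1), seed = 2)
  bk <- attr(on, "bookkeeping")
  expect_gt(sum(bk$per_hotspot[flagged$id]), 0)
})

test_that("H3K4me3 tags cover all hotspots, deterministically", {
  cfg <- tiny_sim()
  truth <- generate_truth(cfg)
  k1 <- simulate_h3k4me3_tags(truth, seed = 5)
  k2 <- simulate_h3k4me3_tags(truth, seed = 5)
  expect_identical(k1, k2)
  expect_identical(nrow(k1$peaks), nrow(truth$hotspots))
  expect_true(all(k1$tags$chrom %in% names(cfg$chrom_lengths)))

  empty <- sim_config(chrom_lengths = c(chr1 = 1e6), n_hotspots = 0,
                      par = list(n_hotspots = 0, fraction = 0), seed = 1)
  k0 <- simulate_h3k4me3_tags(generate_truth(empty), seed = 5)
  expect_identical(nrow(k0$tags), 0L)
})

test_that("config validation rejects impossible geometries", {
  expect_error(sim_config(suppression_factor = 0), "suppression_factor")
  expect_error(sim_config(chrom_lengths = c(chr1 = 1e6),
                          par = list(width = 2e6)), "PAR")
  expect_error(generate_truth(sim_config(
    chrom_lengths = c(chr1 = 5e4), n_hotspots = 50)), "too short")
})
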