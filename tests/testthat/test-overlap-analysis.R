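# Central-window arithmetic, overlap fractions against a quadratic oracle,
# hotspot classification, strength correlation, motif-centered profiles.

test_that("central windows are centered, clipped, and center-aware", {
  iv <- data.frame(chrom = "chr1", start = 1000, end = 3000)
  w <- central_window(iv, 400)
  expect_identical(c(w$start, w$end), c(1800L, 2200L))

  # explicit center takes precedence over the midpoint
  ivc <- data.frame(chrom = "chr1", start = 1000, end = 3000, center = 1200)
  wc <- central_window(ivc, 400)
  expect_identical(c(wc$start, wc$end), c(1000L, 1400L))

  # window may exceed a narrow interval; clipping is to the chromosome
  narrow <- data.frame(chrom = "chr1", start = 100, end = 140)
  wn <- central_window(narrow, 400, c(chr1 = 100000))
  expect_identical(c(wn$start, wn$end), c(0L, 320L))

  same <- central_window(iv, 2000)
  expect_identical(c(same$start, same$end), c(1000L, 3000L))
})

test_that("overlap fraction counts each query once with >=1 bp contact", {
  hs <- data.frame(chrom = "chr1", start = 9000, end = 11000, center = 10000)
  motif <- data.frame(chrom = "chr1", start = 9900, end = 9917)
  ov <- overlap_fraction(hs, motif, window_a = 2000, window_b = 0)
  expect_identical(ov$n_overlapping, 1L)
  expect_equal(ov$percent, 100.0)

  other <- data.frame(chrom = "chr2", start = 9900, end = 9917)
  expect_identical(overlap_fraction(hs, other, 2000, 0)$n_overlapping, 0L)

  # self-overlap is complete, and the predicate is symmetric
  set.seed(41)
  a <- data.frame(chrom = "chr1", start = s <- sample(0:1e6, 50), end = s + 1500)
  expect_equal(overlap_fraction(a, a, 400, 400)$percent, 100.0)
  b <- data.frame(chrom = "chr1", start = s2 <- sample(0:1e6, 80), end = s2 + 1500)
  ab <- overlap_fraction(a, b, 400, 400)$n_overlapping > 0
  ba <- overlap_fraction(b, a, 400, 400)$n_overlapping > 0
  expect_identical(ab, ba)
})

test_that("overlap counts match the all-pairs oracle on random sets", {
  set.seed(47)
  for (i in 1:5) {
    na <- sample(50:300, 1); nb <- sample(50:300, 1)
    a <- data.frame(chrom = sample(c("chr1", "chr2"), na, TRUE),
                    start = sa <- sample(0:5e5, na, TRUE),
                    end = sa + sample(100:3000, na, TRUE))
    b <- data.frame(chrom = sample(c("chr1", "chr2"), nb, TRUE),
                    start = sb <- sample(0:5e5, nb, TRUE),
                    end = sb + sample(10:2000, nb, TRUE))
    expect_identical(overlap_fraction(a, b, 0, 0)$n_overlapping,
                     oracle_overlap_count(a, b))
  }
})

test_that("classification flags partition consistently", {
  set.seed(53)
  n <- 200
  q <- data.frame(chrom = "chr1", start = s <- seq(1e4, 2e6, length.out = n),
                  end = s + 2000, center = as.integer(s + 1000),
                  strength = ceiling(runif(n) * 100))
  ref <- q[1:120, ]
  motifs <- data.frame(chrom = "chr1", start = m <- q$center[seq(1, n, 3)] - 8,
                       end = m + 17)
  cls <- classify_hotspots(q, ref, motifs = motifs)
  s <- attr(cls, "summary")
  expect_identical(s$n_shared_motif + s$n_specific_motif, s$n_motif)
  expect_identical(s$n_shared, 120L)
  expect_identical(sum(cls$has_motif), length(seq(1, n, 3)))

  # empty reference: everything is specific
  cls0 <- classify_hotspots(q, ref[0, ], motifs = motifs)
  expect_identical(attr(cls0, "summary")$n_shared, 0L)
  expect_identical(attr(cls0, "summary")$n_specific_motif,
                   attr(cls0, "summary")$n_motif)
})

test_that("condition-specific planted motif hotspots classify as specific", {
  cfg <- tiny_sim(chrom_lengths = c(chr1 = 3e6), n_hotspots = 40,
                  gal4_fraction = 0.25, scrub_hotspot_windows = TRUE,
                  par = list(n_hotspots = 0, fraction = 0))
  g <- generate_genome(cfg)
  hs <- g$truth$hotspots
  sites <- scan_consensus(g$genome)
  mk <- function(rows) data.frame(chrom = rows$chrom,
                                  start = rows$center - 1000,
                                  end = rows$center + 1000,
                                  center = rows$center)
  query <- mk(hs)                      # the Gal4-condition hotspot set
  reference <- mk(hs[!hs$has_gal4, ])  # wild-type-like: no flagged hotspots
  cls <- classify_hotspots(query, reference, motifs = sites,
                           chrom_lengths = cfg$chrom_lengths)
  s <- attr(cls, "summary")
  expect_identical(s$n_specific_motif, sum(hs$has_gal4))
  expect_identical(s$n_specific_motif + 0L, nrow(g$truth$motif_sites))
})

test_that("strength correlation is 1 on self, small under permutation", {
  set.seed(59)
  n <- 1000
  hs <- data.frame(chrom = "chr1", start = s <- seq(1e4, 5e7, length.out = n),
                   end = s + 2000, center = as.integer(s + 1000),
                   strength = 10 * runif(n)^-0.5)
  self <- strength_correlation(hs, hs)
  expect_equal(self$rho, 1)
  expect_identical(self$n_pairs, as.integer(n))

  for (seed in 1:5) {
    set.seed(seed)
    perm <- hs
    perm$strength <- sample(perm$strength)
    expect_lt(abs(strength_correlation(hs, perm)$rho), 0.2)
  }
  expect_error(strength_correlation(hs[1:2, ], hs[5:6, ]), "fewer than 3")
})

test_that("replicate simulations at equal depth correlate strongly", {
  # strengths spanning orders of magnitude, as real hotspot strengths do
  cfg <- tiny_sim(chrom_lengths = c(chr1 = 6e6), n_hotspots = 80,
                  strength_shape = 1.3, strength_scale = 30,
                  gal4_fraction = 0,
                  par = list(n_hotspots = 0, fraction = 0))
  truth <- generate_truth(cfg)
  call_one <- function(seed) {
    fr <- process_fragments(list(simulate_fragments(
      truth, condition_params(depth = 3), seed = seed)))
    call_hotspots(fr, cfg$chrom_lengths)
  }
  a <- call_one(101); b <- call_one(202)
  expect_gte(strength_correlation(a, b, chrom_lengths = cfg$chrom_lengths)$rho,
             0.9)
})

test_that("motif-centered profiles reflect site placement", {
  hs <- data.frame(chrom = "chr1", start = s <- seq(1e4, 1e6, 1e4),
                   end = s + 2000, center = as.integer(s + 1000))
  # all sites exactly at hotspot centers: maximal central coverage
  at_center <- data.frame(chrom = "chr1", start = hs$center - 8,
                          end = hs$center + 9)
  prof <- motif_center_profile(hs, at_center, halfwidth = 2500, bin = 50)
  central <- prof$bases[prof$offset_start %in% c(-50, 0)]
  expect_gte(sum(central), nrow(hs) * 17 - 1e-9)
  expect_equal(sum(prof$bases), nrow(hs) * 17)

  # no sites: all-zero profile
  empty <- motif_center_profile(hs, at_center[0, ])
  expect_true(all(empty$bases == 0))
  expect_error(motif_center_profile(hs[0, ], at_center), "empty")

  # uniformly placed sites: flat within Monte Carlo tolerance
  set.seed(61)
  devs <- vapply(1:5, function(i) {
    off <- sample(seq(-2500, 2483), 4000, replace = TRUE)
    h_idx <- sample(nrow(hs), 4000, replace = TRUE)
    sites <- data.frame(chrom = "chr1", start = p <- hs$center[h_idx] + off,
                        end = p + 17)
    pr <- motif_center_profile(hs, sites, halfwidth = 2500, bin = 250)
    max(abs(pr$bases - mean(pr$bases))) / mean(pr$bases)
  }, numeric(1))
  expect_lt(median(devs), 0.25)
})
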