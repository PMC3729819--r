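# Binned in-hotspot landscapes, normalization, masking, the subtelomeric
# depletion statistic, and the PAR fragment fraction.

test_that("profile normalization sums to 100 over unmasked bins", {
  cl <- c(chr1 = 10e6, chr2 = 8e6)
  regions <- data.frame(chrom = rep(c("chr1", "chr2"), each = 20),
                        start = s <- rep(seq(1e5, 9e6, length.out = 20), 2),
                        end = s + 2000)
  set.seed(71)
  n <- 5000
  ridx <- sample(nrow(regions), n, replace = TRUE)
  x <- data.frame(chrom = regions$chrom[ridx],
                  start = p <- regions$start[ridx] + sample(0:1500, n, TRUE),
                  end = p + 300, strand = "+", q1 = 40, q2 = 40,
                  replicate_id = "r")
  prof <- in_hotspot_window_profile(x, regions, cl, bin = 1e6, end_mask = 3e6)
  expect_equal(sum(prof$percent[!prof$masked]), 100, tolerance = 1e-9)
  expect_true(all(is.na(prof$percent[prof$masked])))
  expect_true(all(prof$masked == (prof$bin_start < 3e6)))
  expect_identical(nrow(prof), 18L)
})

test_that("signal outside reference regions is excluded entirely", {
  cl <- c(chr1 = 10e6)
  regions <- data.frame(chrom = "chr1", start = 5e6, end = 5.01e6)
  inside <- frag(start = 5.002e6, end = 5.0023e6)
  outside <- frag(start = 8e6, end = 8.0003e6)
  prof <- in_hotspot_window_profile(rbind(inside, outside), regions, cl,
                                    bin = 1e6, end_mask = 0)
  expect_equal(prof$percent[prof$bin_start == 5e6], 100)
  expect_equal(sum(prof$count), 1L)
  expect_error(in_hotspot_window_profile(outside, regions, cl),
               "no in-region signal")
})

test_that("identical profiles give a depletion ratio of exactly 1", {
  cl <- c(chr1 = 20e6)
  regions <- data.frame(chrom = "chr1",
                        start = s <- seq(1e5, 19.8e6, length.out = 60),
                        end = s + 2000)
  set.seed(73)
  ridx <- sample(60, 3000, replace = TRUE)
  x <- data.frame(chrom = "chr1",
                  start = p <- regions$start[ridx] + sample(0:1500, 3000, TRUE),
                  end = p + 300, strand = "+", q1 = 40, q2 = 40,
                  replicate_id = "r")
  prof <- in_hotspot_window_profile(x, regions, cl)
  d <- subtelomere_depletion_stat(prof, prof, end_width = 5e6)
  expect_equal(d$ratio, 1)
  expect_identical(d$n_end + d$n_interior,
                   sum(!prof$masked & prof$percent > 0))
  expect_error(subtelomere_depletion_stat(prof, prof, end_width = 100e6),
               "interior")
})

test_that("planted end suppression is detected; H3K4me3 stays flat", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 40e6, chr2 = 30e6),
                    n_hotspots = 200, gal4_fraction = 0,
                    par = list(n_hotspots = 0, fraction = 0),
                    end_width = 5e6, seed = 4)
  truth <- generate_truth(cfg)
  regions <- data.frame(chrom = truth$hotspots$chrom,
                        start = truth$hotspots$center - 1000,
                        end = truth$hotspots$center + 1000)
  ref <- simulate_fragments(truth, condition_params(depth = 2), seed = 301)
  mut <- simulate_fragments(truth, condition_params(depth = 2,
                                                    end_factor = 0.2),
                            seed = 401)
  k4 <- simulate_h3k4me3_tags(truth, seed = 501, tag_depth = 2)
  pr <- in_hotspot_window_profile(ref, regions, cfg$chrom_lengths)
  pm <- in_hotspot_window_profile(mut, regions, cfg$chrom_lengths)
  pk <- in_hotspot_window_profile(k4$tags, regions, cfg$chrom_lengths)
  dm <- subtelomere_depletion_stat(pm, pr, seed = 1)
  dk <- subtelomere_depletion_stat(pk, pr, seed = 1)
  expect_lte(dm$ratio, 0.5)
  expect_lt(dm$p_value, 0.01)
  expect_lt(abs(dk$ratio - 1), 0.1)
})

test_that("PAR fragment fraction counts midpoints in the cluster interval", {
  par <- list(chrom = "chrX", start = 960000, end = 1000000)
  inpar <- frag(chrom = "chrX", start = 970000, end = 970300)
  out <- frag(chrom = "chr1", start = 970000, end = 970300)
  expect_equal(par_cluster_fraction(inpar, par)$percent, 100)
  expect_equal(par_cluster_fraction(rbind(inpar, out, out, out), par)$percent,
               25)
  expect_error(par_cluster_fraction(inpar[0, ], par), "empty")
  # midpoint rule: fragment straddling the boundary counts by midpoint
  straddle <- frag(chrom = "chrX", start = 959900, end = 960150)  # mid 960025
  expect_equal(par_cluster_fraction(straddle, par)$n_par, 1L)
})

test_that("fold change between PAR fractions is a simple ratio", {
  expect_equal(par_fold_change(0.33, 0.01), 33)
  expect_gt(par_fold_change(0.33, 0.01), 30)
  expect_error(par_fold_change(0.33, 0), "positive")
})
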