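# Shared configuration for the analysis workflow. Sourced by the numbered
# driver scripts; everything derives from one sim_config and one master
# seed, so the whole workflow is reproducible end to end.

library(dsbscape)

SEED <- 20260925L
OUT <- "results"
DATA <- file.path(OUT, "data")
dir.create(DATA, recursive = TRUE, showWarnings = FALSE)

# one miniature genome: two autosome-like chromosomes plus a sex-like
# chromosome carrying the PAR cluster at its non-centromeric end
SIM <- sim_config(
  chrom_lengths = c(chr1 = 12e6, chr2 = 10e6, chrX = 8e6),
  n_hotspots = 120, gal4_fraction = 0.1,
  end_width = 2e6, suppression_factor = 0.2,
  seed = SEED)

# four conditions mirroring a wild-type reference, a low-depth arrest
# background, and two Gal4-targeting samples with subtelomeric suppression
# and a 33-fold PAR deficiency
CONDITIONS <- list(
  wild_type = condition_params(depth = 1, gal4 = 0),
  arrest = condition_params(depth = 0.25, gal4 = 0),
  gal4 = condition_params(depth = 0.6, gal4 = 1, end_factor = 0.2,
                          par_factor = 1 / 33),
  gal4_arrest = condition_params(depth = 1, gal4 = 1, end_factor = 0.2,
                                 par_factor = 1 / 33))

N_REPLICATES <- 2
LANDSCAPE_BIN <- 5e5
LANDSCAPE_END_MASK <- 1e6   # centromeric-end mask
LANDSCAPE_END_WIDTH <- 2e6  # subtelomeric zone, matches SIM$end_width
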