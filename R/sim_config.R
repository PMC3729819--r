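#' Simulation configuration
#'
#' Parameters of the synthetic SSDS data generator. The generator emulates
#' the statistical structure of a DMC1-ChIP ssDNA fragment experiment:
#' discrete hotspots with heavy-tailed strengths, fragments scattered around
#' hotspot centers, a uniform background, PCR duplicates with paired per-end
#' quality scores, a ~40 kb pseudoautosomal-region (PAR)-like cluster of
#' overlapping hotspots at one chromosome end, a minority of hotspots
#' centered on planted Gal4 consensus sites, and an optional multiplicative
#' suppression of hotspot strength near non-centromeric chromosome ends.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_hotspots hotspots planted per chromosome (outside the PAR).
#' @param strength_shape,strength_scale Pareto parameters of the hotspot
#'   strength law (expected fragment count per hotspot at depth 1); the
#'   Pareto gives the heavy right tail seen in hotspot strength
#'   distributions. Mean is `scale * shape / (shape - 1)` for shape > 1.
#' @param offset_sd standard deviation (bp) of the Gaussian fragment-center
#'   offset around the hotspot center, truncated at +/- 3 sd, so a hotspot's
#'   fragment footprint spans roughly 1-2 kb.
#' @param fragment_length_mean,fragment_length_sd fragment length law (bp).
#' @param background_per_mb expected background fragments per Mb at depth 1.
#' @param duplicate_rate expected number of extra exact copies per distinct
#'   fragment; per-fragment multiplicity is 1 + Geometric with this mean.
#' @param low_quality_frac probability that a read end draws its quality
#'   from the low tail (below 30), so the quality filter removes a
#'   configurable fraction of records.
#' @param gal4_fraction fraction of planted hotspots centered on a planted
#'   exact CGG-N11-CCG site; these hotspots are condition-specific (active
#'   only when the condition enables Gal4 targeting).
#' @param par list describing the PAR-like cluster: `chrom` (default: last
#'   chromosome), `width` (bp, default 40000, placed at the high-coordinate
#'   end), `n_hotspots` (default 20, evenly spaced so individual hotspots
#'   cannot be resolved), and either `fraction` (expected share of all
#'   fragments arising from the cluster, default 0.0033) or an explicit
#'   `total_strength`.
#' @param end_width width (bp) of the subtelomeric zone at the
#'   high-coordinate (non-centromeric) end of each chromosome within which
#'   hotspot strength is multiplied by the condition's suppression factor.
#' @param suppression_factor multiplicative factor in (0, 1] applied to
#'   subtelomeric hotspots in suppressed conditions.
#' @param min_separation minimum spacing (bp) between planted hotspot
#'   centers, enforced by quasi-uniform slot placement.
#' @param scrub_hotspot_windows if TRUE, accidental (non-planted) motif
#'   matches within `scrub_halfwidth` of any planted hotspot center are
#'   removed from the generated sequence, so central windows contain only
#'   planted sites.
#' @param scrub_halfwidth half-width (bp) of the scrubbed window.
#' @param seed integer random seed; all generator outputs are deterministic
#'   given the config (the seed is part of it).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 12e6, chr2 = 10e6, chrX = 8e6),
                       n_hotspots = 120,
                       strength_shape = 2,
                       strength_scale = 10,
                       offset_sd = 500,
                       fragment_length_mean = 300,
                       fragment_length_sd = 50,
                       background_per_mb = 50,
                       duplicate_rate = 0.2,
                       low_quality_frac = 0.1,
                       gal4_fraction = 0.1,
                       par = list(),
                       end_width = 5e6,
                       suppression_factor = 0.2,
                       min_separation = 5000,
                       scrub_hotspot_windows = FALSE,
                       scrub_halfwidth = 1000,
                       seed = 1) {
  chrom_lengths <- validate_chrom_lengths(chrom_lengths)
  stopifnot(n_hotspots >= 0, strength_shape > 0, strength_scale > 0,
            offset_sd > 0, fragment_length_mean > 0,
            background_per_mb >= 0, duplicate_rate >= 0,
            low_quality_frac >= 0, low_quality_frac <= 1,
            gal4_fraction >= 0, gal4_fraction <= 1,
            end_width >= 0, min_separation >= 0, scrub_halfwidth >= 0)
  if (suppression_factor <= 0 || suppression_factor > 1)
    stop("suppression_factor must be in (0, 1]")

  par_defaults <- list(chrom = names(chrom_lengths)[length(chrom_lengths)],
                       width = 40000, n_hotspots = 20,
                       fraction = 0.0033, total_strength = NULL)
  par <- utils::modifyList(par_defaults, par)
  check_chroms(par$chrom, chrom_lengths)
  par_len <- chrom_lengths[[par$chrom]]
  if (par$width <= 0 || par$width > par_len)
    stop("PAR interval does not fit inside its chromosome")
  par$start <- par_len - par$width
  par$end <- par_len
  if (!is.null(par$fraction) && (par$fraction < 0 || par$fraction >= 1))
    stop("par$fraction must be in [0, 1)")

  structure(list(chrom_lengths = chrom_lengths, n_hotspots = n_hotspots,
                 strength_shape = strength_shape,
                 strength_scale = strength_scale, offset_sd = offset_sd,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 background_per_mb = background_per_mb,
                 duplicate_rate = duplicate_rate,
                 low_quality_frac = low_quality_frac,
                 gal4_fraction = gal4_fraction, par = par,
                 end_width = end_width,
                 suppression_factor = suppression_factor,
                 min_separation = min_separation,
                 scrub_hotspot_windows = scrub_hotspot_windows,
                 scrub_halfwidth = scrub_halfwidth,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Condition parameters for fragment simulation
#'
#' A "condition" is one genotype/sample in a simulated experiment. It scales
#' the planted truth multiplicatively, emulating sequencing depth, loss of
#' Gal4-directed targeting, subtelomeric suppression and PAR deficiency.
#'
#' @param depth sequencing-depth multiplier applied to all expected counts
#'   (hotspots and background).
#' @param signal multiplier applied to hotspot means only (0 silences all
#'   hotspots, leaving pure background).
#' @param gal4 multiplier for Gal4-flagged hotspots (0 = the condition lacks
#'   Gal4 targeting, so flagged hotspots are absent; 1 = fully active).
#' @param end_factor multiplicative suppression applied to non-PAR hotspots
#'   whose center lies within `end_width` of the non-centromeric
#'   (high-coordinate) chromosome end; 1 disables suppression.
#' @param par_factor multiplier for PAR-cluster hotspot strength (e.g. 1/33
#'   emulates a 33-fold PAR deficiency).
#' @return list of class `condition_params`.
#' @export
condition_params <- function(depth = 1, signal = 1, gal4 = 0,
                             end_factor = 1, par_factor = 1) {
  stopifnot(depth >= 0, signal >= 0, gal4 >= 0,
            end_factor > 0, end_factor <= 1, par_factor >= 0)
  structure(list(depth = depth, signal = signal, gal4 = gal4,
                 end_factor = end_factor, par_factor = par_factor),
            class = "condition_params")
}
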