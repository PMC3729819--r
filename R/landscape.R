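## Chromosomal landscape: 1-Mb normalized in-hotspot coverage profiles,
## the subtelomeric depletion ratio with a rotation permutation test, and
## the PAR-cluster fragment fraction.

#' Binned in-hotspot coverage profile, percent of total
#'
#' Signal fragments (or tags) whose midpoint falls inside any reference
#' region are assigned to the fixed-width bin containing the midpoint. Bin
#' values are expressed as percent of the genome-wide total of in-region
#' signal in unmasked bins, so the unmasked values sum to 100. Bins whose
#' start lies within `end_mask` of the chromosome start (the centromeric
#' end, where assembly sequence is typically unavailable) are masked and
#' carry no value.
#'
#' @param signal data.frame with chrom, start, end (fragments or tags).
#' @param regions reference hotspot intervals (chrom, start, end).
#' @param chrom_lengths named chromosome-length vector.
#' @param bin bin width (bp, default 1 Mb).
#' @param end_mask centromeric mask width (bp, default 3 Mb; 0 disables).
#' @return data.frame of class `bin_profile` (chrom, bin_start, bin_end,
#'   count, percent, masked) with `chrom_lengths` attached.
#' @export
in_hotspot_window_profile <- function(signal, regions, chrom_lengths = NULL,
                                      bin = 1e6, end_mask = 3e6) {
  cl <- chrom_lengths_of(signal, chrom_lengths)
  check_chroms(signal$chrom, cl)
  check_chroms(regions$chrom, cl)
  stopifnot(bin > 0, end_mask >= 0)

  mids <- interval_midpoints(signal)
  lv <- names(cl)
  pts <- GenomicRanges::GRanges(factor(signal$chrom, levels = lv),
                                IRanges::IRanges(mids + 1L, width = 1L))
  inside <- GenomicRanges::countOverlaps(pts,
                                         intervals_to_gr(regions, lv)) > 0

  rows <- lapply(names(cl), function(chrom) {
    nb <- as.integer(ceiling(cl[[chrom]] / bin))
    bin_start <- (seq_len(nb) - 1) * bin
    m <- mids[inside & signal$chrom == chrom]
    count <- tabulate(pmin(m %/% bin, nb - 1L) + 1L, nbins = nb)
    data.frame(chrom = chrom, bin_start = bin_start,
               bin_end = pmin(bin_start + bin, cl[[chrom]]),
               count = count, masked = bin_start < end_mask,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  total <- sum(prof$count[!prof$masked])
  if (total == 0)
    stop("no in-region signal outside masked bins; profile undefined")
  prof$percent <- ifelse(prof$masked, NA_real_, 100 * prof$count / total)
  rownames(prof) <- NULL
  attr(prof, "chrom_lengths") <- cl
  class(prof) <- c("bin_profile", "data.frame")
  prof
}

#' Subtelomeric depletion ratio with a rotation permutation test
#'
#' Per unmasked bin with positive reference value, the query/reference
#' percent ratio is computed. The statistic is
#' `R = mean(ratio in end bins) / mean(ratio in interior bins)`, where end
#' bins lie within `end_width` of the non-centromeric (high-coordinate)
#' chromosome end. R < 1 indicates depletion of the query signal near
#' chromosome ends relative to the reference. Significance comes from
#' circular rotations of the per-bin ratios within each chromosome
#' (one-sided: P(R_perm <= R_observed)).
#'
#' @param profile_query,profile_reference `bin_profile`s on identical
#'   binning.
#' @param end_width subtelomeric zone width (bp, default 5 Mb).
#' @param n_perm number of rotations (default 1000).
#' @param seed integer seed for the rotations.
#' @return list with `ratio` (R), `p_value`, `n_end`, `n_interior`.
#' @export
subtelomere_depletion_stat <- function(profile_query, profile_reference,
                                       end_width = 5e6, n_perm = 1000,
                                       seed = 1) {
  if (!identical(profile_query[c("chrom", "bin_start")],
                 profile_reference[c("chrom", "bin_start")]))
    stop("profiles are not on identical binning")
  cl <- chrom_lengths_of(profile_query)
  set.seed(as.integer(seed))

  ok <- !profile_query$masked & !is.na(profile_reference$percent) &
    profile_reference$percent > 0
  q <- profile_query[ok, ]
  r <- profile_reference[ok, ]
  ratio <- q$percent / r$percent
  is_end <- (cl[q$chrom] - q$bin_start) <= end_width
  if (!any(is_end)) stop("no subtelomeric bins after masking")
  if (all(is_end)) stop("no interior bins; end_width too large")

  stat <- function(rt) mean(rt[is_end]) / mean(rt[!is_end])
  r_obs <- stat(ratio)

  chroms <- q$chrom
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    rt <- ratio
    for (chrom in unique(chroms)) {
      sel <- which(chroms == chrom)
      k <- sample.int(length(sel), 1)
      rt[sel] <- rt[sel][c(seq(k, length(sel)), seq_len(k - 1))]
    }
    perm[b] <- stat(rt)
  }
  list(ratio = r_obs,
       p_value = (1 + sum(perm <= r_obs)) / (n_perm + 1),
       n_end = sum(is_end), n_interior = sum(!is_end))
}

#' PAR-cluster fragment fraction
#'
#' Percent of all fragments whose midpoint lies inside the PAR hotspot
#' cluster interval.
#'
#' @param fragments fragment data.frame.
#' @param par list with chrom, start, end (0-based half-open), e.g.
#'   `truth$par`.
#' @return list with `n_par`, `n_total`, `percent` (two decimals, half-up)
#'   and `percent_raw`.
#' @export
par_cluster_fraction <- function(fragments, par) {
  if (nrow(fragments) == 0) stop("empty fragment set")
  stopifnot(!is.null(par$chrom), !is.null(par$start), !is.null(par$end))
  mids <- interval_midpoints(fragments)
  n_par <- sum(fragments$chrom == par$chrom &
                 mids >= par$start & mids < par$end)
  pct <- 100 * n_par / nrow(fragments)
  list(n_par = n_par, n_total = nrow(fragments),
       percent = round_half_up(pct, 2), percent_raw = pct)
}

#' Fold change between two PAR fractions
#'
#' @param percent_a,percent_b PAR percentages (same units).
#' @return `percent_a / percent_b`.
#' @export
par_fold_change <- function(percent_a, percent_b) {
  if (percent_b <= 0) stop("reference percentage must be positive")
  percent_a / percent_b
}
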