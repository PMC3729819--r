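## Central-window overlap classification: hotspot-hotspot sharing (400 nt),
## hotspot-H3K4me3 (1 kb), hotspot-motif (2 kb), TSS, strength
## correlations of shared hotspots, and motif-centered coverage profiles.

#' Central-window widths for overlap calls
#'
#' @param hotspot_window hotspot-hotspot central window (nt, default 400).
#' @param h3k4me3_window hotspot-H3K4me3 central window (nt, default 1000).
#' @param motif_window hotspot-motif central window (nt, default 2000).
#' @param tss_window window applied to TSS points (nt, default 2000, i.e.
#'   +/- 1 kb around the TSS).
#' @return list of class `overlap_params`.
#' @export
overlap_params <- function(hotspot_window = 400, h3k4me3_window = 1000,
                           motif_window = 2000, tss_window = 2000) {
  w <- c(hotspot_window, h3k4me3_window, motif_window, tss_window)
  if (any(w <= 0) || any(w %% 2 != 0))
    stop("central windows must be positive even integers")
  structure(list(hotspot_window = hotspot_window,
                 h3k4me3_window = h3k4me3_window,
                 motif_window = motif_window, tss_window = tss_window),
            class = "overlap_params")
}

#' Central window of intervals
#'
#' Returns `[center - width/2, center + width/2)` for each interval, clipped
#' to chromosome bounds when lengths are supplied. An explicit `center`
#' column takes precedence; otherwise the center is
#' `floor((start + end) / 2)`. The window may exceed a narrow interval.
#'
#' @param intervals data.frame with chrom, start, end and optional center.
#' @param width window width (bp, positive even integer).
#' @param chrom_lengths optional named vector for clipping.
#' @return data.frame with the same rows, windowed start/end.
#' @export
central_window <- function(intervals, width, chrom_lengths = NULL) {
  stopifnot(width > 0)
  centers <- if (!is.null(intervals$center)) intervals$center
             else (intervals$start + intervals$end) %/% 2
  start <- centers - width %/% 2
  end <- centers + width %/% 2
  if (!is.null(chrom_lengths)) {
    check_chroms(intervals$chrom, chrom_lengths)
    start <- pmax(0, start)
    end <- pmin(as.numeric(chrom_lengths[intervals$chrom]), end)
  } else {
    start <- pmax(0, start)
  }
  out <- intervals
  out$start <- as.integer(start)
  out$end <- as.integer(pmax(end, start + 1))
  out
}

window_or_raw <- function(x, width, chrom_lengths) {
  if (width > 0) central_window(x, width, chrom_lengths) else x
}

#' Fraction of set-A elements whose central window overlaps set B
#'
#' An A element counts as overlapping if its central window (width
#' `window_a`) shares at least 1 bp with the central window of any B element
#' (width `window_b`; 0 means the raw B intervals, as for 17-bp motif
#' sites). Each A element is counted once regardless of how many B elements
#' it hits.
#'
#' @param set_a,set_b interval data.frames (chrom, start, end, optional
#'   center).
#' @param window_a,window_b central-window widths (bp; 0 = raw intervals).
#' @param chrom_lengths optional named vector; both sets must live on it.
#' @return list with `n_overlapping`, `n_total`, and `percent` (one decimal,
#'   half-up).
#' @export
overlap_fraction <- function(set_a, set_b, window_a, window_b = 0,
                             chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    check_chroms(set_a$chrom, chrom_lengths)
    check_chroms(set_b$chrom, chrom_lengths)
  }
  hit <- overlap_flags(set_a, set_b, window_a, window_b, chrom_lengths)
  n <- sum(hit)
  list(n_overlapping = n, n_total = nrow(set_a),
       percent = if (nrow(set_a) > 0)
         round_half_up(100 * n / nrow(set_a), 1) else NA_real_)
}

#' @keywords internal
overlap_flags <- function(set_a, set_b, window_a, window_b,
                          chrom_lengths = NULL) {
  if (nrow(set_a) == 0) return(logical(0))
  if (is.null(set_b) || nrow(set_b) == 0) return(rep(FALSE, nrow(set_a)))
  wa <- window_or_raw(set_a, window_a, chrom_lengths)
  wb <- window_or_raw(set_b, window_b, chrom_lengths)
  lv <- unique(c(as.character(wa$chrom), as.character(wb$chrom)))
  GenomicRanges::countOverlaps(intervals_to_gr(wa, lv),
                               intervals_to_gr(wb, lv)) > 0
}

#' Classify hotspots by central-window overlaps
#'
#' Flags each query hotspot as shared with a reference hotspot set (central
#' 400 nt on both sides), carrying a motif site in its central 2 kb (raw
#' motif intervals), overlapping an H3K4me3 peak (central 1 kb vs raw
#' peaks), and overlapping a TSS (central 1 kb vs TSS +/- 1 kb). Any of the
#' annotation sets may be NULL.
#'
#' @param query hotspot data.frame.
#' @param reference reference hotspot data.frame or NULL.
#' @param motifs motif-site intervals or NULL.
#' @param h3k4me3 peak intervals or NULL.
#' @param tss TSS intervals/points or NULL.
#' @param params an [overlap_params()].
#' @param chrom_lengths optional named vector.
#' @return `query` with added logical columns shared, has_motif,
#'   overlaps_h3k4me3, overlaps_tss, and a `summary` attribute with category
#'   counts (shared_motif + specific_motif = total motif-bearing).
#' @export
classify_hotspots <- function(query, reference = NULL, motifs = NULL,
                              h3k4me3 = NULL, tss = NULL,
                              params = overlap_params(),
                              chrom_lengths = NULL) {
  cl <- chrom_lengths %||% attr(query, "chrom_lengths")
  out <- query
  out$shared <- overlap_flags(query, reference, params$hotspot_window,
                              params$hotspot_window, cl)
  out$has_motif <- overlap_flags(query, motifs, params$motif_window, 0, cl)
  out$overlaps_h3k4me3 <- overlap_flags(query, h3k4me3,
                                        params$h3k4me3_window, 0, cl)
  out$overlaps_tss <- overlap_flags(query, tss, params$h3k4me3_window,
                                    params$tss_window, cl)
  n <- nrow(out)
  attr(out, "summary") <- list(
    n_total = n,
    n_shared = sum(out$shared),
    n_motif = sum(out$has_motif),
    n_shared_motif = sum(out$shared & out$has_motif),
    n_specific_motif = sum(!out$shared & out$has_motif),
    n_specific_h3k4me3 = sum(!out$shared & out$overlaps_h3k4me3),
    n_specific_tss = sum(!out$shared & out$overlaps_tss),
    pct_shared = if (n > 0) round_half_up(100 * sum(out$shared) / n, 1)
                 else NA_real_,
    pct_motif = if (n > 0) round_half_up(100 * sum(out$has_motif) / n, 1)
                else NA_real_)
  attr(out, "chrom_lengths") <- cl
  out
}

#' Spearman correlation of log strength over shared hotspots
#'
#' Query and reference hotspots are paired by central-400-nt overlap; when a
#' query window hits several reference hotspots the one with the nearest
#' center wins. The correlation is Spearman's rho on log10 strength of the
#' pairs.
#'
#' @param query,reference hotspot data.frames with `strength`.
#' @param params an [overlap_params()].
#' @param chrom_lengths optional named vector.
#' @return list with `rho`, `n_pairs`, and the pair table.
#' @export
strength_correlation <- function(query, reference,
                                 params = overlap_params(),
                                 chrom_lengths = NULL) {
  cl <- chrom_lengths %||% attr(query, "chrom_lengths")
  wq <- central_window(query, params$hotspot_window, cl)
  wr <- central_window(reference, params$hotspot_window, cl)
  lv <- unique(c(as.character(wq$chrom), as.character(wr$chrom)))
  ov <- GenomicRanges::findOverlaps(intervals_to_gr(wq, lv),
                                    intervals_to_gr(wr, lv))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  if (length(qh) > 0) {
    qc <- if (!is.null(query$center)) query$center
          else (query$start + query$end) %/% 2
    rc <- if (!is.null(reference$center)) reference$center
          else (reference$start + reference$end) %/% 2
    d <- abs(qc[qh] - rc[sh])
    ord <- order(qh, d)
    qh <- qh[ord]; sh <- sh[ord]
    keep <- !duplicated(qh)
    qh <- qh[keep]; sh <- sh[keep]
  }
  if (length(qh) < 3)
    stop("fewer than 3 shared hotspots; correlation undefined")
  pairs <- data.frame(query_idx = qh, ref_idx = sh,
                      query_strength = query$strength[qh],
                      ref_strength = reference$strength[sh])
  rho <- stats::cor(log10(pairs$query_strength),
                    log10(pairs$ref_strength), method = "spearman")
  list(rho = rho, n_pairs = nrow(pairs), pairs = pairs)
}

#' Motif-site coverage profile around hotspot centers
#'
#' For offsets in `[-halfwidth, +halfwidth)` binned at `bin` bp, counts the
#' number of motif-site bases covering each offset bin, summed over
#' hotspots, plus the per-hotspot mean.
#'
#' @param hotspots hotspot data.frame (uses `center`, else the interval
#'   midpoint).
#' @param sites motif-site intervals.
#' @param halfwidth profile half-width (bp).
#' @param bin offset bin width (bp).
#' @param chrom_lengths optional named vector.
#' @return data.frame (offset_start, offset_mid, bases, per_hotspot).
#' @export
motif_center_profile <- function(hotspots, sites, halfwidth = 2500,
                                 bin = 50, chrom_lengths = NULL) {
  if (nrow(hotspots) == 0) stop("empty hotspot set")
  stopifnot(halfwidth > 0, bin > 0, (2 * halfwidth) %% bin == 0)
  nb <- as.integer(2 * halfwidth / bin)
  bases <- numeric(nb)
  centers <- if (!is.null(hotspots$center)) hotspots$center
             else (hotspots$start + hotspots$end) %/% 2
  win <- data.frame(chrom = hotspots$chrom, start = centers - halfwidth,
                    end = centers + halfwidth)
  win$start <- pmax(0, win$start)
  if (nrow(sites) > 0) {
    lv <- unique(c(as.character(win$chrom), as.character(sites$chrom)))
    ov <- GenomicRanges::findOverlaps(intervals_to_gr(win, lv),
                                      intervals_to_gr(sites, lv))
    for (p in seq_along(ov)) {
      h <- S4Vectors::queryHits(ov)[p]
      s <- S4Vectors::subjectHits(ov)[p]
      a <- max(sites$start[s], centers[h] - halfwidth) -
        (centers[h] - halfwidth)
      b <- min(sites$end[s], centers[h] + halfwidth) -
        (centers[h] - halfwidth)
      if (b <= a) next
      for (j in (a %/% bin):((b - 1) %/% bin)) {
        bases[j + 1] <- bases[j + 1] +
          min(b, (j + 1) * bin) - max(a, j * bin)
      }
    }
  }
  data.frame(offset_start = seq_len(nb) * bin - bin - halfwidth,
             offset_mid = seq_len(nb) * bin - bin - halfwidth + bin / 2,
             bases = bases,
             per_hotspot = bases / nrow(hotspots))
}
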