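## Hotspot detection: sliding-window Poisson enrichment against the larger
## of a local-flank and a genome-wide background rate, Benjamini-Hochberg
## control, merging of nearby significant windows, fragment-midpoint
## centroid centers, strength = fragment count in the merged interval.

#' Hotspot caller parameters
#'
#' @param window sliding-window width (bp).
#' @param step window step (bp); must divide `window` and `flank`.
#' @param flank local-background half-width (bp) on each side of a window.
#' @param fdr Benjamini-Hochberg false-discovery level in (0, 1).
#' @param merge_gap significant windows separated by at most this many bp
#'   are merged into one hotspot.
#' @param min_fragments minimum fragments for a window to be considered and
#'   for a merged hotspot to be reported.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(window = 1000, step = 100, flank = 10000,
                          fdr = 0.05, merge_gap = 200, min_fragments = 5) {
  stopifnot(window > 0, step > 0, flank > 0, merge_gap >= 0,
            min_fragments >= 0, window %% step == 0, flank %% step == 0)
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  structure(list(window = as.integer(window), step = as.integer(step),
                 flank = as.integer(flank), fdr = fdr,
                 merge_gap = as.integer(merge_gap),
                 min_fragments = as.integer(min_fragments)),
            class = "caller_params")
}

#' Fragment-midpoint coverage in fixed-width bins
#'
#' Each fragment is assigned to the bin containing its midpoint, so the bin
#' counts sum to the number of fragments.
#'
#' @param fragments fragment data.frame.
#' @param chrom_lengths named chromosome-length vector (taken from the
#'   fragments when attached).
#' @param bin bin width (bp).
#' @return named list (per chromosome) of integer bin-count vectors; bin i
#'   covers `[(i-1)*bin, i*bin)`.
#' @export
compute_coverage <- function(fragments, chrom_lengths = NULL, bin = 100) {
  cl <- chrom_lengths_of(fragments, chrom_lengths)
  validate_fragments(fragments, cl)
  mids <- interval_midpoints(fragments)
  out <- lapply(names(cl), function(chrom) {
    nb <- as.integer(ceiling(cl[[chrom]] / bin))
    m <- mids[fragments$chrom == chrom]
    tabulate(pmin(m %/% bin, nb - 1L) + 1L, nbins = nb)
  })
  names(out) <- names(cl)
  attr(out, "bin") <- bin
  out
}

#' Call DSB hotspots from filtered, pooled fragments
#'
#' Windows of `window` bp, advanced by `step`, are scored against a Poisson
#' background whose rate is the larger of the local flank mean (±`flank` bp)
#' and the genome-wide mean. Window p-values are Benjamini-Hochberg
#' adjusted genome-wide; significant windows (q <= `fdr`, count >=
#' `min_fragments`) closer than `merge_gap` are merged. Each merged hotspot
#' gets `strength` = fragment-midpoint count in its interval, `center` =
#' floor of the mean midpoint, and `qvalue` = the minimum q of its windows.
#' Output intervals are non-overlapping and deterministic for fixed input.
#'
#' @param fragments fragment data.frame (filtered and pooled).
#' @param chrom_lengths named chromosome-length vector.
#' @param params a [caller_params()].
#' @return hotspot data.frame (chrom, start, end, center, strength, qvalue),
#'   0-based half-open, sorted by (chrom, start), with `chrom_lengths`
#'   attached.
#' @export
call_hotspots <- function(fragments, chrom_lengths = NULL,
                          params = caller_params()) {
  cl <- chrom_lengths_of(fragments, chrom_lengths)
  validate_fragments(fragments, cl)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), center = integer(),
                      strength = integer(), qvalue = numeric())
  attr(empty, "chrom_lengths") <- cl
  if (nrow(fragments) == 0) return(empty)

  step <- params$step
  k <- params$window %/% step
  fb <- params$flank %/% step
  total_bins <- sum(ceiling(cl / step))
  global_rate <- nrow(fragments) / total_bins     # fragments per step-bin

  cov <- compute_coverage(fragments, cl, bin = step)
  win <- list()
  for (chrom in names(cl)) {
    counts <- cov[[chrom]]
    nb <- length(counts)
    nw <- max(nb - k + 1L, 1L)
    cs <- c(0, cumsum(counts))
    i <- seq_len(nw)
    hi <- pmin(i + k - 1L, nb)
    wc <- cs[hi + 1L] - cs[i]
    flank_hi <- pmin(hi + fb, nb)
    flank_lo <- pmax(i - 1L - fb, 0L)
    flank_count <- (cs[flank_hi + 1L] - cs[flank_lo + 1L]) - wc
    flank_bins <- (flank_hi - hi) + (i - 1L - flank_lo)
    local_rate <- ifelse(flank_bins > 0, flank_count / flank_bins, 0)
    lambda <- pmax(local_rate, global_rate) * k
    p <- stats::ppois(wc - 1, lambda, lower.tail = FALSE)
    win[[chrom]] <- data.frame(chrom = chrom, idx = i, count = wc, p = p,
                               stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, win)
  win$q <- stats::p.adjust(win$p, method = "BH")
  sig <- win[win$q <= params$fdr & win$count >= params$min_fragments, ]
  if (nrow(sig) == 0) return(empty)

  mids <- interval_midpoints(fragments)
  hs <- list()
  for (chrom in unique(sig$chrom)) {
    s <- sig[sig$chrom == chrom, ]
    w_start <- (s$idx - 1L) * step
    w_end <- pmin(w_start + params$window, cl[[chrom]])
    ir <- IRanges::reduce(IRanges::IRanges(start = w_start + 1L,
                                           end = w_end),
                          min.gapwidth = params$merge_gap + 1L)
    m <- mids[fragments$chrom == chrom]
    for (j in seq_along(ir)) {
      a <- BiocGenerics::start(ir)[j] - 1L
      b <- BiocGenerics::end(ir)[j]
      inside <- m[m >= a & m < b]
      if (length(inside) < params$min_fragments) next
      covered <- w_start < b & w_end > a
      hs[[length(hs) + 1L]] <- data.frame(
        chrom = chrom, start = a, end = b,
        center = as.integer(floor(mean(inside))),
        strength = length(inside),
        qvalue = min(s$q[covered]), stringsAsFactors = FALSE)
    }
  }
  if (length(hs) == 0) return(empty)
  out <- do.call(rbind, hs)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- cl
  out
}

#' Top-n hotspots by strength
#'
#' Descending strength, ties broken by (chrom, start).
#'
#' @param hotspots hotspot data.frame.
#' @param n number to keep; `min(n, nrow)` are returned.
#' @return truncated hotspot data.frame.
#' @export
rank_and_truncate <- function(hotspots, n) {
  if (length(n) != 1 || is.na(n) || n < 0) stop("n must be >= 0")
  ord <- order(-hotspots$strength, hotspots$chrom, hotspots$start)
  out <- hotspots[ord[seq_len(min(n, nrow(hotspots)))], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- attr(hotspots, "chrom_lengths")
  out
}
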