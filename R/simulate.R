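## Synthetic SSDS data generator: miniature genomes with planted truth,
## fragment and H3K4me3 tag simulation. Everything is deterministic given
## the config seed (generation) and the per-call seed (sampling).

BASES <- c("A", "C", "G", "T")

# Pareto(shape, scale) via inverse CDF; heavy-tailed hotspot strengths.
rpareto <- function(n, shape, scale) scale * stats::runif(n)^(-1 / shape)

# overlapping-match starts (0-based) of CGG-N11-CCG in a character string;
# regex lookahead, independent of the Biostrings-based scanner.
naive_gal4_starts <- function(s) {
  m <- gregexpr("(?=CGG[ACGT]{11}CCG)", s, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' Plant the simulation truth set
#'
#' Draws hotspot positions (quasi-uniform slot placement guaranteeing a
#' minimum separation), Pareto strengths, Gal4 flags with motif sites at the
#' flagged centers, and the PAR-like cluster of overlapping hotspots at the
#' high-coordinate end of its chromosome. Called by [generate_genome()];
#' exported so fragment-level analyses that do not need sequence can skip
#' sequence generation.
#'
#' @param config a [sim_config()].
#' @return a `truth_set`: list with `hotspots` (id, chrom, center, strength,
#'   has_gal4, in_par), `motif_sites` (chrom, start, end, hotspot_id,
#'   0-based half-open), `par` interval, and the config.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cl <- config$chrom_lengths
  pad <- max(config$min_separation / 2, 3 * config$offset_sd, 2000)

  hs <- list()
  for (chrom in names(cl)) {
    len <- cl[[chrom]]
    usable <- if (chrom == config$par$chrom) config$par$start - 2 * pad else len
    n <- config$n_hotspots
    if (n == 0) next
    slot <- usable / n
    if (slot < 2 * pad + 1)
      stop("chromosome ", chrom, " too short to host ", n,
           " hotspots at the configured separation")
    lo <- (seq_len(n) - 1) * slot + pad
    hi <- seq_len(n) * slot - pad
    centers <- floor(stats::runif(n, lo, hi))
    hs[[chrom]] <- data.frame(
      chrom = chrom, center = as.integer(centers),
      strength = rpareto(n, config$strength_shape, config$strength_scale),
      has_gal4 = FALSE, in_par = FALSE, stringsAsFactors = FALSE)
  }
  hotspots <- do.call(rbind, hs) %||%
    data.frame(chrom = character(), center = integer(), strength = numeric(),
               has_gal4 = logical(), in_par = logical())

  n_reg <- nrow(hotspots)
  k <- round(config$gal4_fraction * n_reg)
  if (k > 0) hotspots$has_gal4[sample.int(n_reg, k)] <- TRUE

  # PAR cluster: overlapping hotspots evenly spaced across the interval,
  # total expected strength set so the cluster contributes the configured
  # fraction of all expected fragments (background included).
  par <- config$par
  total_strength <- par$total_strength
  if (is.null(total_strength)) {
    # Gal4-flagged hotspots are silent in the reference-like conditions
    # where the PAR fraction is defined, so they are excluded here.
    e_other <- sum(hotspots$strength[!hotspots$has_gal4]) +
      config$background_per_mb * sum(cl) / 1e6
    total_strength <- par$fraction / (1 - par$fraction) * e_other
  }
  if (par$n_hotspots > 0 && total_strength > 0) {
    centers <- par$start +
      floor(par$width * (seq_len(par$n_hotspots) - 0.5) / par$n_hotspots)
    hotspots <- rbind(hotspots, data.frame(
      chrom = par$chrom, center = as.integer(centers),
      strength = total_strength / par$n_hotspots,
      has_gal4 = FALSE, in_par = TRUE, stringsAsFactors = FALSE))
  }
  hotspots$id <- if (nrow(hotspots) > 0)
    paste0("hs", seq_len(nrow(hotspots))) else character(0)

  flagged <- hotspots[hotspots$has_gal4, ]
  motif_sites <- data.frame(
    chrom = flagged$chrom,
    start = flagged$center - 8L,      # 17-bp site midpoint at the center
    end = flagged$center + 9L,
    hotspot_id = flagged$id, stringsAsFactors = FALSE)

  structure(list(hotspots = hotspots, motif_sites = motif_sites,
                 par = list(chrom = par$chrom, start = par$start,
                            end = par$end),
                 config = config),
            chrom_lengths = cl, class = "truth_set")
}

# resample accidental motif matches inside windows; positions inside planted
# site intervals are never touched.
scrub_windows <- function(seq, windows, planted, len) {
  if (nrow(windows) == 0) return(seq)
  protected <- function(p) {
    any(p >= planted$start & p < planted$end)
  }
  for (iter in 1:50) {
    dirty <- FALSE
    for (w in seq_len(nrow(windows))) {
      a <- max(0, windows$start[w]); b <- min(len, windows$end[w])
      lo <- max(0, a - 16); hi <- min(len, b + 16)
      if (hi - lo < 17) next
      starts <- naive_gal4_starts(substr(seq, lo + 1, hi)) + lo
      starts <- starts[starts < b & starts + 17 > a]
      starts <- setdiff(starts, planted$start)
      for (s0 in starts) {
        for (p in s0:(s0 + 16)) {
          if (nrow(planted) > 0 && protected(p)) next
          substr(seq, p + 1, p + 1) <- sample(BASES, 1)
        }
        dirty <- TRUE
      }
    }
    if (!dirty) return(seq)
  }
  stop("could not scrub accidental motif matches (pathological overlap)")
}

#' Generate a synthetic genome with planted truth
#'
#' Draws i.i.d. uniform A/C/G/T sequence for every chromosome, writes an
#' exact CGG-N11-CCG occurrence at each Gal4-flagged hotspot center (the 11
#' degenerate positions keep their random bases), and removes accidental
#' matches that would collide with planted sites; when
#' `config$scrub_hotspot_windows` is TRUE accidental matches within
#' `scrub_halfwidth` of any planted hotspot center are also removed, so a
#' scan of those central windows recovers planted sites only.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named `DNAStringSet`) and `truth`
#'   (see [generate_truth()]); byte-identical across runs for the same
#'   config.
#' @export
generate_genome <- function(config) {
  truth <- generate_truth(config)   # seeds the RNG; sequence draws follow
  cl <- config$chrom_lengths
  seqs <- character(length(cl))
  names(seqs) <- names(cl)
  for (chrom in names(cl)) {
    len <- cl[[chrom]]
    s <- paste(sample(BASES, len, replace = TRUE), collapse = "")
    sites <- truth$motif_sites[truth$motif_sites$chrom == chrom, ]
    for (i in seq_len(nrow(sites))) {
      if (sites$start[i] < 0 || sites$end[i] > len)
        stop("chromosome ", chrom, " too short for a planted motif site")
      substr(s, sites$start[i] + 1, sites$start[i] + 3) <- "CGG"
      substr(s, sites$start[i] + 15, sites$start[i] + 17) <- "CCG"
    }
    # windows to keep free of accidental matches: planted-site
    # neighbourhoods always; hotspot central windows when configured
    win <- data.frame(start = sites$start - 16, end = sites$end + 16)
    if (config$scrub_hotspot_windows) {
      ctr <- truth$hotspots[truth$hotspots$chrom == chrom, "center"]
      win <- rbind(win, data.frame(start = ctr - config$scrub_halfwidth,
                                   end = ctr + config$scrub_halfwidth))
    }
    seqs[[chrom]] <- scrub_windows(s, win, sites, len)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  list(genome = genome, truth = truth)
}

draw_quality <- function(n, low_frac) {
  low <- stats::runif(n) < low_frac
  q <- sample(30:60, n, replace = TRUE)
  q[low] <- sample(0:29, sum(low), replace = TRUE)
  as.integer(q)
}

rnorm_trunc <- function(n, sd, cut = 3) {
  x <- stats::rnorm(n, 0, sd)
  bad <- which(abs(x) > cut * sd)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(x[bad]) > cut * sd]
  }
  x
}

#' Simulate ssDNA fragment records from a planted truth set
#'
#' Per-hotspot fragment counts are Poisson with mean
#' `strength * depth * signal`, further multiplied by the condition's Gal4
#' multiplier (Gal4-flagged hotspots), PAR multiplier (PAR-cluster
#' hotspots), or subtelomeric suppression factor (non-PAR hotspots whose
#' center lies within `end_width` of the high-coordinate chromosome end).
#' Fragment centers are the hotspot center plus truncated-Gaussian noise;
#' background fragments are uniform over the genome at
#' `background_per_mb * depth`. Exact duplicates (same chrom/start/end/
#' strand) are appended with geometric multiplicity; every emitted record
#' carries two independently drawn per-end quality scores.
#'
#' @param truth a `truth_set` from [generate_truth()]/[generate_genome()].
#' @param condition a [condition_params()].
#' @param seed integer seed for this sample.
#' @param replicate_id replicate tag stored on every record.
#' @return fragment data.frame (chrom, start, end, strand, q1, q2,
#'   replicate_id) with attributes `chrom_lengths` and `bookkeeping`
#'   (per-hotspot draws, background count, distinct and total counts).
#' @export
simulate_fragments <- function(truth, condition = condition_params(),
                               seed = 1, replicate_id = "rep1") {
  stopifnot(inherits(truth, "truth_set"),
            inherits(condition, "condition_params"))
  config <- truth$config
  cl <- config$chrom_lengths
  set.seed(as.integer(seed))

  hs <- truth$hotspots
  near_end <- !hs$in_par &
    (cl[hs$chrom] - hs$center) <= config$end_width
  mult <- ifelse(hs$has_gal4, condition$gal4, 1) *
    ifelse(hs$in_par, condition$par_factor, 1) *
    ifelse(near_end, condition$end_factor, 1)
  means <- hs$strength * condition$depth * condition$signal * mult
  draws <- stats::rpois(nrow(hs), means)

  idx <- rep(seq_len(nrow(hs)), draws)
  mids <- hs$center[idx] + round(rnorm_trunc(length(idx), config$offset_sd))
  chroms <- hs$chrom[idx]

  n_bg <- stats::rpois(1, config$background_per_mb * condition$depth *
                            sum(cl) / 1e6)
  if (n_bg > 0) {
    bg_chr <- sample(names(cl), n_bg, replace = TRUE, prob = cl / sum(cl))
    bg_mid <- floor(stats::runif(n_bg, 0, cl[bg_chr]))
    chroms <- c(chroms, bg_chr)
    mids <- c(mids, bg_mid)
  }

  n <- length(mids)
  lens <- pmax(50, round(stats::rnorm(n, config$fragment_length_mean,
                                      config$fragment_length_sd)))
  start <- mids - lens %/% 2
  end <- start + lens
  start <- pmax(0L, as.integer(start))
  end <- pmin(as.integer(cl[chroms]), as.integer(end))
  end <- pmax(end, start + 1L)
  start <- pmin(start, end - 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  dup_extra <- if (config$duplicate_rate > 0)
    stats::rgeom(n, prob = 1 / (1 + config$duplicate_rate)) else rep(0L, n)
  rep_idx <- rep(seq_len(n), dup_extra + 1L)

  out <- data.frame(chrom = chroms[rep_idx], start = start[rep_idx],
                    end = end[rep_idx], strand = strand[rep_idx],
                    q1 = draw_quality(length(rep_idx),
                                      config$low_quality_frac),
                    q2 = draw_quality(length(rep_idx),
                                      config$low_quality_frac),
                    replicate_id = rep(replicate_id, length(rep_idx)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- cl
  attr(out, "bookkeeping") <- list(
    per_hotspot = stats::setNames(draws, hs$id),
    n_background = n_bg, n_distinct = n, n_total = nrow(out))
  out
}

#' Simulate H3K4me3 tags and peak intervals
#'
#' Tags cluster at every planted hotspot (including PAR and subtelomeric
#' ones) with no suppression of any kind, emulating the observation that
#' PRDM9-dependent H3K4me3 is deposited normally even where DSB signal is
#' depleted. No background tags are emitted.
#'
#' @param truth a `truth_set`.
#' @param seed integer seed.
#' @param tag_depth multiplier on expected tag counts per hotspot.
#' @param tag_length tag interval length (bp).
#' @return list with `tags` (chrom, start, end) and `peaks`
#'   (chrom, start, end; hotspot center +/- 500 bp), both 0-based half-open,
#'   with `chrom_lengths` attached.
#' @export
simulate_h3k4me3_tags <- function(truth, seed = 1, tag_depth = 1,
                                  tag_length = 100) {
  stopifnot(inherits(truth, "truth_set"))
  config <- truth$config
  cl <- config$chrom_lengths
  set.seed(as.integer(seed))
  hs <- truth$hotspots
  draws <- if (nrow(hs) > 0)
    stats::rpois(nrow(hs), hs$strength * tag_depth) else integer(0)
  idx <- rep(seq_len(nrow(hs)), draws)
  mids <- if (length(idx) > 0)
    hs$center[idx] + round(rnorm_trunc(length(idx), config$offset_sd))
  else integer(0)
  start <- pmax(0L, as.integer(mids - tag_length %/% 2))
  end <- pmin(as.integer(cl[hs$chrom[idx]]),
              as.integer(start + tag_length))
  tags <- data.frame(chrom = hs$chrom[idx], start = start,
                     end = pmax(end, start + 1L), stringsAsFactors = FALSE)
  rownames(tags) <- NULL
  peaks <- data.frame(chrom = hs$chrom,
                      start = pmax(0L, hs$center - 500L),
                      end = pmin(as.integer(cl[hs$chrom]),
                                 hs$center + 500L),
                      stringsAsFactors = FALSE)
  attr(tags, "chrom_lengths") <- cl
  attr(peaks, "chrom_lengths") <- cl
  list(tags = tags, peaks = peaks)
}
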