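## End-to-end orchestration: simulate -> filter -> call -> scan -> classify
## -> landscape, with a machine-readable report and summary-table rendering.

#' Pipeline run configuration
#'
#' Bundles the generator config, stage parameters and the simulated
#' conditions into one reproducible unit. The default conditions emulate a
#' four-sample experiment: a wild-type-like reference, a low-depth
#' meiotic-arrest-background sample sharing the reference truth, and two
#' Gal4-targeting samples (normal and high depth) in which Gal4-flagged
#' hotspots are active, subtelomeric hotspots are suppressed and the PAR
#' cluster is reduced 33-fold.
#'
#' @param sim a [sim_config()].
#' @param filter a [filter_params()].
#' @param caller a [caller_params()].
#' @param overlap an [overlap_params()].
#' @param conditions named list of [condition_params()].
#' @param n_replicates simulated replicates per condition.
#' @param landscape_bin,landscape_end_mask,landscape_end_width landscape
#'   binning (bp), centromeric mask (bp) and subtelomeric zone width (bp).
#' @param outdir output directory for stage files, or NULL to skip writing.
#' @param seed master seed; all per-sample seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       filter = filter_params(),
                       caller = caller_params(),
                       overlap = overlap_params(),
                       conditions = NULL,
                       n_replicates = 2,
                       landscape_bin = 1e6,
                       landscape_end_mask = 3e6,
                       landscape_end_width = 5e6,
                       outdir = NULL,
                       seed = 1) {
  if (is.null(conditions)) {
    sf <- sim$suppression_factor
    conditions <- list(
      wild_type = condition_params(depth = 1, gal4 = 0),
      arrest = condition_params(depth = 0.25, gal4 = 0),
      gal4 = condition_params(depth = 0.6, gal4 = 1, end_factor = sf,
                              par_factor = 1 / 33),
      gal4_arrest = condition_params(depth = 1, gal4 = 1, end_factor = sf,
                                     par_factor = 1 / 33))
  }
  stopifnot(inherits(sim, "sim_config"), n_replicates >= 1,
            length(conditions) >= 1, !is.null(names(conditions)))
  structure(list(sim = sim, filter = filter, caller = caller,
                 overlap = overlap, conditions = conditions,
                 n_replicates = n_replicates,
                 landscape_bin = landscape_bin,
                 landscape_end_mask = landscape_end_mask,
                 landscape_end_width = landscape_end_width,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' @keywords internal
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "outdir")]), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates the genome and truth set, scans it for the Gal4 consensus,
#' simulates H3K4me3 tags/peaks and, per condition, `n_replicates` fragment
#' replicates; filters (quality then duplicate cap), pools, calls hotspots,
#' classifies every condition against the first condition's hotspots
#' (the reference), computes the binned landscape and subtelomeric depletion
#' statistic per condition, and the PAR fragment fraction. Two runs with an
#' identical config produce identical reports.
#'
#' @param config a [run_config()].
#' @return a `run_report`: list with `table1` (per-condition rows), `hotspots`,
#'   `classifications`, `landscape` (profiles + depletion stats, DSB and
#'   H3K4me3), `par` (per-condition fractions and the fold change of the
#'   first vs last condition), `motif_sites`, `config_hash`, and `version`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  gen <- generate_genome(config$sim)
  truth <- gen$truth
  cl <- config$sim$chrom_lengths

  motif_sites <- scan_consensus(gen$genome, gal4_consensus())
  k4 <- simulate_h3k4me3_tags(truth, seed = config$seed + 7919L)

  samples <- list()
  for (i in seq_along(config$conditions)) {
    cname <- names(config$conditions)[i]
    reps <- lapply(seq_len(config$n_replicates), function(r)
      simulate_fragments(truth, config$conditions[[i]],
                         seed = config$seed + 1000L * i + r,
                         replicate_id = paste0(cname, "_rep", r)))
    raw_n <- sum(vapply(reps, nrow, integer(1)))
    pooled <- process_fragments(reps, config$filter)
    hotspots <- call_hotspots(pooled, cl, config$caller)
    samples[[cname]] <- list(fragments = pooled, hotspots = hotspots,
                             n_raw = raw_n)
  }

  ref_name <- names(config$conditions)[1]
  reference <- samples[[ref_name]]$hotspots

  table1 <- list()
  classifications <- list()
  for (cname in names(samples)) {
    cls <- classify_hotspots(samples[[cname]]$hotspots,
                             reference = reference, motifs = motif_sites,
                             h3k4me3 = k4$peaks, params = config$overlap,
                             chrom_lengths = cl)
    classifications[[cname]] <- cls
    s <- attr(cls, "summary")
    table1[[cname]] <- data.frame(
      sample = cname,
      fragments_millions = round(nrow(samples[[cname]]$fragments) / 1e6, 3),
      n_hotspots = s$n_total,
      n_motif = s$n_motif, pct_motif = s$pct_motif,
      n_shared = s$n_shared, pct_shared = s$pct_shared,
      stringsAsFactors = FALSE)
  }
  table1 <- do.call(rbind, table1)
  rownames(table1) <- NULL

  # landscape over the reference hotspot intervals
  landscape <- list()
  ref_profile <- in_hotspot_window_profile(
    samples[[ref_name]]$fragments, reference, cl,
    bin = config$landscape_bin, end_mask = config$landscape_end_mask)
  k4_profile <- in_hotspot_window_profile(
    k4$tags, reference, cl,
    bin = config$landscape_bin, end_mask = config$landscape_end_mask)
  for (cname in names(samples)) {
    prof <- in_hotspot_window_profile(
      samples[[cname]]$fragments, reference, cl,
      bin = config$landscape_bin, end_mask = config$landscape_end_mask)
    dep <- subtelomere_depletion_stat(prof, ref_profile,
                                      end_width = config$landscape_end_width,
                                      seed = config$seed + 17L)
    landscape[[cname]] <- list(profile = prof, depletion = dep)
  }
  k4_dep <- subtelomere_depletion_stat(k4_profile, ref_profile,
                                       end_width = config$landscape_end_width,
                                       seed = config$seed + 18L)
  landscape$h3k4me3 <- list(profile = k4_profile, depletion = k4_dep)

  par <- lapply(samples, function(s)
    par_cluster_fraction(s$fragments, truth$par))
  first <- par[[1]]$percent_raw
  last <- par[[length(par)]]$percent_raw
  par$fold_change <- if (last > 0) par_fold_change(first, last) else Inf

  report <- structure(list(
    table1 = table1, hotspots = lapply(samples, `[[`, "hotspots"),
    classifications = classifications, landscape = landscape, par = par,
    motif_sites = motif_sites, truth = truth,
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("dsbscape"))),
    class = "run_report")

  if (!is.null(config$outdir)) write_report_files(report, config)
  report
}

#' @keywords internal
write_report_files <- function(report, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$table1,
                     file.path(config$outdir, "table1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(report$motif_sites,
            file.path(config$outdir, "gal4_sites.bed"))
  for (cname in names(report$hotspots)) {
    hs <- report$hotspots[[cname]]
    hs$name <- paste0(cname, "_", seq_len(nrow(hs)))
    hs$score <- hs$strength
    write_bed(hs, file.path(config$outdir, paste0(cname, "_hotspots.bed")),
              extra = c("center", "qvalue"))
  }
  summary <- list(table1 = report$table1,
                  depletion = lapply(report$landscape, function(x)
                    x$depletion[c("ratio", "p_value")]),
                  par = report$par, config_hash = report$config_hash,
                  version = report$version)
  jsonlite::write_json(summary,
                       file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$outdir)
}

#' @keywords internal
fmt_count <- function(n) formatC(n, big.mark = ",", format = "d")

#' @keywords internal
fmt_pct <- function(n, total) {
  if (total == 0) return("(—)")
  pct <- round_half_up(100 * n / total, 1)
  if (pct == 100) "(100%)" else sprintf("(%.1f%%)", pct)
}

#' Render a summary table of hotspot counts and overlap percentages
#'
#' One row per sample: identified hotspots, hotspots with a Gal4 consensus
#' (count and percent), hotspots present in the reference (count and
#' percent); percentages to one decimal with half-up rounding, thousands
#' separators in the rendered output only.
#'
#' @param report a `run_report` from [run_pipeline()], or its `table1`
#'   data.frame.
#' @return character vector of tab-separated rows, including a header.
#' @export
format_table1 <- function(report) {
  tab <- if (inherits(report, "run_report")) report$table1 else report
  header <- paste("Sample", "Identified hotspots",
                  "Hotspots with Gal4 consensus",
                  "Hotspots present in the reference", sep = "\t")
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    with(tab[i, ], paste(
      sample, fmt_count(n_hotspots),
      paste(fmt_count(n_motif), fmt_pct(n_motif, n_hotspots)),
      paste(fmt_count(n_shared), fmt_pct(n_shared, n_hotspots)),
      sep = "\t"))
  }, character(1))
  c(header, rows)
}

#' Percent share of a count, table-style
#'
#' `100 * count / total` rounded half-up to one decimal — the convention of
#' the rendered summary tables (e.g. 546 of 13,445 is 4.1).
#'
#' @param count,total non-negative counts, `total > 0`.
#' @return percentage, one decimal.
#' @export
percent_share <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  round_half_up(100 * count / total, 1)
}
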