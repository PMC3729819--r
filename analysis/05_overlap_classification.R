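# Classify each condition's hotspots against the wild-type reference set,
# the scanned Gal4 sites and the H3K4me3 peaks; render the per-sample
# summary table; profile Gal4-site coverage around shared vs specific
# hotspot centers; correlate shared-hotspot strengths.

source("analysis/00_config.R")

sites <- read_bed(file.path(OUT, "gal4_sites.bed"))
peaks <- read_bed(file.path(DATA, "h3k4me3_peaks.bed"))
read_hotspots <- function(cname) {
  df <- read_bed(file.path(OUT, paste0(cname, "_hotspots.bed")))
  names(df)[7:8] <- c("center", "qvalue")
  df$strength <- df$score
  df
}
reference <- read_hotspots("wild_type")

rows <- list()
for (cname in names(CONDITIONS)) {
  hs <- read_hotspots(cname)
  cls <- classify_hotspots(hs, reference, motifs = sites, h3k4me3 = peaks,
                           chrom_lengths = SIM$chrom_lengths)
  s <- attr(cls, "summary")
  write.table(cls, file.path(OUT, paste0(cname, "_classified.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rows[[cname]] <- data.frame(sample = cname, n_hotspots = s$n_total,
                              n_motif = s$n_motif, pct_motif = s$pct_motif,
                              n_shared = s$n_shared,
                              pct_shared = s$pct_shared)
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(OUT, "classification_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(format_table1(tab), file.path(OUT, "classification_table.txt"))
message(paste(format_table1(tab), collapse = "\n"))

# shared vs specific motif profiles for the strongest Gal4 condition
mut <- read_hotspots("gal4_arrest")
cls <- classify_hotspots(mut, reference, motifs = sites,
                         chrom_lengths = SIM$chrom_lengths)
shared <- cls[cls$shared & cls$has_motif, ]
specific <- cls[!cls$shared & cls$has_motif, ]
prof <- rbind(
  cbind(group = "shared",
        motif_center_profile(shared, sites)),
  cbind(group = "specific",
        motif_center_profile(specific, sites)))
write.table(prof, file.path(OUT, "motif_center_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("motif-bearing hotspots: %d shared, %d specific",
                nrow(shared), nrow(specific)))

rho <- strength_correlation(mut, reference,
                            chrom_lengths = SIM$chrom_lengths)
message(sprintf("log-strength Spearman rho over %d shared hotspots: %.3f",
                rho$n_pairs, rho$rho))
jsonlite::write_json(list(rho = rho$rho, n_pairs = rho$n_pairs),
                     file.path(OUT, "strength_correlation.json"),
                     auto_unbox = TRUE, digits = NA)
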