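# Generate the synthetic study: genome with planted Gal4 sites, truth set,
# per-condition ssDNA fragment replicates, and H3K4me3 tags/peaks.

source("analysis/00_config.R")

gen <- generate_genome(SIM)
truth <- gen$truth

write_genome_fasta(gen$genome, file.path(DATA, "genome.fa"))
write.table(truth$hotspots, file.path(DATA, "truth_hotspots.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(truth$par, file.path(DATA, "par_interval.json"),
                     auto_unbox = TRUE)

message(sprintf("planted %d hotspots (%d Gal4-flagged, %d in the PAR cluster)",
                nrow(truth$hotspots), sum(truth$hotspots$has_gal4),
                sum(truth$hotspots$in_par)))

for (cname in names(CONDITIONS)) {
  for (r in seq_len(N_REPLICATES)) {
    fr <- simulate_fragments(truth, CONDITIONS[[cname]],
                             seed = SEED + 1000L * match(cname,
                                                         names(CONDITIONS)) + r,
                             replicate_id = paste0(cname, "_rep", r))
    write_fragments(fr, file.path(DATA, sprintf("%s_rep%d.bed", cname, r)))
    message(sprintf("  %s rep%d: %d fragments", cname, r, nrow(fr)))
  }
}

k4 <- simulate_h3k4me3_tags(truth, seed = SEED + 7919L)
write_bed(k4$tags, file.path(DATA, "h3k4me3_tags.bed"))
write_bed(k4$peaks, file.path(DATA, "h3k4me3_peaks.bed"))
message(sprintf("H3K4me3: %d tags at %d peaks", nrow(k4$tags),
                nrow(k4$peaks)))
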