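#!/usr/bin/env Rscript
# Per-locus informativeness statistics for the simulated study fixture:
# aligned length, indel events and total indel bp, transitions and
# transversions (consensus-counted), merged microsatellite loci, and
# parsimony-informative sites, plus per-kb rates — the table a marker
# screen ranks loci by. Detected counts are put side by side with the
# simulator's logged events.
#
# Finding: at survey-regime rates the detectors recover the configured
# event counts closely (substitutions slightly below the logged events
# where multiple hits overprint the same column).

library(spacerscreen)

sim <- make_marker_fixture(seed = 42)
report <- do.call(rbind, lapply(sim$alignments, informativeness_report))
rownames(report) <- NULL

recovery <- truth_compare(sim, partition = sim$partition)

dir.create("results", showWarnings = FALSE)
write.table(report, "results/informativeness.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(recovery, "results/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("per-locus informativeness (results/informativeness.tsv):\n")
print(report[, c("locus_name", "length", "n_indels", "indel_bp",
                 "transitions", "transversions", "n_ssr", "n_pis")],
      row.names = FALSE)
cat("\ndetected vs logged events (results/recovery.tsv):\n")
print(recovery[, c("locus_name", "true_indel_events", "detected_indels",
                   "true_subs", "detected_subs", "planted_ssr",
                   "detected_ssr")], row.names = FALSE)
cat(sprintf("\nindel replay exact for %d/%d loci\n",
            sum(recovery$indel_replay_exact), nrow(recovery)))
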