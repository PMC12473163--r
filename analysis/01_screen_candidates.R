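#!/usr/bin/env Rscript
# In-silico candidate screen: extract the 49 catalogued plastome regions
# (43 intergenic spacers, 6 introns) from three annotated genome records,
# align the homologous copies and score their informativeness. Here the
# records are synthetic plastome-like sequences with a shared gene order and
# divergent spacers, so the screen demonstrates extraction, alignment and
# ranking on inputs with known structure. Real GenBank flat files can be
# substituted via read_genbank().
#
# Finding: spacer/intron regions present in all three records are extracted,
# aligned and ranked by substitutions/kb + SSR count; regions whose flank
# genes are absent from the synthetic gene order are reported in the log.

library(spacerscreen)

genomes <- synthetic_plastomes(n = 3, seed = 42)
cat(sprintf("screening %d genomes (%s) against %d catalogued regions\n",
            length(genomes),
            paste(vapply(genomes, `[[`, "", "id"), collapse = ", "),
            length(builtin_catalogue())))

screen <- screen_regions(genomes, builtin_catalogue())

dir.create("results", showWarnings = FALSE)
write.table(screen$report, "results/screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(screen$log, "results/screen_log.txt")

cat(sprintf("scored %d regions (report: results/screen.tsv); %d log lines\n",
            nrow(screen$report), length(screen$log)))
cat("top five regions by informativeness score:\n")
print(screen$report[1:5, c("locus_name", "length", "transitions",
                           "transversions", "n_ssr", "n_pis")],
      row.names = FALSE)
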