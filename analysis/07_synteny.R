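#!/usr/bin/env Rscript
# Syntenic mouse-human CNA concordance: map mouse CNA-positive regions to
# their human homologues, apply the strict 5% human carrier-frequency
# rule, and test each CNA type's contingency table with the two-tailed
# Fisher exact test.

library(atf6scope)

sim <- "results/sim"
mouse <- read_regions(file.path(sim, "mouse_cna.bed"))
human <- read_regions(file.path(sim, "human_cna.bed"))
map <- read.table(file.path(sim, "homology_map.tsv"), header = TRUE,
                  sep = "\t")
background <- read.table(file.path(sim, "cna_background.tsv"),
                         header = TRUE, sep = "\t")

mh <- map_homologues(mouse, map, human)
message(nrow(mh$pairs), " homologous pairs, ",
        length(mh$unmapped), " unmapped mouse regions")
write.table(mh$pairs, "results/synteny_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

report <- do.call(rbind, lapply(c("gain", "loss"), function(tp) {
  tab <- concordance_table(mh$pairs, background, tp, threshold = 0.05)
  p <- fisher_exact(tab)
  message(sprintf(
    "%s: %d/%d pairs concordant (human freq > 5%%) vs %d/%d background; Fisher p = %.3g",
    tp, tab$table["cna", "concordant"], sum(tab$table["cna", ]),
    tab$table["background", "concordant"], sum(tab$table["background", ]), p))
  data.frame(cna_type = tp,
             concordant = tab$table["cna", "concordant"],
             discordant = tab$table["cna", "discordant"],
             bg_concordant = tab$table["background", "concordant"],
             bg_discordant = tab$table["background", "discordant"],
             fisher_p = p)
}))
write.table(report, "results/synteny_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
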