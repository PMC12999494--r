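#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with
# known ground truth, and write them in the exchange formats the package
# reads (TSV matrices, GMT gene sets, BED-like regions, label-image
# matrices). Conditions mirror the study: 22 tumour/non-tumour datasets
# with a planted up/down signature, a 370-patient scored survival cohort,
# a disc-packed tissue image, mouse/human CNA calls and a MIBI feature
# table with planted QC violations.

library(atf6scope)

seed <- 20260101
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- sim_spec(n_genes = 1000, n_samples_per_group = 50, n_datasets = 22,
                 effect_size = 0.8, seed = seed)

## multi-dataset expression panel with shared signature
panel <- gen_multi_dataset(spec)
for (co in panel$cohorts) {
  write_matrix(co$expr, file.path(out, paste0("expr_", co$dataset, ".tsv")))
  write.table(data.frame(sample = names(co$labels), label = co$labels),
              file.path(out, paste0("labels_", co$dataset, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
sig <- panel$signature
write_gmt(structure(list(name = "planted",
                         sets = list(ATF6_UP = sig$up, ATF6_DN = sig$dn)),
                    class = "GeneSetCollection"),
          file.path(out, "signature.gmt"))
message("wrote ", spec$n_datasets, " cohorts (",
        spec$n_genes, " genes x ", 2 * spec$n_samples_per_group,
        " samples), signature: ", length(sig$up), " up / ",
        length(sig$dn), " dn genes")

## survival cohort: hazard driven by the combined score of cohort 1
sc <- score_signature(panel$cohorts[[1]]$expr, sig)
surv <- gen_survival_cohort(sim_spec(seed = seed, hazard_beta = 1),
                            rep(sc$es_combined, length.out = 370))
write.table(surv, file.path(out, "survival.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote survival cohort: n = ", nrow(surv),
        ", events = ", sum(surv$event))

## tissue image for the IMC stack
tis <- gen_tissue_image(sim_spec(n_cells = 100, seed = seed))
write_label_image(tis$cells, file.path(out, "cells.txt"))
write_label_image(tis$nuclei, file.path(out, "nuclei.txt"))
for (m in names(tis$planes)) {
  write.table(tis$planes[[m]], file.path(out, paste0("plane_", m, ".txt")),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}
write.table(tis$truth, file.path(out, "tissue_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote tissue image: ", length(label_ids(tis$cells)), " cells")

## mouse/human CNA call sets
cna <- gen_cna_dataset(sim_spec(n_regions = 40, concordance_frac = 0.9,
                                background_frac = 0.1, seed = seed))
write_regions(cna$mouse, file.path(out, "mouse_cna.bed"))
write_regions(cna$human, file.path(out, "human_cna.bed"))
write.table(cna$map, file.path(out, "homology_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cna$background, file.path(out, "cna_background.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote CNA sets: ", nrow(cna$mouse), " mouse regions, planted ",
        sum(cna$truth), " concordant")

## MIBI per-cell features with planted QC violations
ft <- gen_sc_feature_table(sim_spec(n_cells = 500, seed = seed),
                           violations = c(area_low = 5, area_high = 3,
                                          nuclear_dim = 4, prop_low = 2,
                                          prop_high = 2))
write.table(ft, file.path(out, "mibi_features.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote MIBI features: ", nrow(ft), " cells, 16 planted violations")
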