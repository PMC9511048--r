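#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# A universe of 500 proteins annotated over 200 GO terms and 30 KEGG pathways
# (background prevalence 0.05), with 10 planted signal terms (prevalence 0.2)
# whose co-annotation is 20-fold enriched among the 2,000 positive pairs.
# Writes the interaction and annotation TSVs that stage 2 reads, plus the
# ground truth, under results/data/.

library(ppifun)

cfg <- synthetic_config(n_proteins = 500, n_go = 200, n_kegg = 30,
                        base_prevalence = 0.05, n_signal = 10,
                        signal_prevalence = 0.2, n_pos = 2000,
                        enrichment = 20, seed = 101)
sim <- generate_synthetic(cfg)
paths <- write_synthetic_inputs(sim, "results/data")

sig <- sim$truth$signal_terms
cat("universe:", length(sim$profiles), "proteins,",
    length(sim$catalog$go_terms), "GO terms,",
    length(sim$catalog$kegg_pathways), "KEGG pathways\n")
cat("positives:", nrow(sim$interactions), "pairs\n")
cat("signal terms (", length(sig), "):", paste(sig, collapse = ", "), "\n")
cat("written:\n"); for (p in paths) cat("  ", p, "\n")
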