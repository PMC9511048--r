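#!/usr/bin/env Rscript
# Stage 2: ingest the interaction and annotation tables and build balanced
# datasets.
#
# Negatives are uniform random non-positive pairs; the pool is partitioned
# into K = 5 disjoint subsets, each combined with the full positive set
# (~1:1 classes). Writes one labelled pair-list TSV per dataset under
# results/datasets/.

library(ppifun)

SEED <- 202
K <- 5

ann <- read_annotations("results/data/go_annotations.tsv",
                        "results/data/kegg_annotations.tsv")
positives <- read_interactions("results/data/interactions.tsv", 0)
positives <- restrict_to_annotated(positives, ann$profiles)
proteins <- sort(unique(c(positives$protein1, positives$protein2)))

cat("catalog:", length(ann$catalog$go_terms), "GO +",
    length(ann$catalog$kegg_pathways), "KEGG terms;",
    nrow(positives), "positive pairs over", length(proteins), "proteins\n")
cat("all pairs:", count_all_pairs(length(proteins)),
    "-> K =", K, "balanced datasets\n")

negatives <- sample_negatives(proteins, positives, K * nrow(positives),
                              seed = derive_seed(SEED, "negatives"))
subsets <- partition_negatives(negatives, K,
                               seed = derive_seed(SEED, "partition"))
datasets <- build_datasets(positives, subsets)

dir.create("results/datasets", showWarnings = FALSE, recursive = TRUE)
for (ds in datasets) {
  df <- rbind(cbind(ds$positives[, 1:2], label = 1L),
              cbind(ds$negatives[, 1:2], label = 0L))
  f <- sprintf("results/datasets/dataset_%02d.tsv", ds$dataset_id)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("  ", f, ":", nrow(ds$positives), "positives +",
      nrow(ds$negatives), "negatives\n")
}
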