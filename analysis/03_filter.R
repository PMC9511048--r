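#!/usr/bin/env Rscript
# Stage 3: encode each balanced dataset as the 2(n+m)-channel sum/absdiff
# pair-feature matrix and filter it with the shadow-feature procedure.
#
# Each dataset is filtered independently (50 iterations of a 50-tree forest,
# two-sided binomial decisions at alpha = 0.05 with Bonferroni correction);
# writes per-dataset selections and the selected-count table (the violin-plot
# data) under results/filter/.

library(ppifun)

SEED <- 202

ann <- read_annotations("results/data/go_annotations.tsv",
                        "results/data/kegg_annotations.tsv")
files <- sort(list.files("results/datasets", full.names = TRUE))
dir.create("results/filter", showWarnings = FALSE, recursive = TRUE)

filter_results <- lapply(seq_along(files), function(k) {
  d <- read.delim(files[k])
  ds <- structure(list(
    dataset_id = k,
    positives = d[d$label == 1, c("protein1", "protein2")],
    negatives = d[d$label == 0, c("protein1", "protein2")]),
    class = "balanced_dataset")
  pfm <- encode_dataset(ds, ann$profiles, ann$catalog)
  res <- boruta_filter(pfm, max_iter = 50, num_trees = 50,
                       seed = derive_seed(SEED, "boruta", k), dataset_id = k)
  cat(sprintf("dataset %d: %d/%d features selected in %d iterations\n",
              k, length(res$selected), ncol(pfm$X), res$n_iterations))
  jsonlite::write_json(
    list(dataset_id = k, selected = res$selected,
         selected_names = res$selected_names, n_iterations = res$n_iterations),
    sprintf("results/filter/selected_%02d.json", k), auto_unbox = TRUE)
  res
})

u <- union_selected(filter_results)
cat("union of selections across datasets:", length(u$features), "features\n")
counts <- data.frame(dataset_id = seq_along(files),
                     n_selected = vapply(filter_results,
                                         function(r) length(r$selected), 0L))
write.table(counts, "results/filter/selected_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
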