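#!/usr/bin/env Rscript
# Stage 4: rank each dataset's selected features with the three schemes —
# L1-penalised regression coefficients (lasso), gradient-boosted-tree split
# counts (gbdt) and greedy minimum-redundancy maximum-relevance (mrmr).
#
# Writes one TSV per (dataset, algorithm) under results/ranked/.

library(ppifun)

SEED <- 202

ann <- read_annotations("results/data/go_annotations.tsv",
                        "results/data/kegg_annotations.tsv")
files <- sort(list.files("results/datasets", full.names = TRUE))
dir.create("results/ranked", showWarnings = FALSE, recursive = TRUE)

for (k in seq_along(files)) {
  d <- read.delim(files[k])
  ds <- structure(list(
    dataset_id = k,
    positives = d[d$label == 1, c("protein1", "protein2")],
    negatives = d[d$label == 0, c("protein1", "protein2")]),
    class = "balanced_dataset")
  pfm <- encode_dataset(ds, ann$profiles, ann$catalog)
  sel <- jsonlite::read_json(sprintf("results/filter/selected_%02d.json", k),
                             simplifyVector = TRUE)
  filt <- structure(list(dataset_id = k, selected = as.integer(sel$selected)),
                    class = "filter_result")
  ranked <- rank_dataset(pfm, filt, seed = SEED)
  for (alg in names(ranked)) {
    f <- sprintf("results/ranked/%s_%02d.tsv", alg, k)
    write.table(ranked[[alg]], f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cat(sprintf("dataset %d: ranked %d features with %s\n", k,
              length(filt$selected), paste(names(ranked), collapse = ", ")))
}
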