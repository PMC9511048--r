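#!/usr/bin/env Rscript
# Stage 5: integrate each algorithm's per-dataset lists with the importance
# score M(f)/W(f), take the top 40 of each integrated list, intersect the
# three top sets (Venn partition), and score recovery of the planted signal
# terms.
#
# Writes the integrated lists, Venn table and run metadata under
# results/consensus/, and prints the headline numbers.

library(ppifun)

TOP_N <- 40

ann <- read_annotations("results/data/go_annotations.tsv",
                        "results/data/kegg_annotations.tsv")
descriptors <- feature_descriptors(ann$catalog)
K <- length(list.files("results/datasets"))

read_ranked <- function(path, alg) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  attr(df, "algorithm") <- alg
  class(df) <- c("ranked_list", "data.frame")
  df
}

integrated <- list()
tops <- list()
for (alg in c("lasso", "gbdt", "mrmr")) {
  paths <- sort(list.files("results/ranked", pattern = paste0("^", alg),
                           full.names = TRUE))
  lists <- lapply(paths, read_ranked, alg = alg)
  integrated[[alg]] <- integrate_ranked_lists(lists, K = K)
  tops[[alg]] <- suppressWarnings(top_features(integrated[[alg]], TOP_N))
  cat(alg, ": integrated", nrow(integrated[[alg]]), "features from",
      length(lists), "lists; top", length(tops[[alg]]), "retained\n")
}

venn <- venn_partition(tops)
print(venn)
report <- render_report(tops, venn, descriptors)
cat("GO/KEGG split of each top list:\n")
print(report$channel_counts)
if (nrow(report$venn_table)) {
  cat("features found by all three algorithms:\n")
  triple <- report$venn_table[report$venn_table$n_algorithms == 3, ]
  print(triple[, c("feature", "display_name")], row.names = FALSE)
}

truth_json <- jsonlite::read_json("results/data/truth.json",
                                  simplifyVector = TRUE)
truth <- structure(list(signal_terms = sort(truth_json$signal_terms),
                        signal_features = sort(truth_json$signal_features)),
                   class = "synthetic_truth")
for (alg in names(tops)) {
  sep <- signal_separation(truth, integrated[[alg]]$name, descriptors, seed = 7)
  cat(sprintf(
    "%s: recovery of signal terms in top %d = %.2f; rank separation %.2f (p = %.4f)\n",
    alg, TOP_N, recovery_rate(truth, tops[[alg]], TOP_N),
    sep$difference, sep$p_value))
}

paths <- write_outputs(list(integrated = integrated, venn = venn,
                            metadata = list(top_n = TOP_N, K = K)),
                       "results/consensus")
cat("written:\n"); for (p in paths) cat("  ", p, "\n")
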