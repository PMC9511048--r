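# shared in-code fixtures: a tiny annotated universe and TSV writers

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# catalog with 3 GO terms and 2 KEGG pathways plus four profiles
tiny_universe <- function() {
  catalog <- annotation_catalog(c("GO:0000001", "GO:0000002", "GO:0000003"),
                                c("hsa00010", "hsa00020"))
  profiles <- list(
    A = protein_profile("A", go_set = 1L, kegg_set = 1L, catalog),
    B = protein_profile("B", go_set = c(1L, 2L), kegg_set = integer(), catalog),
    C = protein_profile("C", go_set = 3L, kegg_set = 2L, catalog),
    D = protein_profile("D", go_set = integer(), kegg_set = 2L, catalog))
  list(catalog = catalog, profiles = profiles)
}

# random profile over a catalog, for property-style checks
random_profile <- function(id, catalog, p = 0.4) {
  n <- length(catalog$go_terms); m <- length(catalog$kegg_pathways)
  repeat {
    gs <- which(stats::runif(n) < p)
    ks <- which(stats::runif(m) < p)
    if (length(gs) + length(ks) > 0) break
  }
  protein_profile(id, gs, ks, catalog)
}

# hand-built ranked_list for consensus tests (rank i = i-th element)
make_ranked <- function(feature_ids, algorithm = "mrmr", dataset_id = 1L,
                        names = paste0("f", feature_ids)) {
  df <- data.frame(rank = seq_along(feature_ids), feature_id = feature_ids,
                   name = names, score = rev(seq_along(feature_ids)),
                   stringsAsFactors = FALSE)
  attr(df, "algorithm") <- algorithm
  attr(df, "dataset_id") <- dataset_id
  class(df) <- c("ranked_list", "data.frame")
  df
}

# independent brute-force greedy mRMR oracle, entropy form via table();
# deliberately a different code path from the package implementation
mrmr_oracle <- function(X, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  mi <- function(a, b) ent(a) + ent(b) - ent(paste(a, b))
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) mi(X[, j], y), 0)
  selected <- integer(0)
  remaining <- seq_len(p)
  while (length(remaining) > 0) {
    crit <- vapply(remaining, function(j) {
      if (length(selected) == 0) rel[j] else
        rel[j] - mean(vapply(selected, function(s) mi(X[, j], X[, s]), 0))
    }, 0)
    # same declared tie rule as the package: ties at 1e-12 resolve by id
    best <- remaining[order(-round(crit, 12), remaining)[1]]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}
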