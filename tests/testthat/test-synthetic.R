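test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_proteins = 60, n_go = 30, n_kegg = 8,
                          n_signal = 4, n_pos = 100, enrichment = 10, seed = 3)
  s1 <- generate_synthetic(cfg)
  s2 <- generate_synthetic(cfg)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(s1$truth$signal_terms, s2$truth$signal_terms)
  expect_identical(lapply(s1$profiles, unclass), lapply(s2$profiles, unclass))
})

test_that("every protein carries at least one annotation", {
  cfg <- synthetic_config(n_proteins = 200, n_go = 20, n_kegg = 5,
                          base_prevalence = 0.02, n_signal = 2,
                          n_pos = 50, seed = 8)
  sim <- generate_synthetic(cfg)
  sizes <- vapply(sim$profiles, function(p)
    length(p$go_set) + length(p$kegg_set), 0L)
  expect_true(all(sizes >= 1))
  expect_length(sim$profiles, 200)
})

test_that("signal terms span both channels and are in the catalog", {
  cfg <- synthetic_config(n_proteins = 50, n_go = 30, n_kegg = 30,
                          n_signal = 6, n_pos = 40, seed = 2)
  sim <- generate_synthetic(cfg)
  terms <- sim$truth$signal_terms
  expect_true(all(terms %in% c(sim$catalog$go_terms, sim$catalog$kegg_pathways)))
  expect_true(any(terms %in% sim$catalog$go_terms))
  expect_true(any(terms %in% sim$catalog$kegg_pathways))
  expect_length(sim$truth$signal_features, 12) # sum + absdiff per term
})

shared_fraction <- function(sim, pairs) {
  sig <- sim$truth$signal_terms
  sig_sets <- lapply(sim$profiles, function(p) {
    intersect(c(sim$catalog$go_terms[p$go_set],
                sim$catalog$kegg_pathways[p$kegg_set]), sig)
  })
  mean(mapply(function(a, b) length(intersect(sig_sets[[a]], sig_sets[[b]])) > 0,
              pairs$protein1, pairs$protein2))
}

test_that("enrichment = 1 gives positives statistically like uniform pairs", {
  cfg <- synthetic_config(n_proteins = 300, n_go = 100, n_kegg = 20,
                          n_signal = 8, enrichment = 1, n_pos = 1500, seed = 5)
  sim <- generate_synthetic(cfg)
  f_pos <- shared_fraction(sim, sim$interactions)
  # direct resampling oracle: uniform random pairs from the same universe
  set.seed(99)
  ids <- names(sim$profiles)
  i <- sample(ids, 4000, replace = TRUE); j <- sample(ids, 4000, replace = TRUE)
  keep <- i != j
  unif <- data.frame(protein1 = i[keep], protein2 = j[keep])
  f_unif <- shared_fraction(sim, unif)
  # within binomial error of each other
  se <- sqrt(f_unif * (1 - f_unif) * (1 / nrow(sim$interactions) + 1 / nrow(unif)))
  expect_lt(abs(f_pos - f_unif), 4 * se)
})

test_that("strong enrichment makes positives share signal terms more often", {
  cfg <- synthetic_config(n_proteins = 500, n_go = 200, n_kegg = 30,
                          n_signal = 10, enrichment = 20, n_pos = 2000, seed = 1)
  sim <- generate_synthetic(cfg)
  f_pos <- shared_fraction(sim, sim$interactions)
  set.seed(42)
  ids <- names(sim$profiles)
  i <- sample(ids, 2500, replace = TRUE); j <- sample(ids, 2500, replace = TRUE)
  keep <- i != j
  f_unif <- shared_fraction(sim, data.frame(protein1 = i[keep],
                                            protein2 = j[keep])[1:2000, ])
  expect_gt(f_pos, f_unif)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(n_proteins = 4, n_go = 5, n_kegg = 0,
                                n_signal = 1, n_pos = 10, seed = 1),
               "n_pos")
  expect_error(synthetic_config(n_proteins = 10, n_go = 2, n_kegg = 1,
                                n_signal = 5, n_pos = 3, seed = 1))
})

test_that("recovery_rate counts terms with any derived feature in the top-n", {
  cfg <- synthetic_config(n_proteins = 20, n_go = 10, n_kegg = 2,
                          n_signal = 2, n_pos = 12, seed = 4)
  sim <- generate_synthetic(cfg)
  truth <- sim$truth
  # all signal features ranked first -> 1.0
  lst <- c(truth$signal_features, "sum:GO:zzz")
  expect_equal(recovery_rate(truth, lst, length(truth$signal_features)), 1.0)
  # a list with no signal-derived features -> 0.0
  expect_equal(recovery_rate(truth, c("sum:none1", "absdiff:none2"), 2), 0)
  # partial recovery is a plain fraction
  one_term <- truth$signal_terms[1]
  expect_equal(recovery_rate(truth, paste0("sum:", one_term), 5), 0.5)
  expect_error(recovery_rate(truth, character(), 3), "empty")
})

test_that("synthetic TSV outputs round-trip through the readers", {
  cfg <- synthetic_config(n_proteins = 40, n_go = 15, n_kegg = 5,
                          n_signal = 3, n_pos = 30, enrichment = 5, seed = 6)
  sim <- generate_synthetic(cfg)
  dir <- tempfile()
  paths <- write_synthetic_inputs(sim, dir)
  tab <- read_interactions(paths["interactions"], 0)
  expect_equal(nrow(tab), 30)
  ann <- read_annotations(paths["go"], paths["kegg"])
  expect_identical(ann$catalog$go_terms, sim$catalog$go_terms)
  expect_identical(ann$catalog$kegg_pathways, sim$catalog$kegg_pathways)
  # profiles agree (every synthetic protein is annotated by construction)
  expect_setequal(names(ann$profiles), names(sim$profiles))
  expect_equal(ann$profiles[["P00001"]]$go_set, sim$profiles[["P00001"]]$go_set)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(sort(truth$signal_terms), sim$truth$signal_terms)
})

test_that("signal_separation assigns worst rank to unlisted features", {
  cfg <- synthetic_config(n_proteins = 20, n_go = 4, n_kegg = 2,
                          n_signal = 2, n_pos = 10, seed = 9)
  sim <- generate_synthetic(cfg)
  desc <- feature_descriptors(sim$catalog)
  # put all signal features at the head of the list
  lst <- c(sim$truth$signal_features,
           setdiff(desc$name, sim$truth$signal_features)[1:2])
  sep <- signal_separation(sim$truth, lst, desc, n_perm = 500, seed = 1)
  expect_gt(sep$difference, 0)
  expect_lt(sep$p_value, 0.05)
  # empty list: every feature ties at the worst rank, no separation
  sep0 <- signal_separation(sim$truth, character(), desc, n_perm = 200, seed = 1)
  expect_equal(sep0$difference, 0)
  expect_gt(sep0$p_value, 0.5)
})
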