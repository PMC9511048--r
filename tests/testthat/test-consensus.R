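test_that("integration reproduces the worked importance-score examples", {
  # feature at rank r in all K lists -> M = r, W = 1, score = r
  K <- 4
  lists <- lapply(1:K, function(i) make_ranked(c(7L, 9L, 11L), dataset_id = i))
  cl <- integrate_ranked_lists(lists, K)
  expect_equal(cl$score[cl$feature_id == 7L], 1)
  expect_equal(cl$score[cl$feature_id == 9L], 2)
  expect_equal(cl$M[cl$feature_id == 11L], 3)
  expect_equal(cl$W[cl$feature_id == 11L], 1)

  # K = 4, feature at ranks 3 and 5 in two lists -> M = 4, W = 0.5, score = 8
  l1 <- make_ranked(c(1L, 2L, 42L), dataset_id = 1)        # rank 3
  l2 <- make_ranked(c(1L, 2L, 3L, 4L, 42L), dataset_id = 2) # rank 5
  l3 <- make_ranked(c(1L, 2L), dataset_id = 3)
  l4 <- make_ranked(c(1L, 3L), dataset_id = 4)
  cl2 <- integrate_ranked_lists(list(l1, l2, l3, l4), K = 4)
  rec <- cl2[cl2$feature_id == 42L, ]
  expect_equal(rec$N, 2L)
  expect_equal(rec$M, 4)
  expect_equal(rec$W, 0.5)
  expect_equal(rec$score, 8)

  # K = 310, feature at rank 1 in exactly one list -> M = 1, W = 1/310, score = 310
  solo <- make_ranked(5L, dataset_id = 1)
  cl3 <- integrate_ranked_lists(list(solo), K = 310)
  expect_equal(cl3$M, 1)
  expect_equal(cl3$W, 1 / 310)
  expect_equal(cl3$score, 310)
})

test_that("score identity and tie-breaking hold on random inputs", {
  set.seed(30)
  K <- 6
  lists <- lapply(1:K, function(i) {
    ids <- sort(sample(1:40, sample(10:25, 1)))
    make_ranked(sample(ids), dataset_id = i)
  })
  cl <- integrate_ranked_lists(lists, K)
  expect_equal(cl$score * cl$W, cl$M, tolerance = 1e-12)
  expect_true(all(cl$N >= 1 & cl$N <= K))
  expect_true(all(cl$M >= 1))
  expect_true(all(cl$W > 0 & cl$W <= 1))
  # sorted by score, ties by ascending feature id
  expect_true(all(diff(cl$score) >= 0))
  ties <- which(diff(cl$score) == 0)
  expect_true(all(cl$feature_id[ties] < cl$feature_id[ties + 1]))
  expect_equal(cl$rank, seq_len(nrow(cl)))
})

test_that("rank dominance implies score dominance", {
  set.seed(31)
  K <- 5
  lists <- lapply(1:K, function(i) make_ranked(sample(1:12), dataset_id = i))
  cl <- integrate_ranked_lists(lists, K)
  # brute-force dominance check over all feature pairs
  ranks <- sapply(1:12, function(f) sapply(lists, function(l) {
    r <- l$rank[l$feature_id == f]
    if (length(r)) r else NA_integer_
  }))
  for (a in 1:12) for (b in 1:12) {
    in_a <- !is.na(ranks[, a]); in_b <- !is.na(ranks[, b])
    shared <- in_a & in_b
    if (all(in_b <= in_a) && all(ranks[shared, a] <= ranks[shared, b])) {
      expect_lte(cl$score[cl$feature_id == a], cl$score[cl$feature_id == b])
    }
  }
})

test_that("integration rejects empty and mixed-algorithm input", {
  expect_error(integrate_ranked_lists(list()), "no ranked lists")
  l1 <- make_ranked(1:3, algorithm = "mrmr")
  l2 <- make_ranked(1:3, algorithm = "lasso")
  expect_error(integrate_ranked_lists(list(l1, l2)), "different algorithm")
})

test_that("top_features truncates or returns everything with a warning", {
  cl <- integrate_ranked_lists(list(make_ranked(c(4L, 2L, 9L, 1L, 6L))), K = 1)
  expect_equal(top_features(cl, 3), cl$name[1:3])
  expect_warning(all_of_them <- top_features(cl, 10), "only 5")
  expect_length(all_of_them, 5)
  expect_identical(top_features(cl, 3), top_features(cl, 3))
})

test_that("venn partition classifies multiplicities with source labels", {
  v <- venn_partition(list(A = c("f1", "f2"), B = c("f1", "f3"),
                           C = c("f1", "f2")))
  expect_equal(v$triple, "f1")
  expect_equal(v$double$feature, "f2")
  expect_equal(v$double$algorithms, "A,C")
  expect_equal(v$single$feature, "f3")
  expect_equal(v$single$algorithm, "B")
})

test_that("venn conservation holds for identical, disjoint and random sets", {
  s <- paste0("f", 1:100)
  v_same <- venn_partition(list(a = s, b = s, c = s))
  expect_equal(unname(v_same$counts), c(100L, 0L, 0L))
  v_disj <- venn_partition(list(a = paste0("a", 1:100), b = paste0("b", 1:100),
                                c = paste0("c", 1:100)))
  expect_equal(unname(v_disj$counts["single"]), 300L)
  set.seed(32)
  for (i in 1:20) {
    tops <- lapply(1:3, function(j) sample(paste0("f", 1:30), 15))
    names(tops) <- c("x", "y", "z")
    v <- venn_partition(tops)
    expect_equal(3 * length(v$triple) + 2 * nrow(v$double) + nrow(v$single),
                 sum(lengths(tops)))
  }
  expect_error(venn_partition(list(a = s, a = s, b = s)), "distinct")
  expect_error(venn_partition(list(a = s, b = s)), "three")
})

test_that("display names follow the published report style", {
  expect_equal(display_feature_name("sum:hsa04060"), "hsa04060_1 + hsa04060_2")
  expect_equal(display_feature_name("absdiff:GO:0031224"),
               "abs (GO:0031224_1-GO:0031224_2)")
})

test_that("render_report summarises channels, venn and filter counts", {
  u <- tiny_universe()
  desc <- feature_descriptors(u$catalog)
  tops <- list(lasso = c("sum:GO:0000001", "sum:hsa00010"),
               gbdt = c("sum:GO:0000001", "absdiff:GO:0000002"),
               mrmr = c("sum:GO:0000001"))
  venn <- venn_partition(tops)
  filt <- list(structure(list(dataset_id = 1L, selected = 1:3),
                         class = "filter_result"))
  rep <- render_report(tops, venn, desc, filt)
  expect_equal(rep$channel_counts$GO, c(1, 2, 1))
  expect_equal(rep$channel_counts$KEGG, c(1, 0, 0))
  expect_true("hsa00010_1 + hsa00010_2" %in% rep$venn_table$display_name ||
                "sum:hsa00010" %in% rep$venn_table$feature)
  expect_equal(rep$filter_counts$n_selected, 3L)
  # empty venn does not crash
  rep0 <- render_report(tops, NULL, desc, NULL)
  expect_equal(nrow(rep0$venn_table), 0)
})
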