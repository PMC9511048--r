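test_that("lasso ranks a label-identical column first", {
  set.seed(20)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y, matrix(rbinom(n * 5, 2, 0.3), n, 5))
  colnames(X) <- paste0("f", 1:6)
  rl <- lasso_rank(X, y, alpha = 0.001)
  expect_equal(rl$feature_id[1], 1L)
  expect_s3_class(rl, "ranked_list")
  expect_equal(rl$rank, 1:6)
})

test_that("lasso puts constant (zero-coefficient) columns in the id-ordered tail", {
  set.seed(21)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y, konst = rep(1, n), matrix(rbinom(n * 3, 2, 0.3), n, 3))
  colnames(X) <- c("sig", "konst", paste0("f", 1:3))
  rl <- lasso_rank(X, y, alpha = 0.001)
  expect_equal(rl$score[rl$feature_id == 2L], 0)
  zero_ids <- rl$feature_id[rl$score == 0]
  expect_equal(zero_ids, sort(zero_ids)) # ascending id within the zero tail
})

test_that("a duplicated informative column still beats pure noise under lasso", {
  set.seed(22)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y, y, matrix(rbinom(n * 4, 1, 0.5), n, 4))
  colnames(X) <- paste0("f", 1:6)
  rl <- lasso_rank(X, y, alpha = 0.001)
  ranks <- rl$rank[match(1:2, rl$feature_id)]
  noise_ranks <- rl$rank[match(3:6, rl$feature_id)]
  expect_true(all(ranks < min(noise_ranks) | rl$score[match(1:2, rl$feature_id)] >
                    max(rl$score[match(3:6, rl$feature_id)])))
})

test_that("gbdt ranks a label-identical column first with split counts", {
  set.seed(23)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y, matrix(rbinom(n * 5, 2, 0.3), n, 5))
  colnames(X) <- paste0("g", 1:6)
  rl <- gbdt_rank(X, y, n_trees = 30, seed = 4)
  expect_equal(rl$feature_id[1], 1L)
  expect_true(rl$score[1] >= max(rl$score[-1]))
  # determinism
  rl2 <- gbdt_rank(X, y, n_trees = 30, seed = 4)
  expect_identical(rl, rl2)
})

test_that("gbdt gives never-split features count zero in the id-ordered tail", {
  set.seed(24)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y, zero1 = rep(0, n), zero2 = rep(0, n))
  colnames(X) <- c("sig", "zero1", "zero2")
  rl <- gbdt_rank(X, y, n_trees = 10, seed = 2)
  expect_equal(rl$score[match(2:3, rl$feature_id)], c(0, 0))
  expect_equal(rl$feature_id[2:3], c(2L, 3L))
})

test_that("mutual information matches the entropy identity on known cases", {
  # independent fair coins: MI = 0
  x <- rep(c(0, 0, 1, 1), 25); y <- rep(c(0, 1, 0, 1), 25)
  expect_equal(mutual_information(x, y), 0, tolerance = 1e-12)
  # identical binary vectors: MI = H(X) = log 2 for a balanced vector
  z <- rep(c(0, 1), 50)
  expect_equal(mutual_information(z, z), log(2), tolerance = 1e-12)
})

test_that("mrmr picks the plain-MI maximiser first", {
  set.seed(25)
  n <- 60
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y, matrix(rbinom(n * 4, 2, 0.4), n, 4))
  colnames(X) <- paste0("m", 1:5)
  rl <- mrmr_rank(X, y)
  rel <- apply(X, 2, mutual_information, y = y)
  expect_equal(rl$feature_id[1], unname(which.max(rel)))
})

test_that("mrmr matches the brute-force greedy oracle on 50 random instances", {
  set.seed(26)
  for (i in 1:50) {
    p <- sample(3:6, 1)
    n <- sample(12:30, 1)
    X <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
    colnames(X) <- paste0("v", seq_len(p))
    y <- rbinom(n, 1, 0.5)
    rl <- mrmr_rank(X, y, top_k = p)
    expect_equal(rl$feature_id, mrmr_oracle(X, y),
                 info = paste("instance", i))
  }
})

test_that("a duplicate of a selected feature is deferred by redundancy", {
  set.seed(27)
  n <- 80
  f1 <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(f1, rbinom(n, 1, 0.15)))
  f2 <- as.integer(xor(y, rbinom(n, 1, 0.3))) # related to y, not a copy of f1
  X <- cbind(f1, dup = f1, f2)
  colnames(X) <- c("f1", "dup", "f2")
  rl <- mrmr_rank(X, y)
  expect_equal(rl$feature_id[1], 1L) # f1 most relevant, lowest id on tie
  # the duplicate (maximal redundancy) is not chosen while f2 remains
  expect_equal(rl$feature_id[2], 3L)
})

test_that("mrmr clamps an oversized top_k with a warning and appends a tail", {
  set.seed(28)
  X <- matrix(sample(0:2, 40, replace = TRUE), 10, 4)
  colnames(X) <- paste0("t", 1:4)
  y <- rbinom(10, 1, 0.5)
  expect_warning(rl <- mrmr_rank(X, y, top_k = 9), "clamped")
  expect_equal(rl$rank, 1:4)
  # explicit small top_k: tail is in ascending feature-id order with NA score
  rl2 <- mrmr_rank(X, y, top_k = 2)
  tail_ids <- rl2$feature_id[3:4]
  expect_equal(tail_ids, sort(tail_ids))
  expect_true(all(is.na(rl2$score[3:4])))
})

test_that("all three rankers are permutation-equivariant", {
  set.seed(29)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y * rbinom(n, 2, 0.8), matrix(rbinom(n * 5, 2, 0.35), n, 5))
  colnames(X) <- paste0("p", 1:6)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  Xp <- X[, perm]
  ids_p <- (1:6)[perm] # feature identity travels with its column
  for (fn in list(
    function(A, ids) lasso_rank(A, y, alpha = 0.001, feature_ids = ids),
    function(A, ids) gbdt_rank(A, y, n_trees = 20, seed = 9, feature_ids = ids),
    function(A, ids) mrmr_rank(A, y, feature_ids = ids))) {
    r_orig <- fn(X, 1:6)
    r_perm <- fn(Xp, ids_p)
    expect_equal(r_perm$feature_id, r_orig$feature_id)
  }
})

test_that("rank_dataset restricts rankers to the filter-selected columns", {
  u <- tiny_universe()
  pos <- interaction_table(c("A", "B"), c("B", "C"))
  neg <- data.frame(protein1 = c("A", "B"), protein2 = c("C", "D"), score = 0)
  ds <- build_datasets(pos, list(neg))[[1]]
  pfm <- encode_dataset(ds, u$profiles, u$catalog)
  filt <- structure(list(dataset_id = 1L, selected = c(1L, 3L, 5L)),
                    class = "filter_result")
  # four rows cannot support any split: the gbdt ranker takes its declared
  # degenerate path (all-tie list in feature-id order, with a warning)
  expect_warning(rks <- rank_dataset(pfm, filt, gbdt_trees = 5, seed = 2),
                 "no splits")
  expect_equal(rks$gbdt$feature_id, c(1L, 3L, 5L))
  expect_named(rks, c("lasso", "gbdt", "mrmr"))
  for (rl in rks) {
    expect_setequal(rl$feature_id, c(1L, 3L, 5L))
    expect_equal(rl$rank, 1:3)
    expect_true(all(rl$name %in% pfm$descriptors$name[c(1, 3, 5)]))
  }
  # empty selection yields no lists
  filt0 <- structure(list(dataset_id = 1L, selected = integer()),
                     class = "filter_result")
  expect_length(rank_dataset(pfm, filt0), 0)
})
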