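# A ranked list is a data.frame(rank, feature_id, name, score) with
# attributes `algorithm` and `dataset_id`. Rank 1 = most important; ranks are
# contiguous 1..L over exactly the features given to the ranker (the
# Boruta-selected set of one balanced dataset).
ranked_list <- function(order_idx, feature_ids, feat_names, scores,
                        algorithm, dataset_id) {
  stopifnot(!anyDuplicated(order_idx), length(order_idx) == length(feature_ids))
  df <- data.frame(rank = seq_along(order_idx),
                   feature_id = feature_ids[order_idx],
                   name = feat_names[order_idx],
                   score = scores[order_idx],
                   stringsAsFactors = FALSE)
  attr(df, "algorithm") <- algorithm
  attr(df, "dataset_id") <- dataset_id
  class(df) <- c("ranked_list", "data.frame")
  df
}

# descending score, ties (and the zero/unscored tail) by ascending feature id
order_by_score <- function(scores, feature_ids) {
  order(-scores, feature_ids)
}

#' Rank features by L1-penalised regression coefficients
#'
#' Fits the linear (regression-form) lasso of the 0/1 labels on standardized
#' features at a fixed penalty and ranks by descending absolute coefficient.
#' Zero-coefficient features are ranked after all non-zero ones, in ascending
#' feature-id order, so lists are deterministic.
#'
#' @param X numeric matrix (rows = pairs, columns = candidate features);
#'   sparse matrices are accepted.
#' @param y 0/1 labels.
#' @param alpha L1 penalty weight (glmnet lambda), > 0; default 0.01.
#' @param feature_ids global integer ids of the columns (default 1..ncol).
#' @param dataset_id stored in the result.
#' @return a `ranked_list` with `score` = |coefficient|.
#' @export
lasso_rank <- function(X, y, alpha = 0.01, feature_ids = seq_len(ncol(X)),
                       dataset_id = NA_integer_) {
  stopifnot(alpha > 0, ncol(X) >= 1)
  feat_names <- colnames(X) %||% paste0("f", feature_ids)
  if (ncol(X) == 1) {
    # ranking a single feature is trivial; report its least-squares slope
    b <- stats::coef(stats::lm(as.numeric(y) ~ as.numeric(X[, 1])))[2]
    return(ranked_list(1L, feature_ids, feat_names,
                       abs(unname(b)), "lasso", dataset_id))
  }
  fit <- NULL
  for (maxit in c(1e5, 1e6, 1e7)) {
    fit <- tryCatch(
      glmnet::glmnet(X, as.numeric(y), family = "gaussian", alpha = 1,
                     lambda = alpha, standardize = TRUE, maxit = maxit),
      warning = function(w) NULL, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("lasso did not converge")
  coefs <- abs(as.numeric(stats::coef(fit))[-1]) # drop intercept
  ord <- order_by_score(coefs, feature_ids)
  ranked_list(ord, feature_ids, feat_names, coefs, "lasso", dataset_id)
}

#' Rank features by gradient-boosted-tree split counts
#'
#' Fits a gradient-boosted decision-tree classifier and counts, per feature,
#' how many tree splits use it; features are ranked by descending split
#' count, ties broken by ascending feature id. A degenerate fit with no
#' splits yields an all-tie list in feature-id order with a warning.
#'
#' @param X numeric matrix of features (sparse accepted).
#' @param y 0/1 labels.
#' @param n_trees number of boosting rounds, >= 1 (default 100).
#' @param seed integer seed (single-threaded fit, reproducible).
#' @param feature_ids global integer ids of the columns.
#' @param dataset_id stored in the result.
#' @return a `ranked_list` with `score` = split count.
#' @export
gbdt_rank <- function(X, y, n_trees = 100, seed = 1L,
                      feature_ids = seq_len(ncol(X)),
                      dataset_id = NA_integer_) {
  stopifnot(n_trees >= 1, ncol(X) >= 1)
  feat_names <- colnames(X) %||% paste0("f", feature_ids)
  # the tree builder is not column-order invariant (equal-gain splits break
  # ties by internal column index), so fit in canonical feature-id order to
  # make the ranking a function of feature identity alone
  canon <- order(feature_ids)
  Xd <- as.matrix(X)[, canon, drop = FALSE]
  colnames(Xd) <- paste0("c", seq_len(ncol(Xd))) # positional, collision-safe
  fit <- xgboost::xgboost(x = Xd, y = factor(y), nrounds = n_trees,
                          nthreads = 1, verbosity = 0, seed = seed)
  tree_tab <- xgboost::xgb.model.dt.tree(model = fit)
  splits <- tree_tab$Feature[tree_tab$Feature != "Leaf"]
  counts_canon <- rep(0, ncol(Xd))
  if (length(splits)) {
    tb <- table(splits)
    counts_canon[match(names(tb), colnames(Xd))] <- as.numeric(tb)
  } else {
    warning("gradient boosting produced no splits; returning feature-id order")
  }
  counts <- numeric(ncol(Xd))
  counts[canon] <- counts_canon
  ord <- order_by_score(counts, feature_ids)
  ranked_list(ord, feature_ids, feat_names, counts, "gbdt", dataset_id)
}

#' Plug-in mutual information between two discrete vectors
#'
#' Empirical mutual information in natural-log units over the observed joint
#' distribution; suitable for the small \{0,1,2\} feature alphabet.
#'
#' @param x,y equal-length discrete vectors.
#' @return mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y) {
  n <- length(x)
  jt <- table(x, y) / n
  px <- rowSums(jt); py <- colSums(jt)
  nz <- jt > 0
  sum(jt[nz] * log(jt[nz] / outer(px, py)[nz]))
}

# MI of one discrete column s against every column of X (values in a small
# alphabet), vectorised with indicator cross-products
mi_against_all <- function(X, s) {
  n <- nrow(X)
  xl <- sort(unique(as.vector(X)))
  sl <- sort(unique(s))
  mi <- numeric(ncol(X))
  px <- matrix(0, length(xl), ncol(X))
  for (bi in seq_along(xl)) px[bi, ] <- colSums(X == xl[bi]) / n
  ps <- vapply(sl, function(a) mean(s == a), 0)
  for (ai in seq_along(sl)) {
    rows <- s == sl[ai]
    for (bi in seq_along(xl)) {
      pj <- colSums(X[rows, , drop = FALSE] == xl[bi]) / n
      ok <- pj > 0
      mi[ok] <- mi[ok] + pj[ok] * log(pj[ok] / (ps[ai] * px[bi, ok]))
    }
  }
  mi
}

#' Rank features by minimum-redundancy maximum-relevance (difference form)
#'
#' Greedy selection on discrete features: the first feature maximises the
#' mutual information I(f; y); each subsequent feature maximises
#' `I(f; y) - mean_{s in S} I(f; s)` over the already-selected set S. Ties
#' are broken by ascending feature id. Selection stops after `top_k`
#' features; any remaining features are appended as an unranked tail in
#' feature-id order (score NA).
#'
#' @param X matrix of discrete features (values in \{0,1,2\}).
#' @param y 0/1 labels.
#' @param top_k number of greedily ranked features (default: all, capped at
#'   500; a larger request is clamped with a warning).
#' @param feature_ids global integer ids of the columns.
#' @param dataset_id stored in the result.
#' @return a `ranked_list` with `score` = greedy criterion value at selection.
#' @export
mrmr_rank <- function(X, y, top_k = NULL, feature_ids = seq_len(ncol(X)),
                      dataset_id = NA_integer_) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(p >= 1)
  feat_names <- colnames(X) %||% paste0("f", feature_ids)
  cap <- 500L
  if (is.null(top_k)) top_k <- min(p, cap)
  if (top_k > p) {
    warning("top_k exceeds feature count; clamped to ", p)
    top_k <- p
  }
  top_k <- min(top_k, cap)
  relevance <- mi_against_all(X, y)
  selected <- integer(0)
  redundancy_sum <- numeric(p)
  scores <- rep(NA_real_, p)
  remaining <- seq_len(p)
  for (step in seq_len(top_k)) {
    crit <- if (length(selected) == 0) relevance[remaining] else
      relevance[remaining] - redundancy_sum[remaining] / length(selected)
    # criterion values that are mathematically equal can differ by ~1e-16
    # depending on summation order; resolve ties at a fixed tolerance so the
    # id tie-break, not floating-point noise, decides
    best <- remaining[order(-round(crit, 12), feature_ids[remaining])[1]]
    scores[best] <- if (length(selected) == 0) relevance[best] else
      relevance[best] - redundancy_sum[best] / length(selected)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) == 0) break
    redundancy_sum[remaining] <- redundancy_sum[remaining] +
      mi_against_all(X[, remaining, drop = FALSE], X[, best])
  }
  tail_feats <- remaining[order(feature_ids[remaining])]
  ord <- c(selected, tail_feats)
  ranked_list(ord, feature_ids, feat_names, scores, "mrmr", dataset_id)
}

#' Run the configured rankers on one balanced dataset's selected features
#'
#' Convenience wrapper: subsets the encoded matrix to the filter-selected
#' columns and produces one `ranked_list` per algorithm, with feature ids in
#' the global (catalog) indexing.
#'
#' @param pfm a `pair_feature_matrix`.
#' @param filter a `filter_result` for the same dataset.
#' @param algorithms subset of `c("lasso", "gbdt", "mrmr")`.
#' @param lasso_alpha,gbdt_trees,mrmr_top_k algorithm parameters.
#' @param seed integer seed (used by the boosted-tree fit).
#' @return named list of `ranked_list` objects.
#' @export
rank_dataset <- function(pfm, filter, algorithms = c("lasso", "gbdt", "mrmr"),
                         lasso_alpha = 0.01, gbdt_trees = 100,
                         mrmr_top_k = NULL, seed = 1L) {
  stopifnot(all(algorithms %in% c("lasso", "gbdt", "mrmr")))
  ids <- filter$selected
  if (length(ids) == 0) return(stats::setNames(list(), character()))
  Xs <- pfm$X[, ids, drop = FALSE]
  y <- pfm$labels
  out <- list()
  if ("lasso" %in% algorithms) {
    out$lasso <- lasso_rank(Xs, y, alpha = lasso_alpha, feature_ids = ids,
                            dataset_id = filter$dataset_id)
  }
  if ("gbdt" %in% algorithms) {
    out$gbdt <- gbdt_rank(Xs, y, n_trees = gbdt_trees,
                          seed = derive_seed(seed, "gbdt", filter$dataset_id),
                          feature_ids = ids, dataset_id = filter$dataset_id)
  }
  if ("mrmr" %in% algorithms) {
    out$mrmr <- mrmr_rank(Xs, y, top_k = mrmr_top_k, feature_ids = ids,
                          dataset_id = filter$dataset_id)
  }
  out
}
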