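#' Shadow-feature (Boruta-style) relevance filtering
#'
#' Implements the all-relevant wrapper: at each iteration every remaining
#' column is copied and row-shuffled ("shadow" features), the shadows are
#' stitched to the actual matrix, a random forest is fitted, and every actual
#' feature whose impurity importance exceeds the maximum shadow importance
#' scores a hit. Hit counts are compared against the 0.5-binomial expectation
#' with a two-sided test (each tail at `alpha/2`) and Bonferroni correction
#' over the original feature count: features significantly above are
#' accepted, significantly below rejected. Rejected features are removed from
#' subsequent iterations and the loop stops early once no feature is
#' undecided. Features still undecided at `max_iter` are handled by
#' `tentative`: `"reject"` (conservative default) or `"median"` (accept those
#' whose median importance over their iterations beats the median of the
#' max-shadow importances).
#'
#' @param x a `pair_feature_matrix` from [encode_dataset()], or a numeric
#'   matrix (then `y` is required).
#' @param y labels (two classes) when `x` is a bare matrix.
#' @param max_iter maximum number of shadow iterations (default 100).
#' @param alpha significance level of the binomial decision test.
#' @param num_trees trees per random forest (default 100).
#' @param tentative `"reject"` or `"median"`.
#' @param seed integer seed; shadow shuffles and forests draw from named
#'   per-iteration streams, so the result is reproducible.
#' @param dataset_id optional id stored in the result.
#' @return a `filter_result`: list with `dataset_id`, `selected` (sorted
#'   integer feature ids, i.e. column indices of `x`), `selected_names`,
#'   `n_iterations`, `tentative` (ids undecided at stop), and `log` (one row
#'   per iteration: active/accepted/rejected counts and the shadow maximum).
#' @export
boruta_filter <- function(x, y = NULL, max_iter = 100, alpha = 0.05,
                          num_trees = 100, tentative = c("reject", "median"),
                          seed = 1L, dataset_id = NA_integer_) {
  tentative <- match.arg(tentative)
  if (inherits(x, "pair_feature_matrix")) {
    y <- x$labels
    x <- x$X
  }
  if (is.null(y)) stop("labels y are required")
  if (length(unique(y)) < 2) stop("labels must contain two classes")
  stopifnot(max_iter >= 1)
  X <- as.matrix(x)
  p <- ncol(X)
  feat_names <- colnames(X) %||% paste0("f", seq_len(p))
  yf <- factor(y)

  is_const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  if (all(is_const)) {
    warning("all features are constant; empty selection")
    return(structure(list(dataset_id = dataset_id, selected = integer(),
                          selected_names = character(), n_iterations = 0L,
                          tentative = integer(),
                          log = data.frame(iter = integer(), n_active = integer(),
                                           n_accepted = integer(),
                                           n_rejected = integer(),
                                           max_shadow = numeric())),
                     class = "filter_result"))
  }

  status <- rep("undecided", p) # undecided / accepted / rejected
  hits <- integer(p)
  iters <- integer(p) # iterations each feature has participated in
  imp_hist <- vector("list", p) # importance history (median tentative policy)
  shadow_max_hist <- numeric(0)
  log <- vector("list", max_iter)
  thr <- alpha / 2 / p # per-tail Bonferroni threshold

  for (it in seq_len(max_iter)) {
    active <- which(status != "rejected")
    Xa <- X[, active, drop = FALSE]
    set.seed(derive_seed(seed, "shadow", it))
    Xs <- apply(Xa, 2, sample)
    Xfull <- cbind(Xa, Xs)
    colnames(Xfull) <- c(paste0("a", seq_along(active)),
                         paste0("s", seq_along(active)))
    fit <- ranger::ranger(x = Xfull, y = yf, num.trees = num_trees,
                          importance = "impurity", num.threads = 1,
                          seed = derive_seed(seed, "forest", it))
    imp <- fit$variable.importance
    imp_actual <- imp[seq_along(active)]
    max_shadow <- max(imp[length(active) + seq_along(active)])
    shadow_max_hist <- c(shadow_max_hist, max_shadow)
    und <- status[active] == "undecided"
    upd <- active[und]
    hits[upd] <- hits[upd] + (imp_actual[und] > max_shadow)
    iters[upd] <- iters[upd] + 1L
    for (kk in seq_along(upd)) {
      imp_hist[[upd[kk]]] <- c(imp_hist[[upd[kk]]], imp_actual[und][kk])
    }
    # binomial decisions on undecided features
    k <- iters[upd]; h <- hits[upd]
    p_acc <- stats::pbinom(h - 1, k, 0.5, lower.tail = FALSE)
    p_rej <- stats::pbinom(h, k, 0.5)
    status[upd[p_acc <= thr]] <- "accepted"
    status[upd[p_rej <= thr]] <- "rejected"
    log[[it]] <- data.frame(iter = it, n_active = length(active),
                            n_accepted = sum(status == "accepted"),
                            n_rejected = sum(status == "rejected"),
                            max_shadow = max_shadow)
    if (!any(status == "undecided")) break
  }
  n_it <- it
  tent <- which(status == "undecided")
  if (length(tent) && tentative == "median") {
    med_shadow <- stats::median(shadow_max_hist)
    promote <- tent[vapply(imp_hist[tent],
                           function(h) stats::median(h) > med_shadow, FALSE)]
    status[promote] <- "accepted"
  }
  selected <- which(status == "accepted")
  structure(list(dataset_id = dataset_id,
                 selected = selected,
                 selected_names = feat_names[selected],
                 n_iterations = n_it,
                 tentative = tent,
                 log = do.call(rbind, log[seq_len(n_it)])),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("filter_result (dataset ", x$dataset_id, "): ", length(x$selected),
      " features selected in ", x$n_iterations, " iterations (",
      length(x$tentative), " tentative)\n", sep = "")
  invisible(x)
}

#' Union of per-dataset feature selections
#'
#' Combines the selected-feature sets of several balanced datasets into one
#' union, with the number of datasets selecting each feature (which feeds the
#' W(f) bookkeeping of the consensus stage).
#'
#' @param results list of `filter_result` objects.
#' @return list with `features` (sorted integer ids of the union) and
#'   `counts` (named integer vector: datasets selecting each feature).
#' @export
union_selected <- function(results) {
  if (length(results) < 1) stop("need at least one filter result")
  all_ids <- unlist(lapply(results, `[[`, "selected"))
  feats <- sort(unique(all_ids))
  counts <- vapply(feats, function(f) sum(vapply(results, function(r)
    f %in% r$selected, FALSE)), 0L)
  names(counts) <- as.character(feats)
  list(features = feats, counts = counts)
}
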