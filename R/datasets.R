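#' Number of unordered protein pairs
#'
#' `C(n, 2) = n(n-1)/2`: unordered pairs, no self-pairs. At the scale of the
#' human STRING-derived universe (6,623 proteins) this is 21,928,753.
#'
#' @param n_proteins number of proteins, at least 2.
#' @return the pair count as a double (exact for any realistic n).
#' @export
count_all_pairs <- function(n_proteins) {
  if (length(n_proteins) != 1 || is.na(n_proteins) || n_proteins < 2) {
    stop("n_proteins must be a single integer >= 2")
  }
  n <- as.double(n_proteins)
  n * (n - 1) / 2
}

# enumerate all C(n,2) unordered pairs of `proteins` as a 2-column matrix of
# canonicalised ids; guarded so it is only used at desk scale.
enumerate_all_pairs <- function(proteins, max_pairs = 5e6) {
  n <- length(proteins)
  total <- count_all_pairs(n)
  if (total > max_pairs) {
    stop("refusing to enumerate ", format(total, big.mark = ","),
         " pairs; request a sampled count instead")
  }
  idx <- utils::combn(n, 2)
  a <- proteins[idx[1, ]]; b <- proteins[idx[2, ]]
  cbind(pmin(a, b), pmax(a, b))
}

#' Sample negative protein pairs
#'
#' A negative sample is any unordered, non-self pair of the protein universe
#' that is not in the positive set. `count = "all"` enumerates the complement
#' exactly (desk scale only); a numeric `count` draws a uniform sample
#' without replacement. For large universes the sample is drawn by rejection
#' against a hash set of positives, so the complement is never materialised.
#'
#' @param proteins character vector of protein ids (the universe).
#' @param positives an [interaction_table()] (or data.frame with `protein1`,
#'   `protein2`) of positive pairs.
#' @param count number of negatives to draw, or `"all"`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return an `interaction_table`-shaped data.frame of negative pairs
#'   (score 0).
#' @export
sample_negatives <- function(proteins, positives, count = "all", seed = 1L) {
  proteins <- unique(as.character(proteins))
  n <- length(proteins)
  if (n < 2) stop("need at least 2 proteins")
  pos_keys <- pair_keys(positives$protein1, positives$protein2)
  total <- count_all_pairs(n)
  max_neg <- total - length(unique(pos_keys))
  if (identical(count, "all")) {
    all_pairs <- enumerate_all_pairs(proteins)
    keys <- pair_keys(all_pairs[, 1], all_pairs[, 2])
    neg <- all_pairs[!(keys %in% pos_keys), , drop = FALSE]
    out <- data.frame(protein1 = neg[, 1], protein2 = neg[, 2],
                      score = 0, stringsAsFactors = FALSE)
    class(out) <- c("interaction_table", "data.frame")
    return(out)
  }
  count <- as.double(count)
  if (count > max_neg) {
    stop("requested ", format(count, big.mark = ","),
         " negatives but only ", format(max_neg, big.mark = ","),
         " non-positive pairs exist")
  }
  set.seed(seed)
  if (total <= 5e6) {
    # exact: enumerate the complement and sample from it
    all_neg <- sample_negatives(proteins, positives, "all", seed)
    pick <- sample.int(nrow(all_neg), count)
    out <- all_neg[sort(pick), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("interaction_table", "data.frame")
    return(out)
  }
  # rejection sampling against the positive hash set
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in pos_keys) assign(k, TRUE, envir = seen)
  got_a <- character(0); got_b <- character(0)
  need <- count
  while (need > 0) {
    m <- max(1000L, ceiling(need * 1.3))
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n, m, replace = TRUE)
    ok <- i != j
    a <- pmin(proteins[i[ok]], proteins[j[ok]])
    b <- pmax(proteins[i[ok]], proteins[j[ok]])
    keys <- paste(a, b, sep = "\r")
    fresh <- !duplicated(keys) & !vapply(keys, exists, FALSE, envir = seen)
    a <- a[fresh]; b <- b[fresh]; keys <- keys[fresh]
    take <- seq_len(min(length(keys), need))
    for (k in keys[take]) assign(k, TRUE, envir = seen)
    got_a <- c(got_a, a[take]); got_b <- c(got_b, b[take])
    need <- count - length(got_a)
  }
  out <- data.frame(protein1 = got_a, protein2 = got_b, score = 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Number of balanced subsets
#'
#' The negative pool is split into `K = max(1, floor(n_negatives /
#' n_positives))` subsets so that each subset is approximately the size of
#' the positive set. At the paper-scale human data (21,858,361 negatives,
#' 70,392 positives) this gives 310.
#'
#' @param n_negatives,n_positives pool sizes, both positive.
#' @return integer K.
#' @export
num_subsets <- function(n_negatives, n_positives) {
  if (n_positives <= 0) stop("number of positives must be positive")
  if (n_negatives <= 0) stop("number of negatives must be positive")
  max(1, floor(n_negatives / n_positives))
}

#' Randomly and equally partition negatives into K subsets
#'
#' Shuffles the pool, then deals pairs round-robin into K subsets, so subset
#' sizes differ by at most one (the remainder goes to the first subsets).
#' Deterministic given the seed.
#'
#' @param negatives data.frame of negative pairs.
#' @param K number of subsets, `1 <= K <= nrow(negatives)`.
#' @param seed integer seed.
#' @return list of K data.frames whose concatenation is a permutation of the
#'   pool.
#' @export
partition_negatives <- function(negatives, K, seed = 1L) {
  P <- nrow(negatives)
  if (K < 1) stop("K must be >= 1")
  if (K > P) stop("K (", K, ") exceeds the number of negatives (", P, ")")
  set.seed(seed)
  ord <- sample.int(P)
  assign_to <- ((seq_len(P) - 1L) %% K) + 1L
  lapply(seq_len(K), function(k) {
    out <- negatives[ord[assign_to == k], , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Combine positives with each negative subset into balanced datasets
#'
#' Each balanced dataset carries the full positive set (label 1) plus one
#' negative subset (label 0); subsets are pairwise disjoint and disjoint from
#' the positives, which is verified.
#'
#' @param positives an [interaction_table()] of positive pairs.
#' @param negative_subsets list of data.frames from [partition_negatives()].
#' @return list of `balanced_dataset` objects with fields `dataset_id`,
#'   `positives`, `negatives`.
#' @export
build_datasets <- function(positives, negative_subsets) {
  pos_keys <- pair_keys(positives$protein1, positives$protein2)
  all_neg_keys <- unlist(lapply(negative_subsets, function(s)
    pair_keys(s$protein1, s$protein2)))
  if (anyDuplicated(all_neg_keys)) stop("negative subsets overlap each other")
  if (any(all_neg_keys %in% pos_keys)) stop("negative subsets overlap the positive set")
  lapply(seq_along(negative_subsets), function(k) {
    structure(list(dataset_id = k,
                   positives = positives,
                   negatives = negative_subsets[[k]]),
              class = "balanced_dataset")
  })
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat("balanced_dataset #", x$dataset_id, ": ", nrow(x$positives),
      " positives, ", nrow(x$negatives), " negatives\n", sep = "")
  invisible(x)
}
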