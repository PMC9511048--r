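#' Integrate one algorithm's per-dataset ranked lists
#'
#' Every feature appearing in at least one list receives:
#' `N(f)` — the number of lists containing it; `M(f)` — the mean of its ranks
#' over those lists (absent lists contribute rank 0 to the sum and are
#' excluded by dividing by `N(f)`); `W(f) = N(f)/K` — the fraction of the K
#' datasets whose filtering retained it; and the importance score
#' `M(f) / W(f)`. Smaller scores are more important: a feature consistently
#' near the top of many lists scores low, a feature that happened to rank
#' well in one dataset only is penalised by the `1/W(f)` factor. Records are
#' sorted by ascending score, ties by ascending feature id. A feature absent
#' from every list has undefined score (W = 0) and is excluded.
#'
#' @param lists list of `ranked_list` objects sharing one algorithm tag.
#' @param K total number of datasets (defaults to `length(lists)`).
#' @return a `consensus_list`: data.frame with columns `feature_id`, `name`,
#'   `N`, `M`, `W`, `score`, `rank` (1 = most important), plus attribute
#'   `algorithm`.
#' @export
integrate_ranked_lists <- function(lists, K = length(lists)) {
  if (length(lists) == 0) stop("no ranked lists to integrate")
  algs <- unique(vapply(lists, function(l) attr(l, "algorithm") %||% NA_character_,
                        ""))
  if (length(algs) > 1) stop("ranked lists carry different algorithm tags")
  stopifnot(K >= length(lists))
  all <- do.call(rbind, lapply(lists, function(l)
    data.frame(feature_id = l$feature_id, name = l$name, rank = l$rank,
               stringsAsFactors = FALSE)))
  agg <- stats::aggregate(rank ~ feature_id + name, data = all,
                          FUN = function(r) c(N = length(r), sum = sum(r)))
  N <- agg$rank[, "N"]
  M <- agg$rank[, "sum"] / N
  W <- N / K
  score <- M / W
  out <- data.frame(feature_id = agg$feature_id, name = agg$name,
                    N = as.integer(N), M = M, W = W, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$score, out$feature_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "algorithm") <- algs
  class(out) <- c("consensus_list", "data.frame")
  out
}

#' Top-N features of an integrated list
#'
#' @param consensus a `consensus_list` from [integrate_ranked_lists()].
#' @param n how many leading features to keep (default 100). If fewer exist,
#'   all are returned with a warning.
#' @return character vector of feature names in consensus order.
#' @export
top_features <- function(consensus, n = 100) {
  stopifnot(n >= 1)
  if (n > nrow(consensus)) {
    warning("requested top ", n, " but the integrated list has only ",
            nrow(consensus), " features")
    n <- nrow(consensus)
  }
  consensus$name[seq_len(n)]
}

#' Venn partition of three top-N feature sets
#'
#' Classifies every feature occurring in any of the three per-algorithm
#' top-N sets by how many sets contain it: `triple` (all three), `double`
#' (exactly two, annotated with the pair), `single` (exactly one, annotated
#' with the algorithm). The classes are pairwise disjoint and satisfy
#' `3|triple| + 2|double| + |single| = sum of the set sizes`.
#'
#' @param tops named list of exactly three character vectors (names = the
#'   algorithm labels; duplicates are an error).
#' @return a `venn_partition`: list with `triple` (character vector),
#'   `double` (data.frame feature/algorithms), `single` (data.frame
#'   feature/algorithm) and `counts`.
#' @export
venn_partition <- function(tops) {
  if (length(tops) != 3) stop("exactly three labeled feature sets are required")
  if (is.null(names(tops)) || anyDuplicated(names(tops)) || any(!nzchar(names(tops)))) {
    stop("the three sets must carry distinct algorithm labels")
  }
  tops <- lapply(tops, unique)
  univ <- sort(unique(unlist(tops)))
  member <- vapply(tops, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, names(tops)))
  mult <- rowSums(member)
  in_sets <- apply(member, 1, function(r) paste(names(tops)[r], collapse = ","))
  triple <- univ[mult == 3]
  double <- data.frame(feature = univ[mult == 2],
                       algorithms = in_sets[mult == 2],
                       stringsAsFactors = FALSE)
  single <- data.frame(feature = univ[mult == 1],
                       algorithm = in_sets[mult == 1],
                       stringsAsFactors = FALSE)
  structure(list(triple = triple, double = double, single = single,
                 counts = c(triple = length(triple), double = nrow(double),
                            single = nrow(single))),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition: ", x$counts["triple"], " in all three, ",
      x$counts["double"], " in exactly two, ", x$counts["single"],
      " in one\n", sep = "")
  invisible(x)
}

# flat membership table of a venn partition (used by write_outputs)
venn_table <- function(venn) {
  rows <- list(
    if (length(venn$triple)) data.frame(feature = venn$triple,
                                        n_algorithms = 3L,
                                        algorithms = "all",
                                        stringsAsFactors = FALSE),
    if (nrow(venn$double)) data.frame(feature = venn$double$feature,
                                      n_algorithms = 2L,
                                      algorithms = venn$double$algorithms,
                                      stringsAsFactors = FALSE),
    if (nrow(venn$single)) data.frame(feature = venn$single$feature,
                                      n_algorithms = 1L,
                                      algorithms = venn$single$algorithm,
                                      stringsAsFactors = FALSE))
  rows <- rows[!vapply(rows, is.null, FALSE)]
  if (!length(rows)) {
    return(data.frame(feature = character(), n_algorithms = integer(),
                      algorithms = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(-out$n_algorithms, out$feature), , drop = FALSE]
}

#' Display name of a feature machine name
#'
#' `sum:hsa04060` becomes `"hsa04060_1 + hsa04060_2"`;
#' `absdiff:GO:0031224` becomes `"abs (GO:0031224_1-GO:0031224_2)"`.
#'
#' @param name character vector of machine names.
#' @return character vector of display names.
#' @export
display_feature_name <- function(name) {
  comb <- sub(":.*$", "", name)
  term <- sub("^(sum|absdiff):", "", name)
  ifelse(comb == "sum",
         paste0(term, "_1 + ", term, "_2"),
         paste0("abs (", term, "_1-", term, "_2)"))
}

#' Summary report tables for a finished run
#'
#' Produces (a) per-algorithm GO-vs-KEGG counts among the top-N features,
#' (b) the Venn membership table with display names, and (c) the per-dataset
#' selected-feature counts from the filtering stage (violin-plot data).
#'
#' @param tops named list of per-algorithm top-N feature-name vectors.
#' @param venn a `venn_partition` (or NULL).
#' @param descriptors feature descriptor table ([feature_descriptors()]).
#' @param filter_results list of `filter_result` objects (optional).
#' @return list of data.frames: `channel_counts`, `venn_table`,
#'   `filter_counts`.
#' @export
render_report <- function(tops, venn = NULL, descriptors,
                          filter_results = NULL) {
  channel_of <- function(names) descriptors$channel[match(names, descriptors$name)]
  channel_counts <- do.call(rbind, lapply(names(tops), function(alg) {
    ch <- channel_of(tops[[alg]])
    data.frame(algorithm = alg,
               GO = sum(ch == "GO", na.rm = TRUE),
               KEGG = sum(ch == "KEGG", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })) %||% data.frame(algorithm = character(), GO = integer(), KEGG = integer())
  vt <- if (!is.null(venn)) venn_table(venn) else
    data.frame(feature = character(), n_algorithms = integer(),
               algorithms = character(), stringsAsFactors = FALSE)
  if (nrow(vt)) vt$display_name <- display_feature_name(vt$feature)
  fc <- if (!is.null(filter_results)) {
    data.frame(dataset_id = vapply(filter_results, `[[`, 0L, "dataset_id"),
               n_selected = vapply(filter_results,
                                   function(r) length(r$selected), 0L))
  } else data.frame(dataset_id = integer(), n_selected = integer())
  list(channel_counts = channel_counts, venn_table = vt, filter_counts = fc)
}
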