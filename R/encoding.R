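#' Feature descriptors for a catalog
#'
#' Every protein pair is encoded by two channels per annotation term: the sum
#' `g1 + g2` (ternary: 0/1/2) and the absolute difference `|g1 - g2|`
#' (binary). The descriptor table fixes the global feature indexing: the GO
#' block first (catalog order; per term, sum before absdiff), then the KEGG
#' block likewise — `2(n + m)` features in total. Machine names are
#' `sum:<term>` / `absdiff:<term>`; display names follow the conventional
#' report style (`"<term>_1 + <term>_2"`, `"abs (<term>_1-<term>_2)"`).
#'
#' @param catalog an [annotation_catalog()].
#' @return data.frame with columns `feature_id`, `term_id`, `channel`
#'   (`"GO"`/`"KEGG"`), `combinator` (`"sum"`/`"absdiff"`), `name`,
#'   `display_name`.
#' @export
feature_descriptors <- function(catalog) {
  terms <- c(catalog$go_terms, catalog$kegg_pathways)
  channel <- rep(c("GO", "KEGG"),
                 c(length(catalog$go_terms), length(catalog$kegg_pathways)))
  term_id <- rep(terms, each = 2)
  chan <- rep(channel, each = 2)
  comb <- rep(c("sum", "absdiff"), times = length(terms))
  data.frame(
    feature_id = seq_along(term_id),
    term_id = term_id,
    channel = chan,
    combinator = comb,
    name = paste0(comb, ":", term_id),
    display_name = ifelse(comb == "sum",
                          paste0(term_id, "_1 + ", term_id, "_2"),
                          paste0("abs (", term_id, "_1-", term_id, "_2)")),
    stringsAsFactors = FALSE
  )
}

#' Encode one protein as binary annotation vectors
#'
#' @param profile a [protein_profile()].
#' @param catalog an [annotation_catalog()].
#' @return list with `v_go` (length n, 0/1) and `v_kegg` (length m, 0/1).
#' @export
encode_protein <- function(profile, catalog) {
  n <- length(catalog$go_terms); m <- length(catalog$kegg_pathways)
  if (length(profile$go_set) && max(profile$go_set) > n ||
      length(profile$kegg_set) && max(profile$kegg_set) > m) {
    stop("annotation index out of range for protein '", profile$protein_id, "'")
  }
  v_go <- integer(n); v_go[profile$go_set] <- 1L
  v_kegg <- integer(m); v_kegg[profile$kegg_set] <- 1L
  list(v_go = v_go, v_kegg = v_kegg)
}

#' Order-invariant encoding of a protein pair
#'
#' For each term i the pair contributes the channel pair
#' `(g_i(p1) + g_i(p2), |g_i(p1) - g_i(p2)|)`; GO channels come first, then
#' KEGG, interleaved sum/absdiff per term. Swapping the two proteins leaves
#' the vector unchanged.
#'
#' @param p1,p2 [protein_profile()] objects.
#' @param catalog an [annotation_catalog()].
#' @return named integer vector of length `2(n + m)`.
#' @export
encode_pair <- function(p1, p2, catalog) {
  e1 <- encode_protein(p1, catalog); e2 <- encode_protein(p2, catalog)
  a <- c(e1$v_go, e1$v_kegg); b <- c(e2$v_go, e2$v_kegg)
  v <- as.integer(rbind(a + b, abs(a - b)))
  names(v) <- feature_descriptors(catalog)$name
  v
}

# sparse protein x (n+m) binary annotation matrix over the given profiles
profiles_to_matrix <- function(profiles, catalog) {
  n <- length(catalog$go_terms); m <- length(catalog$kegg_pathways)
  i <- rep(seq_along(profiles),
           vapply(profiles, function(p) length(p$go_set) + length(p$kegg_set), 0L))
  j <- unlist(lapply(profiles, function(p) c(p$go_set, p$kegg_set + n)))
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(length(profiles), n + m),
                       dimnames = list(names(profiles), NULL))
}

#' Encode a balanced dataset as a sparse pair-feature matrix
#'
#' Rows are the dataset's positive pairs in input order followed by its
#' negative pairs in input order; columns are the `2(n + m)` features of
#' [feature_descriptors()]. Values are small integers: sum channels in
#' \{0,1,2\}, absdiff channels in \{0,1\}, and per term the pair
#' `(sum, absdiff)` is always one of (0,0), (1,1), (2,0).
#'
#' @param ds a `balanced_dataset` from [build_datasets()].
#' @param profiles named list of [protein_profile()] objects covering every
#'   endpoint.
#' @param catalog an [annotation_catalog()].
#' @return a `pair_feature_matrix`: list with `X` (sparse dgCMatrix), `labels`
#'   (1 positive / 0 negative), `pairs` (data.frame), `descriptors`.
#' @export
encode_dataset <- function(ds, profiles, catalog) {
  pairs <- rbind(ds$positives[, c("protein1", "protein2")],
                 ds$negatives[, c("protein1", "protein2")])
  labels <- c(rep(1L, nrow(ds$positives)), rep(0L, nrow(ds$negatives)))
  missing <- setdiff(unique(c(pairs$protein1, pairs$protein2)), names(profiles))
  if (length(missing)) {
    stop("no annotation profile for protein '", missing[1], "'",
         if (length(missing) > 1) paste0(" (and ", length(missing) - 1, " more)"))
  }
  A <- profiles_to_matrix(profiles, catalog)
  i1 <- match(pairs$protein1, names(profiles))
  i2 <- match(pairs$protein2, names(profiles))
  S <- A[i1, , drop = FALSE] + A[i2, , drop = FALSE]
  D <- abs(A[i1, , drop = FALSE] - A[i2, , drop = FALSE])
  nt <- ncol(A)
  perm <- as.integer(rbind(seq_len(nt), nt + seq_len(nt)))
  X <- methods::as(cbind(S, D)[, perm, drop = FALSE], "CsparseMatrix")
  desc <- feature_descriptors(catalog)
  dimnames(X) <- list(NULL, desc$name)
  structure(list(X = X, labels = labels, pairs = pairs, descriptors = desc),
            class = "pair_feature_matrix")
}

#' @export
print.pair_feature_matrix <- function(x, ...) {
  cat("pair_feature_matrix: ", nrow(x$X), " pairs x ", ncol(x$X),
      " features (", sum(x$labels), " positive)\n", sep = "")
  invisible(x)
}

#' Export a pair-feature matrix in MatrixMarket format
#'
#' Writes `matrix.mtx` plus sidecar TSVs for the row pairs (with labels) and
#' the column descriptors.
#'
#' @param pfm a `pair_feature_matrix`.
#' @param dir output directory, created if missing.
#' @return character vector of written paths.
#' @export
export_mtx <- function(pfm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(pfm$X, mtx)
  rows <- file.path(dir, "rows.tsv")
  utils::write.table(cbind(pfm$pairs, label = pfm$labels), rows,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cols <- file.path(dir, "columns.tsv")
  utils::write.table(pfm$descriptors, cols, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(mtx, rows, cols)
}
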