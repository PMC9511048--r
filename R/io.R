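#' Annotation catalog: the ordered GO and KEGG term universes
#'
#' The catalog fixes the index of every GO term and KEGG pathway for the
#' lifetime of a run; all protein vectors and pair feature matrices share this
#' indexing. Identifiers are unique within each channel and the two channels
#' are disjoint.
#'
#' @param go_terms character vector of GO term identifiers (may be empty).
#' @param kegg_pathways character vector of KEGG pathway identifiers.
#' @return an `annotation_catalog` object with fields `go_terms` and
#'   `kegg_pathways`.
#' @export
annotation_catalog <- function(go_terms = character(), kegg_pathways = character()) {
  go_terms <- as.character(go_terms)
  kegg_pathways <- as.character(kegg_pathways)
  if (anyDuplicated(go_terms)) stop("duplicate GO term identifiers in catalog")
  if (anyDuplicated(kegg_pathways)) stop("duplicate KEGG pathway identifiers in catalog")
  both <- intersect(go_terms, kegg_pathways)
  if (length(both) > 0) {
    stop("term identifiers present in both GO and KEGG channels: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  if (length(go_terms) + length(kegg_pathways) < 1) {
    stop("catalog must contain at least one annotation term")
  }
  structure(list(go_terms = go_terms, kegg_pathways = kegg_pathways),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("annotation_catalog:", length(x$go_terms), "GO terms,",
      length(x$kegg_pathways), "KEGG pathways\n")
  invisible(x)
}

#' Protein annotation profile
#'
#' A protein's binary annotation vectors stored as sparse index sets into the
#' catalog. A protein annotated by neither channel is invalid: such proteins
#' carry no usable functional information and are discarded upstream.
#'
#' @param protein_id protein identifier.
#' @param go_set integer indices into `catalog$go_terms`.
#' @param kegg_set integer indices into `catalog$kegg_pathways`.
#' @param catalog an [annotation_catalog()] used for bounds checking.
#' @return a `protein_profile` object.
#' @export
protein_profile <- function(protein_id, go_set = integer(), kegg_set = integer(),
                            catalog) {
  go_set <- sort(unique(as.integer(go_set)))
  kegg_set <- sort(unique(as.integer(kegg_set)))
  if (length(go_set) + length(kegg_set) == 0) {
    stop("protein '", protein_id, "' has no GO or KEGG annotations")
  }
  if (length(go_set) && (min(go_set) < 1 || max(go_set) > length(catalog$go_terms))) {
    stop("GO index out of range for protein '", protein_id, "'")
  }
  if (length(kegg_set) && (min(kegg_set) < 1 || max(kegg_set) > length(catalog$kegg_pathways))) {
    stop("KEGG index out of range for protein '", protein_id, "'")
  }
  structure(list(protein_id = as.character(protein_id),
                 go_set = go_set, kegg_set = kegg_set),
            class = "protein_profile")
}

#' Interaction table of unordered protein pairs
#'
#' Pairs are canonicalised to `(min(id), max(id))` lexicographically — the
#' pair encoding is order-invariant, so orientation carries no information.
#' Self-pairs and duplicate unordered pairs are rejected.
#'
#' @param protein1,protein2 character vectors of endpoint identifiers.
#' @param score non-negative per-pair experimental scores.
#' @return an `interaction_table`: a data.frame with columns `protein1`,
#'   `protein2`, `score`, canonicalised and unique.
#' @export
interaction_table <- function(protein1, protein2, score = rep(1, length(protein1))) {
  protein1 <- as.character(protein1); protein2 <- as.character(protein2)
  stopifnot(length(protein1) == length(protein2), length(score) == length(protein1))
  if (any(protein1 == protein2)) stop("self-pairs are not allowed in an interaction table")
  a <- pmin(protein1, protein2); b <- pmax(protein1, protein2)
  if (anyDuplicated(paste(a, b, sep = "\r"))) stop("duplicate unordered pairs")
  if (any(score < 0)) stop("scores must be non-negative")
  df <- data.frame(protein1 = a, protein2 = b, score = as.numeric(score),
                   stringsAsFactors = FALSE)
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Read a protein-protein interaction table
#'
#' Reads a STRING-like tab-separated layout: columns `protein1`, `protein2`,
#' `experimental_score` (further columns ignored); lines starting with `#`
#' are comments. Pairs are kept only when the score is strictly greater than
#' `score_threshold`; pairs are canonicalised and de-duplicated and
#' self-pairs are dropped with a message reporting the count.
#'
#' @param path path to the TSV file.
#' @param score_threshold keep pairs with score strictly greater than this;
#'   must be >= 0.
#' @return an [interaction_table()].
#' @export
read_interactions <- function(path, score_threshold = 0) {
  stopifnot(score_threshold >= 0)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  # tolerate a header row naming the columns
  if (length(fields) && identical(tolower(fields[[1]][1]), "protein1")) {
    fields <- fields[-1]; lineno <- lineno[-1]
  }
  if (!length(fields)) stop("no interactions passed threshold")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed interaction row at line ", lineno[which(nf < 3)[1]],
         ": expected at least 3 tab-separated columns")
  }
  p1 <- vapply(fields, `[[`, "", 1)
  p2 <- vapply(fields, `[[`, "", 2)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(sc)) {
    stop("malformed interaction row at line ", lineno[which(is.na(sc))[1]],
         ": score is not numeric")
  }
  selfp <- p1 == p2
  if (any(selfp)) {
    message("read_interactions: dropped ", sum(selfp), " self-pair(s)")
    p1 <- p1[!selfp]; p2 <- p2[!selfp]; sc <- sc[!selfp]
  }
  a <- pmin(p1, p2); b <- pmax(p1, p2)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  a <- a[first]; b <- b[first]; sc <- sc[first]
  pass <- sc > score_threshold
  if (!any(pass)) stop("no interactions passed threshold")
  interaction_table(a[pass], b[pass], sc[pass])
}

# parse one annotation file into a protein -> term-id map (2-column data.frame).
# Accepts two-column TSV (protein<TAB>term) or GMT-style
# (term<TAB>description<TAB>member...). format: "auto", "tsv" or "gmt".
parse_annotation_file <- function(path, format = "auto") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (!length(fields)) {
    return(data.frame(protein = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  if (format == "auto") {
    format <- if (all(lengths(fields) == 2)) "tsv" else "gmt"
  }
  if (format == "tsv") {
    bad <- which(lengths(fields) != 2)
    if (length(bad)) stop("malformed annotation row at line ", which(keep)[bad[1]])
    df <- data.frame(protein = vapply(fields, `[[`, "", 1),
                     term = vapply(fields, `[[`, "", 2),
                     stringsAsFactors = FALSE)
  } else {
    bad <- which(lengths(fields) < 3)
    if (length(bad)) {
      stop("malformed gene-set row at line ", which(keep)[bad[1]],
           ": expected term, description, members...")
    }
    df <- do.call(rbind, lapply(fields, function(f) {
      data.frame(protein = f[-(1:2)], term = f[1], stringsAsFactors = FALSE)
    }))
  }
  unique(df)
}

#' Read GO and KEGG annotation maps
#'
#' Each file is either a two-column TSV (`protein<TAB>term`) or a GMT-style
#' gene-set file (`term<TAB>description<TAB>member...`); the layout is
#' auto-detected per file. The catalog orders terms by lexicographic sort of
#' their identifiers so feature indices are reproducible across runs.
#' Proteins with no annotation in either channel cannot occur (they simply do
#' not appear in the files); a term id found in both files violates channel
#' disjointness and is an error.
#'
#' @param go_path path to the GO annotation file.
#' @param kegg_path path to the KEGG annotation file.
#' @param format `"auto"`, `"tsv"` or `"gmt"`, applied to both files.
#' @return a list with `catalog` (an [annotation_catalog()]) and `profiles`
#'   (a named list of [protein_profile()] objects keyed by protein id).
#' @export
read_annotations <- function(go_path, kegg_path, format = "auto") {
  go_map <- parse_annotation_file(go_path, format)
  kegg_map <- parse_annotation_file(kegg_path, format)
  go_terms <- sort(unique(go_map$term))
  kegg_terms <- sort(unique(kegg_map$term))
  catalog <- annotation_catalog(go_terms, kegg_terms)
  proteins <- sort(unique(c(go_map$protein, kegg_map$protein)))
  go_idx <- split(match(go_map$term, go_terms), go_map$protein)
  kegg_idx <- split(match(kegg_map$term, kegg_terms), kegg_map$protein)
  profiles <- lapply(proteins, function(p) {
    protein_profile(p, go_idx[[p]] %||% integer(),
                    kegg_idx[[p]] %||% integer(), catalog)
  })
  names(profiles) <- proteins
  list(catalog = catalog, profiles = profiles)
}

#' Restrict an interaction table to annotated proteins
#'
#' Drops every pair with an endpoint lacking an annotation profile (the
#' retained protein universe is the intersection of proteins occurring in
#' pairs and proteins with a non-empty profile). The dropped-pair count is
#' reported with a message.
#'
#' @param table an [interaction_table()].
#' @param profiles named list of [protein_profile()] objects.
#' @return the filtered [interaction_table()].
#' @export
restrict_to_annotated <- function(table, profiles) {
  ok <- table$protein1 %in% names(profiles) & table$protein2 %in% names(profiles)
  dropped <- sum(!ok)
  if (dropped > 0) {
    message("restrict_to_annotated: dropped ", dropped,
            " pair(s) with unannotated endpoints")
  }
  if (!any(ok)) stop("no interaction pairs have annotated endpoints")
  out <- table[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Write pipeline outputs
#'
#' Writes the per-algorithm integrated feature lists (TSV: feature name,
#' N(f), M(f), W(f), importance score, rank), the Venn membership table
#' (TSV), and a run-metadata JSON (seeds, parameters, counts). Content is
#' deterministic: a rerun with the same inputs is byte-identical.
#'
#' @param results list with elements `integrated` (named list of consensus
#'   data.frames as returned by [integrate_ranked_lists()]), `venn` (a
#'   [venn_partition()] or NULL) and `metadata` (a list serialised to JSON).
#' @param out_dir output directory, created if missing.
#' @return character vector of written file paths (the manifest).
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  paths <- character()
  for (alg in names(results$integrated)) {
    cl <- results$integrated[[alg]]
    df <- data.frame(feature = cl$name %||% as.character(cl$feature_id),
                     N = cl$N %||% integer(), M = cl$M %||% numeric(),
                     W = cl$W %||% numeric(), importance_score = cl$score %||% numeric(),
                     rank = cl$rank %||% integer(), stringsAsFactors = FALSE)
    p <- file.path(out_dir, paste0(alg, "_integrated.tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  vdf <- if (!is.null(results$venn)) venn_table(results$venn) else
    data.frame(feature = character(), n_algorithms = integer(),
               algorithms = character(), stringsAsFactors = FALSE)
  p <- file.path(out_dir, "venn.tsv")
  utils::write.table(vdf, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(results$metadata %||% list(), p,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  paths
}
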