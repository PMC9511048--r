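#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' protein universe with sparse binary term annotations over two channels, a
#' small set of "signal" terms whose co-annotation is enriched among positive
#' pairs, and class imbalance large enough to force multi-subset
#' partitioning. It does not simulate sequences, ontology DAG structure or
#' realistic term co-occurrence.
#'
#' @param n_proteins number of proteins in the universe.
#' @param n_go,n_kegg number of GO terms / KEGG pathways.
#' @param base_prevalence probability in (0,1) that a protein carries a given
#'   background term (default 0.05: sparse annotations).
#' @param n_signal number of signal terms, drawn from both channels.
#' @param signal_prevalence probability a protein carries a given signal term
#'   (default 0.2, so that sharing a signal term is common enough to enrich).
#' @param n_pos number of positive pairs to draw.
#' @param enrichment odds multiplier >= 1 favouring candidate pairs that
#'   share at least one signal term; `enrichment = 1` makes positives uniform
#'   random pairs (no planted signal).
#' @param seed integer master seed; one named stream per sub-step.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins, n_go, n_kegg,
                             base_prevalence = 0.05,
                             n_signal = 0,
                             signal_prevalence = 0.2,
                             n_pos,
                             enrichment = 1,
                             seed = 1L) {
  stopifnot(n_proteins >= 2, n_go >= 0, n_kegg >= 0, n_go + n_kegg >= 1,
            base_prevalence > 0, base_prevalence < 1,
            signal_prevalence > 0, signal_prevalence < 1,
            n_signal >= 0, n_signal <= n_go + n_kegg,
            n_pos >= 1, enrichment >= 1)
  if (n_pos > count_all_pairs(n_proteins)) {
    stop("n_pos exceeds the number of distinct pairs C(n_proteins, 2)")
  }
  structure(list(n_proteins = as.integer(n_proteins), n_go = as.integer(n_go),
                 n_kegg = as.integer(n_kegg),
                 base_prevalence = base_prevalence,
                 n_signal = as.integer(n_signal),
                 signal_prevalence = signal_prevalence,
                 n_pos = as.integer(n_pos), enrichment = enrichment,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic protein universe with planted signal terms
#'
#' Annotations are independent Bernoulli draws per (protein, term) at the
#' configured prevalence (signal terms use `signal_prevalence`); proteins
#' that end up with no term are redrawn, so every protein has at least one
#' annotation. Positive pairs are drawn by rejection sampling: a candidate
#' pair sharing at least one signal term is accepted with probability 1,
#' a non-sharing pair with probability `1/enrichment`. Signal terms span
#' both channels (when both exist) so both feature families carry signal.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `catalog`, `profiles`, `interactions` (the positive
#'   [interaction_table()], score 1) and `truth` (signal term ids, the
#'   derived signal feature names, and the config echo).
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  go_terms <- if (cfg$n_go) sprintf("GO:%07d", seq_len(cfg$n_go)) else character()
  kegg <- if (cfg$n_kegg) sprintf("hsa%05d", seq_len(cfg$n_kegg)) else character()
  catalog <- annotation_catalog(go_terms, kegg)
  all_terms <- c(go_terms, kegg)
  nt <- length(all_terms)

  # pick signal terms spanning both channels, proportional to channel size
  set.seed(derive_seed(cfg$seed, "signal"))
  signal_terms <- character()
  if (cfg$n_signal > 0) {
    if (cfg$n_go > 0 && cfg$n_kegg > 0 && cfg$n_signal >= 2) {
      k_kegg <- min(cfg$n_kegg,
                    max(1L, round(cfg$n_signal * cfg$n_kegg / nt)))
      k_go <- cfg$n_signal - k_kegg
      signal_terms <- c(sample(go_terms, k_go), sample(kegg, k_kegg))
    } else {
      signal_terms <- sample(all_terms, cfg$n_signal)
    }
  }
  prev <- ifelse(all_terms %in% signal_terms,
                 cfg$signal_prevalence, cfg$base_prevalence)

  # annotations: one Bernoulli draw per (protein, term); redraw empty proteins
  set.seed(derive_seed(cfg$seed, "annotations"))
  M <- matrix(stats::rbinom(cfg$n_proteins * nt, 1L, rep(prev, each = cfg$n_proteins)),
              nrow = cfg$n_proteins, ncol = nt)
  for (round in 1:100) {
    empty <- which(rowSums(M) == 0)
    if (!length(empty)) break
    M[empty, ] <- matrix(stats::rbinom(length(empty) * nt, 1L,
                                       rep(prev, each = length(empty))),
                         nrow = length(empty))
  }
  empty <- which(rowSums(M) == 0)
  if (length(empty)) { # pathological prevalence; force one background term
    M[cbind(empty, sample.int(nt, length(empty), replace = TRUE))] <- 1L
  }
  # every term annotates at least one protein, so the catalog survives a
  # round-trip through the annotation files (which only carry attached terms)
  orphan <- which(colSums(M) == 0)
  if (length(orphan)) {
    M[cbind(sample.int(cfg$n_proteins, length(orphan), replace = TRUE), orphan)] <- 1L
  }
  ids <- sprintf("P%05d", seq_len(cfg$n_proteins))
  profiles <- lapply(seq_len(cfg$n_proteins), function(i) {
    on <- which(M[i, ] == 1L)
    protein_profile(ids[i], go_set = on[on <= cfg$n_go],
                    kegg_set = on[on > cfg$n_go] - cfg$n_go, catalog)
  })
  names(profiles) <- ids

  # positives by rejection sampling with signal-sharing enrichment
  sig_idx <- match(signal_terms, all_terms)
  Msig <- M[, sig_idx, drop = FALSE]
  set.seed(derive_seed(cfg$seed, "positives"))
  chosen <- new.env(hash = TRUE, parent = emptyenv())
  p1 <- character(cfg$n_pos); p2 <- character(cfg$n_pos)
  got <- 0L
  max_attempts <- 200 * cfg$n_pos + 10000
  attempts <- 0
  while (got < cfg$n_pos) {
    m <- min(10000L, max(1000L, (cfg$n_pos - got) * 4L))
    attempts <- attempts + m
    if (attempts > max_attempts) {
      stop("could not place ", cfg$n_pos, " positive pairs; config infeasible")
    }
    i <- sample.int(cfg$n_proteins, m, replace = TRUE)
    j <- sample.int(cfg$n_proteins, m, replace = TRUE)
    u <- stats::runif(m)
    ok <- i != j
    shares <- if (ncol(Msig)) rowSums(Msig[i, , drop = FALSE] *
                                      Msig[j, , drop = FALSE]) > 0 else
      rep(FALSE, m)
    accept <- ok & (shares | u <= 1 / cfg$enrichment)
    i <- i[accept]; j <- j[accept]
    a <- pmin(ids[i], ids[j]); b <- pmax(ids[i], ids[j])
    keys <- paste(a, b, sep = "\r")
    fresh <- !duplicated(keys) & !vapply(keys, exists, FALSE, envir = chosen)
    a <- a[fresh]; b <- b[fresh]; keys <- keys[fresh]
    take <- seq_len(min(length(keys), cfg$n_pos - got))
    for (k in keys[take]) assign(k, TRUE, envir = chosen)
    p1[got + take] <- a[take]; p2[got + take] <- b[take]
    got <- got + length(take)
  }
  interactions <- interaction_table(p1, p2, rep(1, cfg$n_pos))

  desc <- feature_descriptors(catalog)
  truth <- structure(list(
    signal_terms = sort(signal_terms),
    signal_features = sort(desc$name[desc$term_id %in% signal_terms]),
    config = cfg), class = "synthetic_truth")
  list(catalog = catalog, profiles = profiles,
       interactions = interactions, truth = truth)
}

#' Write synthetic inputs in the formats the readers ingest
#'
#' Emits `interactions.tsv` (protein1, protein2, experimental_score),
#' `go_annotations.tsv` and `kegg_annotations.tsv` (two-column
#' protein<TAB>term) and `truth.json` (signal terms plus config echo), so a
#' full run can be driven from files exactly as with real data.
#'
#' @param sim result of [generate_synthetic()].
#' @param dir output directory.
#' @return named character vector of written paths.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ip <- file.path(dir, "interactions.tsv")
  utils::write.table(sim$interactions, ip, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("protein1", "protein2",
                                                      "experimental_score"))
  maps <- lapply(sim$profiles, function(p) {
    data.frame(protein = p$protein_id,
               term = c(sim$catalog$go_terms[p$go_set],
                        sim$catalog$kegg_pathways[p$kegg_set]),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  is_go <- map$term %in% sim$catalog$go_terms
  gp <- file.path(dir, "go_annotations.tsv")
  kp <- file.path(dir, "kegg_annotations.tsv")
  utils::write.table(map[is_go, ], gp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(map[!is_go, ], kp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(list(signal_terms = sim$truth$signal_terms,
                            signal_features = sim$truth$signal_features,
                            config = unclass(sim$truth$config)),
                       tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(interactions = ip, go = gp, kegg = kp, truth = tp)
}

#' Fraction of signal terms recovered in the top of a ranked list
#'
#' A signal term is recovered when at least one of its two derived features
#' (sum or absdiff channel) appears among the first `top_n` entries of the
#' integrated feature list.
#'
#' @param truth a `synthetic_truth` from [generate_synthetic()].
#' @param ranked_features character vector of feature machine names in rank
#'   order (rank 1 first).
#' @param top_n how many leading features to inspect.
#' @return fraction in \[0, 1\].
#' @export
recovery_rate <- function(truth, ranked_features, top_n) {
  stopifnot(top_n >= 1)
  if (length(ranked_features) == 0) stop("ranked feature list is empty")
  if (length(truth$signal_terms) == 0) stop("truth contains no signal terms")
  top <- utils::head(ranked_features, top_n)
  hit_terms <- sub("^(sum|absdiff):", "", top)
  mean(truth$signal_terms %in% hit_terms)
}

#' Rank separation between signal-derived and background features
#'
#' Measures whether signal-derived features sit higher (smaller rank) in an
#' integrated list than background features. Every feature of the full
#' descriptor table that is absent from the list is assigned the worst rank
#' `L + 1` (L = list length), so the statistic is defined even when the
#' filtering stage selected few or no features. Significance is assessed by
#' permuting the signal/background labels over features.
#'
#' @param truth a `synthetic_truth`.
#' @param ranked_features character vector of feature machine names in rank
#'   order (the integrated list).
#' @param descriptors full feature descriptor table ([feature_descriptors()]).
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list with `mean_signal`, `mean_background`, `difference`
#'   (background minus signal; positive means signal ranks better) and
#'   `p_value` (one-sided permutation P(perm >= observed)).
#' @export
signal_separation <- function(truth, ranked_features, descriptors,
                              n_perm = 1000, seed = 1L) {
  L <- length(ranked_features)
  rk <- rep(L + 1, nrow(descriptors))
  pos <- match(ranked_features, descriptors$name)
  rk[pos] <- seq_len(L)
  is_signal <- descriptors$name %in% truth$signal_features
  if (!any(is_signal) || all(is_signal)) {
    stop("truth must mark a non-trivial subset of features as signal")
  }
  obs <- mean(rk[!is_signal]) - mean(rk[is_signal])
  set.seed(seed)
  n_sig <- sum(is_signal)
  perm <- replicate(n_perm, {
    lab <- logical(length(rk))
    lab[sample.int(length(rk), n_sig)] <- TRUE
    mean(rk[!lab]) - mean(rk[lab])
  })
  list(mean_signal = mean(rk[is_signal]),
       mean_background = mean(rk[!is_signal]),
       difference = obs,
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm))
}
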