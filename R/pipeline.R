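#' Build a full-run configuration
#'
#' One object drives the whole pipeline: ingest (files or synthetic
#' generator) -> negative sampling and balanced datasets -> pair encoding ->
#' shadow-feature filtering -> three-way ranking -> per-algorithm integration
#' -> top-N Venn intersection -> report. The master seed deterministically
#' derives every stage seed, so identical configs give byte-identical
#' outputs.
#'
#' @param interactions_path,go_path,kegg_path input files (NULL when
#'   `synthetic` is given).
#' @param synthetic a [synthetic_config()] (NULL when reading files).
#' @param score_threshold keep pairs with score strictly greater than this.
#' @param K number of balanced datasets, or `"auto"` =
#'   `floor(negatives / positives)`.
#' @param n_negatives negatives to sample: `"auto"` = `K * positives`
#'   (or all available if fewer), or `"all"`, or a count.
#' @param algorithms subset of `c("lasso", "gbdt", "mrmr")`.
#' @param boruta_max_iter,boruta_alpha,boruta_trees filtering parameters.
#' @param tentative tentative-feature policy, `"reject"` or `"median"`.
#' @param lasso_alpha,gbdt_trees,mrmr_top_k ranking parameters.
#' @param top_n integrated-list prefix size for the Venn stage (default 100).
#' @param seed master integer seed.
#' @param out_dir output directory (tables, metadata, stage cache).
#' @return a `run_config` list.
#' @export
run_config <- function(interactions_path = NULL, go_path = NULL,
                       kegg_path = NULL, synthetic = NULL,
                       score_threshold = 0, K = "auto",
                       n_negatives = "auto",
                       algorithms = c("lasso", "gbdt", "mrmr"),
                       boruta_max_iter = 100, boruta_alpha = 0.05,
                       boruta_trees = 100, tentative = "reject",
                       lasso_alpha = 0.01, gbdt_trees = 100,
                       mrmr_top_k = NULL, top_n = 100, seed = 1L,
                       out_dir = tempfile("ppifun_run_")) {
  structure(list(interactions_path = interactions_path, go_path = go_path,
                 kegg_path = kegg_path, synthetic = synthetic,
                 score_threshold = score_threshold, K = K,
                 n_negatives = n_negatives, algorithms = algorithms,
                 boruta_max_iter = boruta_max_iter,
                 boruta_alpha = boruta_alpha, boruta_trees = boruta_trees,
                 tentative = tentative, lasso_alpha = lasso_alpha,
                 gbdt_trees = gbdt_trees, mrmr_top_k = mrmr_top_k,
                 top_n = top_n, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Returns the problems found (empty character vector = valid); nothing is
#' thrown, so callers can report all problems at once before any compute.
#'
#' @param cfg a [run_config()].
#' @return character vector of problem descriptions.
#' @export
validate_run_config <- function(cfg) {
  problems <- character()
  from_files <- !is.null(cfg$interactions_path)
  if (from_files) {
    for (p in c(cfg$interactions_path, cfg$go_path, cfg$kegg_path)) {
      if (is.null(p) || !file.exists(p)) {
        problems <- c(problems, paste0("input file missing: ", p %||% "(unset)"))
      }
    }
    if (!is.null(cfg$synthetic)) {
      problems <- c(problems, "give either input files or a synthetic config, not both")
    }
  } else if (is.null(cfg$synthetic)) {
    problems <- c(problems, "no input: set interactions/annotation paths or a synthetic config")
  } else if (!inherits(cfg$synthetic, "synthetic_config")) {
    problems <- c(problems, "synthetic must be a synthetic_config object")
  }
  if (!is.numeric(cfg$score_threshold) || cfg$score_threshold < 0) {
    problems <- c(problems, "score_threshold must be a non-negative number")
  }
  if (!identical(cfg$K, "auto") && (!is.numeric(cfg$K) || cfg$K < 1)) {
    problems <- c(problems, "K must be 'auto' or a positive integer")
  }
  bad_alg <- setdiff(cfg$algorithms, c("lasso", "gbdt", "mrmr"))
  if (length(bad_alg)) {
    problems <- c(problems, paste0("unknown ranking algorithm: ",
                                   paste(bad_alg, collapse = ", ")))
  }
  if (length(cfg$algorithms) < 1) problems <- c(problems, "no ranking algorithms configured")
  if (!is.numeric(cfg$top_n) || cfg$top_n < 1) {
    problems <- c(problems, "top_n must be a positive integer")
  }
  for (fld in c("boruta_max_iter", "boruta_trees", "gbdt_trees")) {
    if (!is.numeric(cfg[[fld]]) || cfg[[fld]] < 1) {
      problems <- c(problems, paste0(fld, " must be a positive integer"))
    }
  }
  if (!is.numeric(cfg$boruta_alpha) || cfg$boruta_alpha <= 0 || cfg$boruta_alpha >= 1) {
    problems <- c(problems, "boruta_alpha must be in (0, 1)")
  }
  if (!is.numeric(cfg$lasso_alpha) || cfg$lasso_alpha <= 0) {
    problems <- c(problems, "lasso_alpha must be > 0")
  }
  if (!(identical(cfg$tentative, "reject") || identical(cfg$tentative, "median"))) {
    problems <- c(problems, "tentative must be 'reject' or 'median'")
  }
  problems
}

# stage cache: stores RDS keyed by a hash of the stage inputs; reruns with an
# unchanged config reuse cached results and record the stage as cached.
cache_key <- function(...) {
  f <- tempfile()
  saveRDS(list(...), f, version = 2, compress = FALSE)
  key <- unname(tools::md5sum(f))
  unlink(f)
  key
}

cache_fetch <- function(cache_dir, name, key, compute) {
  path <- file.path(cache_dir, paste0(name, "-", key, ".rds"))
  if (file.exists(path)) {
    return(list(value = readRDS(path), cached = TRUE))
  }
  value <- compute()
  saveRDS(value, path)
  list(value = value, cached = FALSE)
}

#' Run the full pipeline
#'
#' Executes every stage in order, caching each stage's result under
#' `out_dir/cache` so an unchanged rerun reuses it. Writes the integrated
#' lists, Venn table and run metadata via [write_outputs()] and returns all
#' in-memory results.
#'
#' @param cfg a [run_config()]; validated first, all problems thrown at once.
#' @return list with `catalog`, `descriptors`, `filter_results`,
#'   `integrated` (per algorithm), `tops`, `venn`, `report`, `truth` (NULL
#'   for file input), `manifest` (seeds, counts, timings, cached flags,
#'   written paths).
#' @export
run_pipeline <- function(cfg) {
  problems <- validate_run_config(cfg)
  if (length(problems)) {
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(cfg$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  t_stage <- function(name, key, compute) {
    t0 <- Sys.time()
    res <- cache_fetch(cache_dir, name, key, compute)
    manifest$stages[[name]] <<- list(
      cached = res$cached,
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
    res$value
  }

  # --- ingest -------------------------------------------------------------
  ingest_key <- cache_key("ingest", cfg$interactions_path, cfg$go_path,
                          cfg$kegg_path,
                          if (!is.null(cfg$synthetic)) unclass(cfg$synthetic),
                          cfg$score_threshold)
  ing <- t_stage("ingest", ingest_key, function() {
    if (!is.null(cfg$synthetic)) {
      sim <- generate_synthetic(cfg$synthetic)
      list(catalog = sim$catalog, profiles = sim$profiles,
           positives = sim$interactions, truth = sim$truth)
    } else {
      ann <- read_annotations(cfg$go_path, cfg$kegg_path)
      tab <- read_interactions(cfg$interactions_path, cfg$score_threshold)
      tab <- restrict_to_annotated(tab, ann$profiles)
      list(catalog = ann$catalog, profiles = ann$profiles,
           positives = tab, truth = NULL)
    }
  })
  proteins <- sort(unique(c(ing$positives$protein1, ing$positives$protein2)))
  n_pos <- nrow(ing$positives)
  manifest$counts <- list(n_proteins = length(proteins), n_positives = n_pos,
                          n_terms_go = length(ing$catalog$go_terms),
                          n_terms_kegg = length(ing$catalog$kegg_pathways))

  # --- negatives and balanced datasets --------------------------------------
  total_pairs <- count_all_pairs(length(proteins))
  avail_neg <- total_pairs - n_pos
  K <- if (identical(cfg$K, "auto")) num_subsets(avail_neg, n_pos) else as.integer(cfg$K)
  n_neg <- if (identical(cfg$n_negatives, "auto")) {
    min(avail_neg, K * n_pos)
  } else if (identical(cfg$n_negatives, "all")) "all" else as.double(cfg$n_negatives)
  ds_key <- cache_key("datasets", ingest_key, K, n_neg, cfg$seed)
  datasets <- t_stage("datasets", ds_key, function() {
    negatives <- sample_negatives(proteins, ing$positives, n_neg,
                                  seed = derive_seed(cfg$seed, "negatives"))
    subsets <- partition_negatives(negatives, K,
                                   seed = derive_seed(cfg$seed, "partition"))
    build_datasets(ing$positives, subsets)
  })
  manifest$counts$K <- K
  manifest$counts$n_negatives <- sum(vapply(datasets, function(d)
    nrow(d$negatives), 0))

  # --- encode + filter per dataset ------------------------------------------
  filt_key <- cache_key("filter", ds_key, cfg$boruta_max_iter,
                        cfg$boruta_alpha, cfg$boruta_trees, cfg$tentative)
  filter_results <- t_stage("filter", filt_key, function() {
    lapply(datasets, function(ds) {
      pfm <- encode_dataset(ds, ing$profiles, ing$catalog)
      boruta_filter(pfm, max_iter = cfg$boruta_max_iter,
                    alpha = cfg$boruta_alpha, num_trees = cfg$boruta_trees,
                    tentative = cfg$tentative,
                    seed = derive_seed(cfg$seed, "boruta", ds$dataset_id),
                    dataset_id = ds$dataset_id)
    })
  })
  manifest$counts$n_selected_union <-
    length(union_selected(filter_results)$features)

  # --- rank per dataset per algorithm ---------------------------------------
  rank_key <- cache_key("rank", filt_key, cfg$algorithms, cfg$lasso_alpha,
                        cfg$gbdt_trees, cfg$mrmr_top_k)
  ranked <- t_stage("rank", rank_key, function() {
    lapply(datasets, function(ds) {
      pfm <- encode_dataset(ds, ing$profiles, ing$catalog)
      rank_dataset(pfm, filter_results[[ds$dataset_id]],
                   algorithms = cfg$algorithms, lasso_alpha = cfg$lasso_alpha,
                   gbdt_trees = cfg$gbdt_trees, mrmr_top_k = cfg$mrmr_top_k,
                   seed = cfg$seed)
    })
  })

  # --- integrate, top-N, venn -----------------------------------------------
  descriptors <- feature_descriptors(ing$catalog)
  integrated <- list()
  tops <- list()
  for (alg in cfg$algorithms) {
    lists <- Filter(Negate(is.null), lapply(ranked, `[[`, alg))
    if (length(lists) == 0) next
    cl <- integrate_ranked_lists(lists, K = K)
    integrated[[alg]] <- cl
    tops[[alg]] <- suppressWarnings(top_features(cl, cfg$top_n))
  }
  venn <- if (length(tops) == 3) venn_partition(tops) else NULL
  report <- render_report(tops, venn, descriptors, filter_results)

  manifest$counts$venn <- if (!is.null(venn)) as.list(venn$counts) else NULL
  manifest$parameters <- cfg[c("score_threshold", "K", "n_negatives",
                               "algorithms", "boruta_max_iter", "boruta_alpha",
                               "boruta_trees", "tentative", "lasso_alpha",
                               "gbdt_trees", "top_n")]
  written <- write_outputs(list(integrated = integrated, venn = venn,
                                metadata = manifest),
                           cfg$out_dir)
  manifest$written <- written
  list(catalog = ing$catalog, descriptors = descriptors,
       filter_results = filter_results, integrated = integrated,
       tops = tops, venn = venn, report = report, truth = ing$truth,
       manifest = manifest)
}
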