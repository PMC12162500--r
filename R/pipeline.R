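#' Assemble a run configuration
#'
#' Builds the full end-to-end run configuration, merging user settings over
#' documented defaults. Either `simulate` (a [sim_config()] or a list of
#' its arguments) or both `repertoire_path` and `metadata_path` must be
#' given.
#'
#' @param repertoire_path AIRR-style rearrangement table (TSV/CSV).
#' @param metadata_path metadata CSV (`barcode,sample_id,subset,state`).
#' @param simulate a [sim_config()] (or argument list) generating the
#'   input instead of reading files.
#' @param chain receptor chain to analyse.
#' @param subsets cell subsets to analyse; `NULL` = all present.
#' @param ks k values, default `c(2, 3, 4)` (seven datasets).
#' @param selection list of [selection_config()] arguments.
#' @param split list of [split_config()] arguments (seed is taken from
#'   `seed`).
#' @param families classifier families to evaluate.
#' @param grids named list of hyperparameter grids overriding the defaults.
#' @param cv_folds grid-search folds.
#' @param n_perm label permutations for the p-value.
#' @param perm_families `"best"`, `"all"` or `"none"`.
#' @param max_features cap on selected features per dataset.
#' @param select_before_split run selection before splitting (reduce-then-split
#'   ordering) instead of inside the training partition.
#' @param shared_top_n top-list size for the shared-kmer analysis.
#' @param quick single-point grids and fewer permutations, for smoke runs.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory; `NULL` returns results without writing.
#' @return List of class `run_config`.
#' @export
run_config <- function(repertoire_path = NULL, metadata_path = NULL,
                       simulate = NULL, chain = "BCRH", subsets = NULL,
                       ks = c(2, 3, 4), selection = list(), split = list(),
                       families = classifier_families(), grids = NULL,
                       cv_folds = 5, n_perm = 199,
                       perm_families = "best", max_features = 2000,
                       select_before_split = FALSE, shared_top_n = 50,
                       quick = FALSE, seed = 1, out_dir = NULL) {
  if (is.null(simulate) &&
      (is.null(repertoire_path) || is.null(metadata_path))) {
    stop("provide either `simulate` or both repertoire_path and metadata_path")
  }
  if (quick) {
    n_perm <- min(n_perm, 49)
    grids <- grids %||% default_grids(quick = TRUE)
    cv_folds <- min(cv_folds, 3)
  }
  split$seed <- seed
  structure(list(repertoire_path = repertoire_path,
                 metadata_path = metadata_path, simulate = simulate,
                 chain = chain, subsets = subsets, ks = sort(unique(ks)),
                 selection = do.call(selection_config, selection),
                 split = do.call(split_config, split),
                 families = families, grids = grids, cv_folds = cv_folds,
                 n_perm = n_perm, perm_families = perm_families,
                 max_features = max_features, select_before_split = select_before_split,
                 shared_top_n = shared_top_n, quick = quick,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML fields mirror the arguments of [run_config()]; `simulate:` may
#' hold [sim_config()] arguments (including a `class_motifs` list of
#' `state`/`motif`/`insertion_prob` entries).
#'
#' @param path YAML file.
#' @param ... overrides applied after reading (e.g. `seed`, `out_dir`).
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate) && !is.null(y$simulate$class_motifs)) {
    cm <- y$simulate$class_motifs
    y$simulate$class_motifs <- data.frame(
      state = vapply(cm, function(m) as.integer(m$state), integer(1)),
      motif = vapply(cm, function(m) as.character(m$motif), character(1)),
      insertion_prob = vapply(cm, function(m) as.numeric(m$insertion_prob),
                              numeric(1)),
      stringsAsFactors = FALSE)
  }
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

.load_records <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!inherits(sim, "sim_config")) {
      sim$seed <- sim$seed %||% config$seed
      sim <- do.call(sim_config, sim)
    }
    generate_repertoire(sim)$records
  } else {
    rec <- read_repertoire(config$repertoire_path, chain = config$chain)
    meta <- .read_table_auto(config$metadata_path)
    join_annotations(rec, meta)
  }
}

#' Run the end-to-end classification pipeline
#'
#' Orchestrates featurize -> filter -> select -> train -> evaluate ->
#' report for every requested cell subset: assembles one dataset per
#' non-empty combination of the k values, evaluates the classifier
#' families on each, derives the best-model table, and intersects top
#' k-mers across subsets. When `config$out_dir` is set, results are written
#' as CSV/JSON together with a provenance record; re-running with the same
#' config and seed reproduces every output byte-identically.
#'
#' @param config a [run_config()] (or a YAML path, passed through
#'   [read_run_config()]).
#' @return Invisibly, a list with `report` (all families x datasets x
#'   subsets), `best` (best-model table per subset), `shared` (shared
#'   k-mer table or NULL), `length_distribution`, `selections`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  records <- .load_records(config)
  if (nrow(records) == 0) stop("pipeline aborted at stage 'load': no records")
  message("loaded ", nrow(records), " records (",
          length(unique(records$sample_id)), " samples)")
  lendist <- length_distribution(records)

  subsets <- config$subsets %||% unique(records$subset)
  reports <- list()
  bests <- list()
  selections <- list()
  rocs <- list()
  for (sb in subsets) {
    message("subset ", sb, ": building ", 2^length(config$ks) - 1,
            " k-mer dataset(s) for k = {",
            paste(config$ks, collapse = ","), "}")
    mats <- seven_datasets(records, ks = config$ks, subset = sb)
    sub_rows <- list()
    for (di in seq_along(mats)) {
      nm <- names(mats)[di]
      ev <- evaluate_dataset(
        mats[[di]], families = config$families,
        sel_cfg = config$selection, split_cfg = config$split,
        grids = config$grids, cv_folds = config$cv_folds,
        n_perm = config$n_perm, perm_families = config$perm_families,
        seed = config$seed + 31L * di, max_features = config$max_features,
        select_before_split = config$select_before_split, dataset_name = nm)
      ev$report$subset <- sb
      ev$roc$subset <- sb
      sub_rows[[nm]] <- ev$report
      rocs[[paste(sb, nm)]] <- ev$roc
      if (nm == paste0("kmer", paste(config$ks, collapse = "_"))) {
        selections[[sb]] <- ev$selection
      }
      message("  ", nm, ": best macro AUC ",
              sprintf("%.3f", max(ev$report$macro_auc)), " (",
              ev$report$family[which.max(ev$report$macro_auc)], "), ",
              ev$report$n_features[1], " features")
    }
    sub_report <- do.call(rbind, sub_rows)
    rownames(sub_report) <- NULL
    reports[[sb]] <- sub_report
    best <- best_model_table(sub_report, alpha = config$selection$alpha)
    best$subset <- sb
    bests[[sb]] <- best
  }
  report <- do.call(rbind, reports)
  best <- do.call(rbind, bests)
  rownames(report) <- rownames(best) <- NULL

  shared <- NULL
  if (length(selections) >= 2) {
    ranked <- lapply(selections, top_features, n = config$shared_top_n)
    shared <- shared_kmer_analysis(ranked, top_n = config$shared_top_n)
  }

  out <- list(report = report, best = best, shared = shared,
              length_distribution = lendist,
              roc = do.call(rbind, rocs), selections = selections,
              config = config)
  if (!is.null(config$out_dir)) .write_run_outputs(out, config)
  invisible(out)
}

# all file outputs are deterministic functions of config + seed: no
# timestamps or environment state are recorded
.write_run_outputs <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)
  utils::write.csv(out$report, p("results_full.csv"), row.names = FALSE)
  utils::write.csv(out$best, p("best_models.csv"), row.names = FALSE)
  utils::write.csv(out$length_distribution, p("length_distribution.csv"),
                   row.names = FALSE)
  if (!is.null(out$roc)) {
    utils::write.csv(out$roc, p("roc_points.csv"), row.names = FALSE)
  }
  if (!is.null(out$shared)) {
    utils::write.csv(out$shared, p("shared_kmers.csv"), row.names = FALSE)
  }
  for (sb in names(out$selections)) {
    sel <- as.data.frame(out$selections[[sb]])
    utils::write.csv(sel[sel$kept, , drop = FALSE],
                     p(paste0("selection_", gsub("[^A-Za-z0-9_.-]", "_", sb),
                              ".csv")),
                     row.names = FALSE)
  }
  prov <- list(
    package = "cdr3kmer",
    version = as.character(utils::packageVersion("cdr3kmer")),
    seed = config$seed,
    ks = config$ks,
    chain = config$chain,
    selection = unclass(config$selection),
    split = unclass(config$split),
    families = config$families,
    cv_folds = config$cv_folds,
    n_perm = config$n_perm,
    perm_families = config$perm_families,
    max_features = config$max_features,
    select_before_split = config$select_before_split,
    simulate = if (!is.null(config$simulate)) "synthetic" else "files",
    inputs = list(repertoire = config$repertoire_path,
                  metadata = config$metadata_path)
  )
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(out$report, p("results_full.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(NULL)
}
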