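#' Train/test split configuration
#'
#' @param train_fraction fraction of rows in the training partition;
#'   default 0.8 (a 4:1 split).
#' @param stratified preserve per-class proportions (default `TRUE`).
#' @param seed integer seed making the partition deterministic.
#' @return List of class `split_config`.
#' @export
split_config <- function(train_fraction = 0.8, stratified = TRUE, seed = 1) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)), class = "split_config")
}

#' Stratified train/test split
#'
#' Splits row indices into disjoint, exhaustive train and test sets,
#' preserving per-class proportions to rounding (each class keeps at least
#' one row on each side). Deterministic under a fixed seed.
#'
#' @param labels class label per row.
#' @param config a [split_config()].
#' @return List with sorted integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, config = split_config()) {
  labels <- as.factor(labels)
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("class(es) with fewer than 2 rows: ",
         paste(names(tab)[tab < 2], collapse = ", "),
         "; merge or remove them before splitting")
  }
  set.seed(config$seed)
  if (!config$stratified) {
    n_tr <- min(max(round(n * config$train_fraction), 1), n - 1)
    train <- sort(sample.int(n, n_tr))
  } else {
    train <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      n_tr <- min(max(round(length(idx) * config$train_fraction), 1),
                  length(idx) - 1)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

# stratified CV fold assignment; reduces the fold count with a warning when
# the smallest class cannot populate every fold, errors below 2 feasible
.make_folds <- function(y, k, seed) {
  y <- as.factor(y)
  k_feasible <- min(k, min(table(y)))
  if (k_feasible < 2) stop("cannot form >= 2 cross-validation folds: ",
                           "smallest class has fewer than 2 rows")
  if (k_feasible < k) {
    warning("reducing cross-validation folds from ", k, " to ", k_feasible)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k_feasible), length(idx))
  }
  lapply(seq_len(k_feasible), function(f) which(fold == f))
}

# one-vs-rest AUC by the Mann-Whitney rank statistic (ties get 0.5 credit)
.binary_auc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest AUC
#'
#' Per-class AUC treats each class in turn as positive against the rest,
#' scored by that class's predicted probability; the macro AUC is their
#' unweighted mean, so large classes carry no extra weight. Classes absent
#' from `labels` get `NA` and the macro is averaged over defined classes
#' with a warning.
#'
#' @param scores n x classes matrix of per-class scores; columns named by
#'   class (defaults to the label levels in order).
#' @param labels class label per row.
#' @return List with `macro` (numeric) and `per_class` (named vector).
#' @export
macro_auc <- function(scores, labels) {
  labels <- as.factor(labels)
  lv <- levels(labels)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    if (ncol(scores) != length(lv)) {
      stop("scores must have one column per class")
    }
    colnames(scores) <- lv
  }
  per <- vapply(lv, function(cl) .binary_auc(scores[, cl], labels == cl),
                numeric(1))
  if (anyNA(per)) {
    warning("class(es) absent from labels; macro AUC over defined classes")
  }
  list(macro = mean(per, na.rm = TRUE), per_class = per)
}

#' One-vs-rest ROC curve points
#'
#' Computes each class's ROC curve (class vs rest, scored by that class's
#' probability) via \pkg{pROC}, in tidy long form.
#'
#' @inheritParams macro_auc
#' @return data.frame with columns `class`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.factor(labels)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) colnames(scores) <- levels(labels)
  out <- lapply(levels(labels), function(cl) {
    pos <- labels == cl
    if (!any(pos) || all(pos)) return(NULL)
    r <- pROC::roc(response = pos, predictor = scores[, cl],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    data.frame(class = cl, fpr = rev(1 - r$specificities),
               tpr = rev(r$sensitivities), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Grid search by stratified cross-validation
#'
#' Evaluates every grid point by stratified k-fold cross-validation on the
#' training partition, scored by macro AUC, then refits the best
#' configuration on the full training partition. Ties keep the earlier
#' (simpler) grid point.
#'
#' @param x training feature matrix.
#' @param y training labels.
#' @param family classifier family code.
#' @param grid data.frame of hyperparameter candidates; default from
#'   [default_grids()].
#' @param cv_folds number of folds (default 5; reduced with a warning when
#'   a class is too small).
#' @param seed integer seed.
#' @return List with `model` (fitted on all of `x`), `best_params` and
#'   `cv_results` (grid plus mean CV macro AUC).
#' @export
grid_search_fit <- function(x, y, family, grid = NULL, cv_folds = 5,
                            seed = 1) {
  family <- match.arg(family, classifier_families())
  grid <- grid %||% default_grids()[[family]]
  if (nrow(grid) == 0) stop("hyperparameter grid is empty")
  y <- droplevels(as.factor(y))
  x <- as.matrix(x)
  cv_auc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    folds <- .make_folds(y, cv_folds, seed)
    for (i in seq_len(nrow(grid))) {
      params <- as.list(grid[i, , drop = FALSE])
      aucs <- vapply(folds, function(hold) {
        fit <- fit_classifier(family, x[-hold, , drop = FALSE], y[-hold],
                              params, seed = seed + 1000L * i)
        macro_auc(predict(fit, x[hold, , drop = FALSE]), y[hold])$macro
      }, numeric(1))
      cv_auc[i] <- mean(aucs, na.rm = TRUE)
    }
    best <- which.max(cv_auc)
  } else {
    best <- 1L
  }
  best_params <- as.list(grid[best, , drop = FALSE])
  model <- fit_classifier(family, x, y, best_params, seed = seed)
  list(model = model, best_params = best_params,
       cv_results = cbind(grid, cv_macro_auc = cv_auc))
}

# selection fitted on the training rows only, then applied to both
# partitions; optionally capped at max_features by decreasing F
.select_and_slice <- function(mat, labels, split, sel_cfg, max_features,
                              select_before_split = FALSE) {
  counts <- mat$counts
  sel_rows <- if (select_before_split) seq_len(nrow(counts)) else split$train
  sel <- anova_select(counts[sel_rows, , drop = FALSE],
                      labels = labels[sel_rows], config = sel_cfg)
  keep <- which(sel$kept)
  if (length(keep) > max_features) {
    keep <- keep[order(sel$f_stat[keep], decreasing = TRUE)][seq_len(max_features)]
    keep <- sort(keep)
  }
  if (length(keep) < 2) {
    # fall back to the strongest features so downstream fits stay defined
    # (every classifier family needs at least two feature columns)
    keep <- utils::head(order(sel$f_stat, decreasing = TRUE),
                        min(10L, length(sel$f_stat)))
    warning("fewer than 2 features passed selection; falling back to the ",
            "top ", length(keep), " features by F")
  }
  list(selection = sel, keep = keep,
       x_train = as.matrix(counts[split$train, keep, drop = FALSE]),
       x_test = as.matrix(counts[split$test, keep, drop = FALSE]))
}

# exact permutation p-value: (1 + #{null >= observed}) / (1 + n_perm)
.perm_pvalue <- function(observed, permuted) {
  (1 + sum(permuted >= observed)) / (1 + length(permuted))
}

#' Label-permutation significance of a fitted pipeline
#'
#' Significance of a model's test macro AUC against the null of no
#' label/feature association. Every permutation re-runs the full pipeline —
#' feature selection on the (permuted) training labels, model fit, test
#' macro AUC — so selection bias is included in the null.
#'
#' @param mat a `kmer_count_matrix`.
#' @param family classifier family code.
#' @param params hyperparameters used for every (re)fit.
#' @param split_cfg a [split_config()]; the partition is held fixed across
#'   permutations.
#' @param sel_cfg a [selection_config()].
#' @param n_perm number of permutations (>= 19).
#' @param seed integer seed.
#' @param max_features cap on selected features (by decreasing F).
#' @return List with `p_value`, `observed` macro AUC and the vector of
#'   permuted macro AUCs.
#' @export
permutation_pvalue <- function(mat, family, params = list(),
                               split_cfg = split_config(),
                               sel_cfg = selection_config(),
                               n_perm = 199, seed = 1, max_features = 2000) {
  if (n_perm < 19) stop("n_perm must be >= 19")
  labels <- factor(mat$labels)
  n <- length(labels)
  split <- stratified_split(labels, split_cfg)
  run_once <- function(lab, fit_seed) {
    sl <- .select_and_slice(mat, lab, split, sel_cfg, max_features)
    fit <- fit_classifier(family, sl$x_train, lab[split$train], params,
                          seed = fit_seed)
    macro_auc(predict(fit, sl$x_test), lab[split$test])$macro
  }
  # draw all permutations up front: fits reset the RNG internally.
  # labels are shuffled within each partition so that both sides keep all
  # classes (the partition itself is ancillary under the null)
  set.seed(seed)
  perm_idx <- lapply(seq_len(n_perm), function(b) {
    idx <- seq_len(n)
    idx[split$train] <- sample(split$train)
    idx[split$test] <- sample(split$test)
    idx
  })
  observed <- run_once(labels, seed)
  permuted <- vapply(seq_len(n_perm), function(b) {
    run_once(labels[perm_idx[[b]]], seed + b)
  }, numeric(1))
  list(p_value = .perm_pvalue(observed, permuted), observed = observed,
       permuted = permuted)
}

#' Evaluate classifier families on one k-mer dataset
#'
#' The per-dataset pipeline: one stratified 4:1 split; zero-count +
#' ANOVA selection fitted on the training partition and applied to both
#' partitions; per family a cross-validated grid search on the training
#' partition, a refit, and test-set macro / per-class AUC; optionally a
#' label-permutation p-value (for the top family only by default, to bound
#' runtime).
#'
#' @param mat a `kmer_count_matrix`.
#' @param families families to evaluate, default all seven.
#' @param sel_cfg a [selection_config()].
#' @param split_cfg a [split_config()] (its seed fixes the partition).
#' @param grids named list of grids overriding [default_grids()].
#' @param cv_folds folds for the grid search.
#' @param n_perm permutations for the p-value; 0 skips it.
#' @param perm_families `"best"` (permute only the top-AUC family),
#'   `"all"`, or `"none"`.
#' @param seed integer seed.
#' @param max_features cap on selected features (by decreasing F).
#' @param select_before_split fit selection on all rows before splitting (the
#'   reduce-then-split ordering); default `FALSE` keeps selection inside
#'   the training partition.
#' @param dataset_name label recorded in the report rows.
#' @return List with `report` (one row per family: `dataset`, `family`,
#'   `macro_auc`, `p_value`, `auc_H`, `auc_M`, `auc_S`, `best_params`,
#'   `n_features`), `roc` (long data.frame), `selection`, `split`,
#'   `models`.
#' @export
evaluate_dataset <- function(mat, families = classifier_families(),
                             sel_cfg = selection_config(),
                             split_cfg = split_config(),
                             grids = NULL, cv_folds = 5, n_perm = 199,
                             perm_families = c("best", "all", "none"),
                             seed = 1, max_features = 2000,
                             select_before_split = FALSE,
                             dataset_name = "dataset") {
  perm_families <- match.arg(perm_families)
  families <- match.arg(families, classifier_families(), several.ok = TRUE)
  labels <- factor(mat$labels)
  split <- stratified_split(labels, split_cfg)
  sl <- .select_and_slice(mat, labels, split, sel_cfg, max_features,
                          select_before_split = select_before_split)
  y_train <- labels[split$train]
  y_test <- labels[split$test]
  all_grids <- default_grids()
  if (!is.null(grids)) all_grids[names(grids)] <- grids

  rows <- list()
  roc_all <- list()
  models <- list()
  for (i in seq_along(families)) {
    fam <- families[i]
    gs <- grid_search_fit(sl$x_train, y_train, fam, grid = all_grids[[fam]],
                          cv_folds = cv_folds, seed = seed + 101L * i)
    prob <- predict(gs$model, sl$x_test)
    au <- macro_auc(prob, y_test)
    pc <- au$per_class
    names(pc) <- .state_display(names(pc))
    roc_df <- roc_points(prob, y_test)
    roc_df$family <- fam
    roc_df$dataset <- dataset_name
    roc_all[[fam]] <- roc_df
    models[[fam]] <- gs$model
    rows[[fam]] <- data.frame(
      dataset = dataset_name, family = fam, macro_auc = au$macro,
      p_value = NA_real_,
      auc_H = unname(pc["H"]), auc_M = unname(pc["M"]),
      auc_S = unname(pc["S"]),
      best_params = paste(names(gs$best_params),
                          unlist(gs$best_params, use.names = FALSE),
                          sep = "=", collapse = ";"),
      n_features = length(sl$keep), stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  if (n_perm > 0 && perm_families != "none") {
    targets <- if (perm_families == "all") seq_len(nrow(report)) else
      which.max(report$macro_auc)
    for (ti in targets) {
      fam <- report$family[ti]
      pv <- permutation_pvalue(mat, fam, models[[fam]]$params,
                               split_cfg = split_cfg, sel_cfg = sel_cfg,
                               n_perm = n_perm,
                               seed = seed + 7919L, max_features = max_features)
      report$p_value[ti] <- pv$p_value
    }
  }
  list(report = report, roc = do.call(rbind, roc_all),
       selection = sl$selection, split = split, models = models)
}

#' Best-model summary table
#'
#' Per dataset, picks the highest-macro-AUC family whose permutation
#' p-value is below `alpha`; ties break by the fixed family order
#' LR < SVM < MLP < KNN < DC < RF < XGB (simpler first). Datasets with no
#' significant model report their best family flagged as not significant.
#' Rows are shaped `kmer, Model, macro_AUC, p_value, H, M, S`; the global
#' best significant row is flagged `best_overall`.
#'
#' @param reports data.frame as produced by [evaluate_dataset()] (rows from
#'   several datasets may be concatenated).
#' @param alpha significance level for the permutation p-value gate.
#' @return data.frame with one row per dataset.
#' @export
best_model_table <- function(reports, alpha = 0.05) {
  fam_rank <- stats::setNames(seq_along(classifier_families()),
                              classifier_families())
  out <- lapply(unique(reports$dataset), function(ds) {
    rows <- reports[reports$dataset == ds, , drop = FALSE]
    sig <- !is.na(rows$p_value) & rows$p_value < alpha
    cand <- if (any(sig)) rows[sig, , drop = FALSE] else rows
    ord <- order(-cand$macro_auc, fam_rank[cand$family])
    top <- cand[ord[1], , drop = FALSE]
    data.frame(kmer = ds, Model = top$family, macro_AUC = top$macro_auc,
               p_value = top$p_value, H = top$auc_H, M = top$auc_M,
               S = top$auc_S, significant = any(sig),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$best_overall <- FALSE
  sig_rows <- which(out$significant)
  pool <- if (length(sig_rows) > 0) sig_rows else seq_len(nrow(out))
  out$best_overall[pool[which.max(out$macro_AUC[pool])]] <- TRUE
  rownames(out) <- NULL
  out
}

#' Shared high-importance k-mers across cell subsets
#'
#' Intersects the top-N most important k-mers of every pair of subsets —
#' shared concatemers point at CDR3 structural similarity between subsets.
#' Importance defaults to the ANOVA F ranking ([top_features()]) but any
#' ranked table works.
#'
#' @param selected named list (one entry per subset) of data.frames with
#'   columns `feature` and optionally `rank` (row order is used if absent),
#'   or plain character vectors in rank order.
#' @param top_n how many top features per subset to intersect (default 50).
#' @return data.frame with columns `subset_a`, `subset_b`, `kmer`,
#'   `rank_a`, `rank_b`, one row per shared k-mer and subset pair.
#' @export
shared_kmer_analysis <- function(selected, top_n = 50) {
  stopifnot(length(selected) >= 2)
  tops <- lapply(selected, function(s) {
    feats <- if (is.character(s)) s else as.character(s$feature)
    utils::head(feats, top_n)
  })
  subs <- names(tops) %||% paste0("subset", seq_along(tops))
  pairs <- utils::combn(seq_along(tops), 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- tops[[pr[1]]]
    b <- tops[[pr[2]]]
    shared <- intersect(a, b)
    if (length(shared) == 0) return(NULL)
    data.frame(subset_a = subs[pr[1]], subset_b = subs[pr[2]],
               kmer = shared, rank_a = match(shared, a),
               rank_b = match(shared, b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(subset_a = character(0), subset_b = character(0),
                      kmer = character(0), rank_a = integer(0),
                      rank_b = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
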