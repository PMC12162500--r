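test_that("stratified split is a deterministic, proportion-preserving partition", {
  labels <- factor(rep(0:2, times = c(40, 30, 30)))
  cfg <- split_config(train_fraction = 0.8, seed = 7)
  sp <- stratified_split(labels, cfg)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(length(sp$train), 80)
  tr_tab <- table(labels[sp$train])
  expect_equal(unname(as.vector(tr_tab)), c(32, 24, 24))

  sp2 <- stratified_split(labels, cfg)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(labels, split_config(seed = 8))
  expect_false(identical(sp$train, sp3$train))

  expect_error(stratified_split(factor(c(0, 0, 1)),
                                split_config(seed = 1)), "fewer than 2")
  expect_error(split_config(train_fraction = 1.2), "train_fraction")
})

test_that("macro AUC is the exact mean of one-vs-rest per-class AUCs", {
  set.seed(5)
  n <- 60
  labels <- factor(sample(0:2, n, replace = TRUE))
  scores <- matrix(runif(n * 3), ncol = 3)
  scores <- scores / rowSums(scores)
  colnames(scores) <- levels(labels)
  au <- macro_auc(scores, labels)
  expect_equal(au$macro, mean(au$per_class), tolerance = 1e-12)
  expect_true(all(au$per_class >= 0 & au$per_class <= 1))
})

test_that("macro AUC matches toy examples and the concordant-pair oracle", {
  # perfectly ranked scores
  labels <- factor(c(0, 0, 1, 1, 2, 2))
  perfect <- rbind(c(.8, .1, .1), c(.9, .05, .05), c(.1, .8, .1),
                   c(.2, .7, .1), c(.05, .15, .8), c(.1, .2, .7))
  colnames(perfect) <- levels(labels)
  au <- macro_auc(perfect, labels)
  expect_equal(au$macro, 1.0)
  expect_equal(unname(au$per_class), c(1, 1, 1))

  # binary toy: all four positive/negative pairs concordant
  y <- factor(c(1, 1, 0, 0), levels = c(0, 1))
  s <- cbind(`0` = 1 - c(.9, .8, .7, .1), `1` = c(.9, .8, .7, .1))
  expect_equal(macro_auc(s, y)$per_class[["1"]], 1.0)

  # random binary toys, including ties, against exhaustive pair counting
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(6:25, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(y) || !any(y)) next
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    got <- macro_auc(cbind(`FALSE` = 1 - s, `TRUE` = s), factor(y))
    expect_equal(got$per_class[["TRUE"]], oracle_pair_auc(s, y))
    expect_equal(got$per_class[["FALSE"]], oracle_pair_auc(1 - s, !y))
  }
})

test_that("rank-based per-class AUC agrees with pROC", {
  set.seed(23)
  labels <- factor(sample(0:2, 80, replace = TRUE))
  scores <- matrix(rexp(240), ncol = 3)
  scores <- scores / rowSums(scores)
  colnames(scores) <- levels(labels)
  au <- macro_auc(scores, labels)
  for (cl in levels(labels)) {
    ref <- as.numeric(pROC::auc(
      response = labels == cl, predictor = scores[, cl],
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE))
    expect_equal(unname(au$per_class[cl]), ref, tolerance = 1e-12)
  }
  rp <- roc_points(scores, labels)
  expect_true(all(rp$fpr >= 0 & rp$fpr <= 1 & rp$tpr >= 0 & rp$tpr <= 1))
  expect_equal(sort(unique(rp$class)), levels(labels))
})

test_that("an absent class yields NA per-class AUC and a warned macro", {
  labels <- factor(c(0, 0, 1, 1), levels = c(0, 1, 2))
  s <- matrix(1 / 3, 4, 3, dimnames = list(NULL, levels(labels)))
  expect_warning(au <- macro_auc(s, labels), "absent")
  expect_true(is.na(au$per_class[["2"]]))
  expect_equal(au$macro, mean(au$per_class[1:2]))
})

test_that("grid search returns the single point of a trivial grid and is seeded", {
  g <- small_benchmark(seed = 3, n_samples = 6, cells = 40)
  m <- build_count_matrix(g$records, 2)
  sel <- anova_select(m)
  x <- as.matrix(m$counts[, sel$kept, drop = FALSE])
  y <- factor(m$labels)

  single <- data.frame(cp = 0.01)
  gs <- grid_search_fit(x, y, "DC", grid = single, seed = 4)
  expect_equal(gs$best_params$cp, 0.01)

  gs_rf1 <- grid_search_fit(x, y, "RF", cv_folds = 3, seed = 11)
  gs_rf2 <- grid_search_fit(x, y, "RF", cv_folds = 3, seed = 11)
  expect_identical(gs_rf1$best_params, gs_rf2$best_params)
  p1 <- predict(gs_rf1$model, x)
  p2 <- predict(gs_rf2$model, x)
  expect_identical(p1, p2)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-8))

  # separable synthetic data is learned almost perfectly
  expect_gte(max(gs_rf1$cv_results$cv_macro_auc), 0.95)
})

test_that("every classifier family fits, predicts proper probabilities, and is reproducible", {
  g <- small_benchmark(seed = 19, n_samples = 5, cells = 40)
  m <- build_count_matrix(g$records, 2)
  sel <- anova_select(m)
  keep <- which(sel$kept)
  y <- factor(m$labels)
  sp <- stratified_split(y, split_config(seed = 2))
  x_tr <- as.matrix(m$counts[sp$train, keep, drop = FALSE])
  x_te <- as.matrix(m$counts[sp$test, keep, drop = FALSE])
  for (fam in classifier_families()) {
    fit <- fit_classifier(fam, x_tr, y[sp$train], seed = 5)
    pr <- predict(fit, x_te)
    expect_equal(dim(pr), c(length(sp$test), 3))
    expect_equal(colnames(pr), levels(y))
    expect_true(all(pr >= 0))
    expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-6)
    fit2 <- fit_classifier(fam, x_tr, y[sp$train], seed = 5)
    expect_equal(predict(fit2, x_te), pr, tolerance = 1e-12)
  }
})

test_that("permutation p-value formula matches its exact cases", {
  perm_p <- cdr3kmer:::.perm_pvalue
  expect_equal(perm_p(0.9, rep(0.5, 99)), 0.01)    # beats all 99
  expect_equal(perm_p(0.2, rep(0.9, 19)), 1.0)     # worst of 19
  expect_equal(perm_p(0.7, c(rep(0.5, 95), rep(0.8, 4))), 0.05)
  expect_equal(perm_p(0.7, rep(0.7, 19)), 1.0)     # ties count against
  expect_error(permutation_pvalue(list(), "RF", n_perm = 5), "n_perm")
})

test_that("permutation test separates signal from null on a small benchmark", {
  g <- small_benchmark(seed = 29, n_samples = 8, cells = 40)
  m <- build_count_matrix(g$records, 2)
  pv <- permutation_pvalue(m, "RF", params = list(mtry_frac = 0.05),
                           split_cfg = split_config(seed = 3),
                           n_perm = 19, seed = 31)
  expect_lte(pv$p_value, 0.1)     # strong signal: observed beats the null
  expect_gt(pv$observed, 0.9)
  expect_length(pv$permuted, 19)
  expect_true(pv$p_value >= 1 / 20 && pv$p_value <= 1)

  pv2 <- permutation_pvalue(m, "RF", params = list(mtry_frac = 0.05),
                            split_cfg = split_config(seed = 3),
                            n_perm = 19, seed = 31)
  expect_identical(pv, pv2)
})

test_that("best_model_table applies the significance gate and fixed tie-break", {
  reports <- data.frame(
    dataset = c("kmer2", "kmer2", "kmer3", "kmer3", "kmer4"),
    family = c("RF", "XGB", "XGB", "LR", "MLP"),
    macro_auc = c(0.90, 0.95, 0.88, 0.88, 0.70),
    p_value = c(0.01, 0.20, 0.01, 0.01, 0.30),
    auc_H = 0.9, auc_M = 0.9, auc_S = 0.9, stringsAsFactors = FALSE)
  tab <- best_model_table(reports, alpha = 0.05)
  # significance gate: kmer2 prefers the significant 0.90 over 0.95
  expect_equal(tab$Model[tab$kmer == "kmer2"], "RF")
  expect_true(tab$significant[tab$kmer == "kmer2"])
  # AUC tie on kmer3 resolves to the simpler family (LR before XGB)
  expect_equal(tab$Model[tab$kmer == "kmer3"], "LR")
  # no significant model: best AUC reported but flagged
  expect_false(tab$significant[tab$kmer == "kmer4"])
  expect_equal(sum(tab$best_overall), 1)
  expect_equal(tab$kmer[tab$best_overall], "kmer2")

  single <- best_model_table(reports[1, , drop = FALSE])
  expect_equal(nrow(single), 1)
  expect_equal(single$Model, "RF")
})

test_that("shared k-mer analysis intersects top lists pairwise", {
  sel <- list(B1 = c("A", "B", "C"), B2 = c("B", "C", "D"))
  out <- shared_kmer_analysis(sel, top_n = 3)
  expect_equal(sort(out$kmer), c("B", "C"))
  expect_equal(out$rank_a[out$kmer == "B"], 2L)
  expect_equal(out$rank_b[out$kmer == "B"], 1L)

  disjoint <- shared_kmer_analysis(list(a = c("A"), b = c("B")), top_n = 5)
  expect_equal(nrow(disjoint), 0)

  # a motif planted in two subsets' repertoires shows up as shared
  cfg <- sim_config(n_samples_per_class = 6, cells_per_sample = 40,
                    subsets = c("B1", "B2"), seed = 37)
  g <- generate_repertoire(cfg)
  ranked <- lapply(c("B1", "B2"), function(sb) {
    m <- build_count_matrix(g$records, 3, subset = sb)
    top_features(anova_select(m), n = 25)
  })
  names(ranked) <- c("B1", "B2")
  shared <- shared_kmer_analysis(ranked, top_n = 25)
  expect_true(all(default_motifs()$motif %in% shared$kmer))
})

test_that("evaluate_dataset produces a coherent, reproducible report", {
  g <- small_benchmark(seed = 41, n_samples = 5, cells = 40)
  m <- build_count_matrix(g$records, 2)
  ev <- evaluate_dataset(m, families = c("DC", "RF"),
                         split_cfg = split_config(seed = 5),
                         n_perm = 19, seed = 9, dataset_name = "kmer2")
  expect_equal(ev$report$dataset, c("kmer2", "kmer2"))
  expect_equal(ev$report$family, c("DC", "RF"))
  expect_true(all(ev$report$macro_auc >= 0 & ev$report$macro_auc <= 1))
  best_row <- which.max(ev$report$macro_auc)
  expect_false(is.na(ev$report$p_value[best_row]))
  expect_true(all(c("fpr", "tpr", "family") %in% names(ev$roc)))

  ev2 <- evaluate_dataset(m, families = c("DC", "RF"),
                          split_cfg = split_config(seed = 5),
                          n_perm = 19, seed = 9, dataset_name = "kmer2")
  expect_identical(ev$report, ev2$report)
})
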