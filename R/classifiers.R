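#' The seven classifier families
#'
#' Fixed family codes, in the tie-break order used by [best_model_table()]
#' (simpler families first): logistic regression (LR), support vector
#' machine (SVM), multilayer perceptron (MLP), k-nearest neighbours (KNN),
#' decision tree (DC), random forest (RF), gradient boosting (XGB).
#'
#' @return Character vector of family codes.
#' @export
classifier_families <- function() {
  c("LR", "SVM", "MLP", "KNN", "DC", "RF", "XGB")
}

#' Default hyperparameter grids
#'
#' Deliberately small grids (at most six points per family) so that a full
#' sweep of seven datasets times seven families stays at desk scale; any
#' grid can be overridden per family. `quick = TRUE` collapses each grid to
#' a single sensible point.
#'
#' @param quick use single-point grids.
#' @return Named list of data.frames, one per family.
#' @export
default_grids <- function(quick = FALSE) {
  grids <- list(
    LR  = expand.grid(lambda = c(0.01, 0.1, 1)),
    SVM = expand.grid(cost = c(0.1, 1, 10)),
    MLP = expand.grid(size = 4, decay = c(0.1, 1)),
    KNN = expand.grid(k = c(3, 5, 7)),
    DC  = expand.grid(cp = c(0.01, 0.001)),
    RF  = expand.grid(mtry_frac = c(0.05, 0.25), ntree = 300),
    XGB = expand.grid(max_depth = c(3, 6), eta = 0.3, nrounds = 60)
  )
  if (quick) grids <- lapply(grids, function(g) g[1, , drop = FALSE])
  grids
}

.softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Fit one classifier family
#'
#' Uniform wrapper over the seven families. Families sensitive to feature
#' scale (SVM, MLP, KNN) are standardized internally using training means
#' and standard deviations (zero-variance columns get scale 1); tree
#' ensembles and the penalized regression use raw counts. All randomized
#' fits are seeded.
#'
#' @param family one of [classifier_families()].
#' @param x numeric matrix (rows = repertoires, columns = features).
#' @param y class labels (coerced to factor).
#' @param params named list of hyperparameters, one row of the family's
#'   grid (see [default_grids()]).
#' @param seed integer seed for randomized fits.
#' @return Object of class `cdr3kmer_model`; use `predict()` to obtain a
#'   per-class probability matrix.
#' @export
fit_classifier <- function(family, x, y, params = list(), seed = 1) {
  family <- match.arg(family, classifier_families())
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  scale_info <- NULL
  if (family %in% c("SVM", "MLP", "KNN")) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
    x <- scale(x, center = ctr, scale = scl)
    scale_info <- list(center = ctr, scale = scl)
  }
  fit <- switch(
    family,
    LR = glmnet::glmnet(x, y,
                        family = if (nlevels(y) > 2) "multinomial" else "binomial",
                        alpha = 0),
    SVM = e1071::svm(x, y, kernel = "radial",
                     cost = params$cost %||% 1,
                     gamma = params$gamma %||% (1 / ncol(x)),
                     scale = FALSE),
    MLP = nnet::nnet(x, nnet::class.ind(y),
                     size = params$size %||% 4,
                     decay = params$decay %||% 0.1,
                     maxit = params$maxit %||% 150,
                     softmax = TRUE, MaxNWts = 200000, trace = FALSE),
    KNN = caret::knn3(x, y, k = params$k %||% 5),
    DC = {
      df <- data.frame(.y = y, x, check.names = TRUE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     cp = params$cp %||% 0.01,
                     minsplit = params$minsplit %||% 5,
                     minbucket = params$minbucket %||% 2, xval = 0))
    },
    RF = {
      mtry <- max(1L, min(ncol(x), round((params$mtry_frac %||% 0.05) * ncol(x))))
      randomForest::randomForest(x, y, ntree = params$ntree %||% 300,
                                 mtry = mtry)
    },
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = nlevels(y),
                      max_depth = params$max_depth %||% 6,
                      eta = params$eta %||% 0.3,
                      nthread = 1,
                      seed = as.integer(seed) %% .Machine$integer.max),
        data = dtrain, nrounds = params$nrounds %||% 60, verbose = 0)
    }
  )
  structure(list(family = family, fit = fit, params = params,
                 levels = levels(y), features = colnames(x),
                 scale_info = scale_info, seed = seed),
            class = "cdr3kmer_model")
}

#' Per-class probability predictions
#'
#' Returns an n x classes matrix of scores summing to 1 per row, with
#' columns ordered and named by the training class levels. The SVM family
#' has no seedable native probabilities; its one-vs-one decision values are
#' aggregated per class and mapped through a softmax, a deterministic
#' monotone score-to-probability mapping (ranking, hence ROC/AUC, is
#' preserved).
#'
#' @param object a `cdr3kmer_model`.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return Numeric matrix of per-class scores (rows sum to 1).
#' @export
predict.cdr3kmer_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- object$features
  if (!is.null(object$scale_info)) {
    x <- scale(x, center = object$scale_info$center,
               scale = object$scale_info$scale)
  }
  lv <- object$levels
  prob <- switch(
    object$family,
    LR = {
      s <- object$params$lambda %||% 0.1
      pr <- predict(object$fit, newx = x, s = s, type = "response")
      if (length(dim(pr)) == 3) {
        m <- pr[, , 1, drop = TRUE]
        if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, dimnames(pr)[[2]]))
        m
      } else {
        p2 <- as.numeric(pr)   # binomial: P(second level)
        m <- cbind(1 - p2, p2)
        colnames(m) <- lv
        m
      }
    },
    SVM = {
      dv <- attr(predict(object$fit, x, decision.values = TRUE),
                 "decision.values")
      sc <- matrix(0, nrow(x), length(lv), dimnames = list(NULL, lv))
      for (cn in colnames(dv)) {
        pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
        sc[, pair[1]] <- sc[, pair[1]] + dv[, cn]
        sc[, pair[2]] <- sc[, pair[2]] - dv[, cn]
      }
      .softmax_rows(sc)
    },
    MLP = {
      m <- predict(object$fit, x, type = "raw")
      if (ncol(m) == 1) cbind(1 - m[, 1], m[, 1]) else m
    },
    KNN = predict(object$fit, x, type = "prob"),
    DC = predict(object$fit,
                 newdata = data.frame(x, check.names = TRUE),
                 type = "prob"),
    RF = predict(object$fit, x, type = "prob"),
    XGB = {
      m <- predict(object$fit, xgboost::xgb.DMatrix(x))
      if (is.null(dim(m))) m <- matrix(m, ncol = length(lv), byrow = TRUE)
      m
    }
  )
  prob <- as.matrix(prob)
  if (is.null(colnames(prob)) || !all(lv %in% colnames(prob))) {
    colnames(prob) <- lv
  }
  prob <- prob[, lv, drop = FALSE]
  prob[prob < 0] <- 0
  rs <- rowSums(prob)
  rs[rs == 0] <- 1
  prob / rs
}
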