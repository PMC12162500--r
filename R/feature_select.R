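#' Feature-selection configuration
#'
#' @param zero_fraction_threshold features are kept only if their fraction
#'   of zero counts across rows is strictly below this value. Default 0.95.
#' @param alpha one-way ANOVA significance level; features with p below
#'   `alpha` are retained. Default 0.05.
#' @param adjust multiple-testing adjustment of the ANOVA p-values:
#'   `"none"` (default, raw p) or `"benjamini_hochberg"`.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(zero_fraction_threshold = 0.95, alpha = 0.05,
                             adjust = c("none", "benjamini_hochberg")) {
  adjust <- match.arg(adjust)
  if (!is.numeric(zero_fraction_threshold) ||
      zero_fraction_threshold < 0 || zero_fraction_threshold > 1) {
    stop("zero_fraction_threshold must be in [0, 1]")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  structure(list(zero_fraction_threshold = zero_fraction_threshold,
                 alpha = alpha, adjust = adjust),
            class = "selection_config")
}

.counts_of <- function(x) {
  if (inherits(x, "kmer_count_matrix")) x$counts else x
}

#' Zero-count filter over features
#'
#' A feature passes iff its fraction of zero entries across rows is
#' strictly below `threshold` (so at threshold 0.9, a feature that is zero
#' in exactly 90% of rows is dropped).
#'
#' @param x a `kmer_count_matrix` or numeric matrix (rows = observations).
#' @param threshold zero-fraction cut-off in \[0, 1\].
#' @return Logical mask over features (`TRUE` = keep).
#' @export
zero_filter <- function(x, threshold = 0.95) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]")
  }
  m <- .counts_of(x)
  if (nrow(m) < 1) stop("matrix must have at least one row")
  nz <- if (inherits(m, "sparseMatrix")) {
    Matrix::colSums(m != 0)
  } else {
    colSums(m != 0)
  }
  zero_fraction <- 1 - nz / nrow(m)
  unname(zero_fraction < threshold)
}

# vectorized one-way ANOVA across all columns of (sparse) X
# returns f, p, df1, df2, degenerate via the standard sums-of-squares
# decomposition: SSB = sum_g n_g (m_g - m)^2, SSW = SST - SSB
.anova_f <- function(X, groups) {
  n <- nrow(X)
  g <- droplevels(as.factor(groups))
  if (length(g) != n) stop("labels length must match row count")
  ng <- nlevels(g)
  if (ng < 2) stop("ANOVA requires >= 2 groups")
  counts_g <- tabulate(g, nbins = ng)
  G <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(g), x = 1,
                            dims = c(n, ng))
  gsum <- as.matrix(Matrix::crossprod(G, X))          # ng x p group sums
  tot <- colSums(gsum)
  sumsq <- as.numeric(Matrix::colSums(X * X))
  sst <- pmax(sumsq - tot^2 / n, 0)
  ssb <- pmax(colSums(gsum^2 / counts_g) - tot^2 / n, 0)
  ssw <- pmax(sst - ssb, 0)
  df1 <- ng - 1
  df2 <- n - ng
  degenerate <- sst <= 1e-9 * pmax(tot^2 / n, 1)      # no variance at all
  f <- (ssb / df1) / (ssw / df2)
  f[ssw == 0 & ssb > 0] <- Inf
  f[degenerate] <- NA_real_
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[is.infinite(f)] <- 0
  list(f = f, p = p, df1 = df1, df2 = df2, degenerate = degenerate)
}

#' ANOVA-based feature selection
#'
#' Applies the zero-count filter, then a per-feature one-way ANOVA F test of
#' the counts across disease-state groups with `(g-1, n-g)` degrees of
#' freedom. A feature is kept iff it passes the zero filter, is not
#' degenerate (zero total variance), has a finite F, and its (optionally
#' BH-adjusted) p-value is below `alpha`.
#'
#' @param x a `kmer_count_matrix`, or a numeric matrix with `labels` given.
#' @param labels state label per row; taken from `x` when omitted.
#' @param config a [selection_config()].
#' @return Object of class `selection_result`: list with `feature` (names),
#'   `zero_fraction`, `f_stat`, `p_value`, `kept` (logical mask),
#'   `degenerate`, `df`, and the `config` snapshot.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
#' res <- anova_select(m, labels = c(0, 0, 1, 1, 2, 2))
#' res$f_stat   # 16, df (2, 3)
#' @export
anova_select <- function(x, labels = NULL, config = selection_config()) {
  m <- .counts_of(x)
  labels <- labels %||% (if (inherits(x, "kmer_count_matrix")) x$labels else
    stop("labels required for a plain matrix"))
  res <- .anova_f(m, labels)
  zf_pass <- zero_filter(m, config$zero_fraction_threshold)
  zero_fraction <- 1 - (if (inherits(m, "sparseMatrix"))
    Matrix::colSums(m != 0) else colSums(m != 0)) / nrow(m)
  p_adj <- res$p
  if (config$adjust == "benjamini_hochberg") {
    sel <- zf_pass & !res$degenerate
    p_adj[sel] <- stats::p.adjust(res$p[sel], method = "BH")
  }
  kept <- zf_pass & !res$degenerate & is.finite(res$f) & !is.na(p_adj) &
    p_adj < config$alpha
  structure(list(feature = colnames(m) %||% paste0("f", seq_len(ncol(m))),
                 zero_fraction = unname(zero_fraction),
                 f_stat = res$f, p_value = res$p, p_adjusted = p_adj,
                 kept = kept, degenerate = res$degenerate,
                 df = c(res$df1, res$df2), config = config),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result: ", sum(x$kept), " of ", length(x$kept),
      " features kept (zero-fraction < ", x$config$zero_fraction_threshold,
      ", ANOVA p < ", x$config$alpha, ", df = ", x$df[1], ",", x$df[2],
      ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.selection_result <- function(x, ...) {
  data.frame(feature = x$feature, zero_fraction = x$zero_fraction,
             F = x$f_stat, p = x$p_value, kept = x$kept,
             stringsAsFactors = FALSE)
}

#' Features ranked by discriminative strength
#'
#' Orders features passing the zero filter (and not degenerate) by
#' decreasing ANOVA F statistic — the package's default importance ranking,
#' used by the shared-motif analysis and planted-motif recovery checks.
#'
#' @param selection a `selection_result`.
#' @param n number of top features to return; `Inf` for all ranked features.
#' @return data.frame with `feature`, `f_stat`, `rank`.
#' @export
top_features <- function(selection, n = 50) {
  ok <- which(!selection$degenerate & is.finite(selection$f_stat) &
                selection$zero_fraction <
                  selection$config$zero_fraction_threshold)
  ord <- ok[order(selection$f_stat[ok], decreasing = TRUE)]
  if (is.finite(n)) ord <- utils::head(ord, n)
  data.frame(feature = selection$feature[ord],
             f_stat = selection$f_stat[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
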