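#' Enumerate the complete k-mer feature space
#'
#' Builds the ordered enumeration of every amino-acid concatemer for a set of
#' k values over an alphabet: `|alphabet|^k` columns per k (400 for k=2,
#' 8000 for k=3, 160000 for k=4 over the 20 standard letters). Columns are
#' lexicographic within each k block and blocks appear in ascending k order,
#' so the mapping concatemer -> column index is deterministic.
#'
#' @param ks integer vector of k values (>= 1), duplicates ignored.
#' @param alphabet ordered letters, default [AA_ALPHABET].
#' @return An object of class `feature_space`: list with `ks`, `alphabet`,
#'   `block_sizes`, `offsets` (0-based start of each k block), `columns`
#'   (all concatemer strings in column order) and `n_columns`.
#' @examples
#' fs <- enumerate_feature_space(2)
#' fs$n_columns            # 400
#' head(fs$columns, 3)     # "AA" "AC" "AD"
#' @export
enumerate_feature_space <- function(ks, alphabet = AA_ALPHABET) {
  if (length(ks) == 0) stop("ks must be non-empty")
  ks <- sort(unique(as.integer(ks)))
  if (any(ks < 1)) stop("all k values must be >= 1")
  if (length(alphabet) == 0) stop("alphabet must be non-empty")
  key <- paste(paste(ks, collapse = ","), paste(alphabet, collapse = ""),
               sep = "|")
  cached <- get0(key, envir = .fs_cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  a <- length(alphabet)
  block_sizes <- a^ks
  offsets <- cumsum(c(0, block_sizes[-length(block_sizes)]))
  names(block_sizes) <- names(offsets) <- as.character(ks)
  columns <- unlist(lapply(ks, function(k) {
    args <- rev(rep(list(alphabet), k))
    g <- do.call(expand.grid, c(args, list(stringsAsFactors = FALSE,
                                           KEEP.OUT.ATTRS = FALSE)))
    do.call(paste0, rev(g))
  }), use.names = FALSE)
  out <- structure(list(ks = ks, alphabet = alphabet,
                        block_sizes = block_sizes, offsets = offsets,
                        columns = columns, n_columns = sum(block_sizes)),
                   class = "feature_space")
  assign(key, out, envir = .fs_cache)
  out
}

# session cache: the enumeration is deterministic, so re-requests of the
# same (ks, alphabet) reuse the stored object
.fs_cache <- new.env(parent = emptyenv())

#' @export
print.feature_space <- function(x, ...) {
  cat("feature_space: k = {", paste(x$ks, collapse = ","), "}, ",
      length(x$alphabet), "-letter alphabet, ", x$n_columns, " columns\n",
      sep = "")
  invisible(x)
}

#' Segment a sequence into overlapping k-mers
#'
#' Returns every sliding window of length `k` (step 1) in left-to-right
#' order. Windows containing characters outside the alphabet are omitted,
#' which keeps the downstream feature space at exactly `|alphabet|^k`.
#'
#' @param seq a single amino-acid string.
#' @param k window length (>= 1).
#' @param alphabet allowed letters, default [AA_ALPHABET].
#' @return Character vector of k-mers (possibly empty).
#' @examples
#' segment_kmers("CASSLG", 3)  # "CAS" "ASS" "SSL" "SLG"
#' @export
segment_kmers <- function(seq, k, alphabet = AA_ALPHABET) {
  if (length(k) != 1 || is.na(k) || k < 1) stop("k must be a single integer >= 1")
  stopifnot(length(seq) == 1)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < k) return(character(0))
  ok <- chars %in% alphabet
  starts <- seq_len(n - k + 1)
  valid <- vapply(starts, function(i) all(ok[i:(i + k - 1)]), logical(1))
  vapply(starts[valid], function(i) paste(chars[i:(i + k - 1)], collapse = ""),
         character(1))
}

# encode the sliding windows of one integer-coded sequence as 0-based k-mer
# codes in base |alphabet|; windows touching non-alphabet characters -> NA
.window_codes <- function(codes0, k, a) {
  n <- length(codes0)
  if (n < k) return(integer(0))
  if (k == 1) return(codes0)
  m <- stats::embed(codes0, k)            # row j = x[j+k-1], ..., x[j]
  as.vector(m %*% a^(0:(k - 1)))
}

#' Build a zero-filled k-mer count matrix per sample
#'
#' Aggregates k-mer occurrences of all CDR3 sequences of each
#' (sample, subset) repertoire into a count matrix over the complete
#' feature space. Every concatemer of the space has a column; concatemers
#' never observed hold count 0. Storage is sparse; the zero-filled contract
#' is semantic.
#'
#' @param records annotated records (columns `cdr3aa`, `sample_id`,
#'   `subset`, `state`).
#' @param ks integer vector of k values.
#' @param subset cell-subset label to restrict to; required when records
#'   span several subsets.
#' @param alphabet letters, default [AA_ALPHABET].
#' @param feature_space optional pre-built [enumerate_feature_space()] result
#'   for `ks` (reused to avoid re-enumeration in tight loops).
#' @return Object of class `kmer_count_matrix`: list with `counts` (sparse
#'   dgCMatrix, rows = samples, columns = feature space), `row_keys`
#'   (data.frame `sample_id`, `subset`), `labels` (integer state per row)
#'   and `feature_space`.
#' @export
build_count_matrix <- function(records, ks, subset = NULL,
                               alphabet = AA_ALPHABET, feature_space = NULL) {
  if (!is.null(subset)) {
    records <- records[records$subset == subset, , drop = FALSE]
  } else {
    subs <- unique(records$subset)
    if (length(subs) > 1) {
      stop("records span several subsets (", paste(subs, collapse = ", "),
           "); pass `subset` to select one")
    }
    subset <- if (length(subs) == 1) subs else NA_character_
  }
  fs <- feature_space %||% enumerate_feature_space(ks, alphabet)
  if (!identical(fs$alphabet, alphabet) ||
      !identical(fs$ks, sort(unique(as.integer(ks))))) {
    stop("feature_space does not match the requested ks/alphabet")
  }
  a <- length(alphabet)

  samples <- sort(unique(records$sample_id))
  labels <- integer(length(samples))
  for (i in seq_along(samples)) {
    st <- unique(records$state[records$sample_id == samples[i]])
    if (length(st) > 1) {
      stop("sample '", samples[i], "' has conflicting state labels: ",
           paste(st, collapse = ", "))
    }
    labels[i] <- if (length(st) == 1) as.integer(st) else NA_integer_
  }

  if (nrow(records) == 0) {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0),
                                   dims = c(0L, fs$n_columns))
    colnames(counts) <- fs$columns
    return(structure(list(counts = counts,
                          row_keys = data.frame(sample_id = character(0),
                                                subset = character(0),
                                                stringsAsFactors = FALSE),
                          labels = integer(0), feature_space = fs),
                     class = "kmer_count_matrix"))
  }

  row_of_seq <- match(records$sample_id, samples)
  coded <- lapply(strsplit(records$cdr3aa, "", fixed = TRUE),
                  function(ch) match(ch, alphabet) - 1L)
  ii <- vector("list", length(fs$ks))
  jj <- vector("list", length(fs$ks))
  for (b in seq_along(fs$ks)) {
    k <- fs$ks[b]
    off <- fs$offsets[[b]]
    per_seq <- lapply(coded, .window_codes, k = k, a = a)
    len <- lengths(per_seq)
    j <- unlist(per_seq, use.names = FALSE)
    i <- rep.int(row_of_seq, len)
    keep <- !is.na(j)
    ii[[b]] <- i[keep]
    jj[[b]] <- off + j[keep] + 1
  }
  i_all <- unlist(ii, use.names = FALSE)
  j_all <- unlist(jj, use.names = FALSE)
  counts <- Matrix::sparseMatrix(i = i_all, j = j_all,
                                 x = rep.int(1, length(i_all)),
                                 dims = c(length(samples), fs$n_columns))
  colnames(counts) <- fs$columns
  rownames(counts) <- samples
  structure(list(counts = counts,
                 row_keys = data.frame(sample_id = samples,
                                       subset = subset,
                                       stringsAsFactors = FALSE),
                 labels = labels, feature_space = fs),
            class = "kmer_count_matrix")
}

#' @export
print.kmer_count_matrix <- function(x, ...) {
  cat("kmer_count_matrix: ", nrow(x$counts), " repertoire(s) x ",
      ncol(x$counts), " concatemers (k = {",
      paste(x$feature_space$ks, collapse = ","), "}), ",
      length(x$counts@x), " non-zero entries\n", sep = "")
  invisible(x)
}

#' @export
dim.kmer_count_matrix <- function(x) dim(x$counts)

#' Concatenate k-mer count matrices column-wise
#'
#' Combines matrices built over disjoint k values for identical rows into a
#' single matrix whose feature space is the union of the inputs (k blocks in
#' ascending order).
#'
#' @param matrices list of `kmer_count_matrix` objects with identical
#'   `row_keys` and labels and disjoint k sets.
#' @return A combined `kmer_count_matrix`.
#' @export
combine_kmer_datasets <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  if (length(matrices) == 1) return(matrices[[1]])
  ord <- order(vapply(matrices, function(m) min(m$feature_space$ks), numeric(1)))
  matrices <- matrices[ord]
  all_ks <- unlist(lapply(matrices, function(m) m$feature_space$ks))
  if (anyDuplicated(all_ks)) stop("k values of inputs must be disjoint")
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(m$row_keys, ref$row_keys) ||
        !identical(m$labels, ref$labels)) {
      stop("row keys / labels of inputs do not align")
    }
    if (!identical(m$feature_space$alphabet, ref$feature_space$alphabet)) {
      stop("alphabets of inputs differ")
    }
  }
  counts <- Reduce(Matrix::cbind2, lapply(matrices, function(m) m$counts))
  fs <- enumerate_feature_space(all_ks, ref$feature_space$alphabet)
  colnames(counts) <- fs$columns
  rownames(counts) <- rownames(ref$counts)
  structure(list(counts = counts, row_keys = ref$row_keys,
                 labels = ref$labels, feature_space = fs),
            class = "kmer_count_matrix")
}

#' Assemble one dataset per non-empty combination of k values
#'
#' For the default `ks = c(2, 3, 4)` this yields the seven datasets
#' `kmer2, kmer3, kmer4, kmer2_3, kmer2_4, kmer3_4, kmer2_3_4`: every
#' non-empty subset of the k values, ordered by size then lexicographically.
#' Single-k matrices are counted once and combined, so the cost is linear in
#' the number of k values.
#'
#' @inheritParams build_count_matrix
#' @return Named list of `kmer_count_matrix` objects.
#' @export
seven_datasets <- function(records, ks = c(2, 3, 4), subset = NULL,
                           alphabet = AA_ALPHABET) {
  ks <- sort(unique(as.integer(ks)))
  singles <- lapply(ks, function(k)
    build_count_matrix(records, k, subset = subset, alphabet = alphabet))
  names(singles) <- as.character(ks)
  combos <- list()
  for (size in seq_along(ks)) {
    sets <- utils::combn(ks, size, simplify = FALSE)
    for (s in sets) {
      nm <- paste0("kmer", paste(s, collapse = "_"))
      combos[[nm]] <- combine_kmer_datasets(singles[as.character(s)])
    }
  }
  combos
}

#' Export a count matrix as MatrixMarket plus sidecar tables
#'
#' Writes `counts.mtx` (MatrixMarket), `columns.txt` (one concatemer per
#' line, in column order) and `rows.csv` (`sample_id,subset,state`).
#'
#' @param x a `kmer_count_matrix`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_count_matrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(x$counts, mtx)
  cols <- file.path(dir, "columns.txt")
  writeLines(x$feature_space$columns, cols)
  rows <- file.path(dir, "rows.csv")
  utils::write.csv(cbind(x$row_keys, state = x$labels), rows,
                   row.names = FALSE, quote = FALSE)
  invisible(c(counts = mtx, columns = cols, rows = rows))
}
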