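# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# naive dictionary count of valid overlapping k-mers across sequences
naive_kmer_counts <- function(seqs, k, alphabet = cdr3kmer::AA_ALPHABET) {
  valid <- paste0("^[", paste(alphabet, collapse = ""), "]+$")
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substring(s, i, i + k - 1)
      if (grepl(valid, w)) {
        counts[[w]] <- (counts[[w]] %||% 0) + 1
      }
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) out <- stats::setNames(numeric(0), character(0))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# classical one-way ANOVA F per column via stats::oneway.test
oracle_oneway_f <- function(x, g) {
  apply(x, 2, function(col) {
    stats::oneway.test(col ~ factor(g), var.equal = TRUE)$statistic
  })
}

# AUC by exhaustive concordant-pair counting (ties credit 0.5)
oracle_pair_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# minimal annotated record table
make_records <- function(cdr3aa, sample_id, state, subset = "sub1",
                         chain = "BCRH") {
  data.frame(
    cell_barcode = sprintf("bc%04d", seq_along(cdr3aa)),
    chain = rep_len(chain, length(cdr3aa)), cdr3aa = cdr3aa,
    sample_id = rep_len(sample_id, length(cdr3aa)),
    subset = rep_len(subset, length(cdr3aa)),
    state = rep_len(state, length(cdr3aa)), stringsAsFactors = FALSE)
}

# write a small AIRR-style TSV and return its path
write_airr_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small, fast synthetic benchmark used by several evaluation tests
small_benchmark <- function(seed, n_samples = 8, cells = 60,
                            insertion_prob = 0.9) {
  cfg <- cdr3kmer::sim_config(
    n_samples_per_class = n_samples, cells_per_sample = cells,
    class_motifs = cdr3kmer::default_motifs(insertion_prob), seed = seed)
  cdr3kmer::generate_repertoire(cfg)
}
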