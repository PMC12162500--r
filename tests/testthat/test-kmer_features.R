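test_that("segment_kmers slides a step-1 window and skips non-standard letters", {
  expect_equal(segment_kmers("CASSLG", 3), c("CAS", "ASS", "SSL", "SLG"))
  expect_equal(segment_kmers("A", 2), character(0))
  expect_equal(segment_kmers("CAXSL", 2), c("CA", "SL"))
  expect_equal(segment_kmers("AC", 1), c("A", "C"))
  expect_error(segment_kmers("CAS", 0), "k must be")
})

test_that("feature space enumeration has the exact cardinality and ordering", {
  expect_equal(enumerate_feature_space(2)$n_columns, 400)
  expect_equal(enumerate_feature_space(3)$n_columns, 8000)

  fs1 <- enumerate_feature_space(1)
  expect_equal(fs1$n_columns, 20)
  expect_equal(fs1$columns[1], "A")
  expect_equal(fs1$columns, AA_ALPHABET)

  # lexicographic within a block, blocks ascending in k
  fs <- enumerate_feature_space(c(3, 2))
  expect_equal(fs$ks, c(2L, 3L))
  block2 <- fs$columns[1:400]
  expect_equal(block2, sort(block2))
  expect_equal(fs$columns[401], "AAA")
  expect_equal(unname(fs$offsets), c(0, 400))

  # generalizes to other alphabets
  fs_dna <- enumerate_feature_space(2, alphabet = c("A", "C", "G", "T"))
  expect_equal(fs_dna$n_columns, 16)
  expect_equal(fs_dna$columns[1:4], c("AA", "AC", "AG", "AT"))
})

test_that("count matrix matches the worked two-sequence example", {
  rec <- make_records(c("CAS", "AS"), sample_id = "p1", state = 0)
  m <- build_count_matrix(rec, 2)
  expect_equal(dim(m), c(1L, 400L))
  expect_equal(unname(m$counts[1, "CA"]), 1)
  expect_equal(unname(m$counts[1, "AS"]), 2)
  expect_equal(sum(m$counts), 3)
  expect_equal(sum(m$counts != 0), 2)
})

test_that("count matrix equals the naive dictionary oracle on random instances", {
  set.seed(42)
  for (rep in 1:30) {
    n_seq <- sample(1:10, 1)
    seqs <- vapply(seq_len(n_seq), function(i) {
      len <- sample(1:15, 1)
      chars <- sample(c(AA_ALPHABET, "X"), len, replace = TRUE,
                      prob = c(rep(1, 20), 0.6))
      paste(chars, collapse = "")
    }, character(1))
    sample_of <- sample(c("p1", "p2"), n_seq, replace = TRUE)
    state_of <- c(p1 = 0, p2 = 2)
    rec <- make_records(seqs, sample_id = sample_of,
                        state = state_of[sample_of])
    k <- sample(1:3, 1)
    m <- build_count_matrix(rec, k)
    for (sid in m$row_keys$sample_id) {
      oracle <- naive_kmer_counts(seqs[sample_of == sid], k)
      row <- m$counts[match(sid, m$row_keys$sample_id), ]
      nz <- row[row != 0]
      expect_equal(sort(names(nz)), sort(names(oracle)))
      if (length(oracle)) {
        expect_equal(unname(nz[names(oracle)]), unname(oracle))
      }
    }
  }
})

test_that("row sums obey the window-count conservation law", {
  set.seed(7)
  seqs <- replicate(12, paste(sample(AA_ALPHABET, sample(3:14, 1),
                                     replace = TRUE), collapse = ""))
  rec <- make_records(seqs, sample_id = "p1", state = 1)
  for (k in 1:4) {
    m <- build_count_matrix(rec, k)
    expected <- sum(pmax(0, nchar(seqs) - k + 1))
    expect_equal(sum(m$counts), expected)
  }
})

test_that("counting is invariant to record order", {
  g <- small_benchmark(seed = 21, n_samples = 2, cells = 20)
  m1 <- build_count_matrix(g$records, c(2, 3))
  set.seed(3)
  m2 <- build_count_matrix(g$records[sample(nrow(g$records)), ], c(2, 3))
  expect_equal(m1$counts, m2$counts)
  expect_equal(m1$labels, m2$labels)
})

test_that("degenerate inputs and data errors are handled", {
  empty <- make_records(character(0), sample_id = character(0),
                        state = integer(0))
  m <- build_count_matrix(empty, 2)
  expect_equal(dim(m), c(0L, 400L))

  # two samples with disjoint sequences give rows with disjoint support
  rec <- make_records(c("AAAA", "CCCC"), sample_id = c("p1", "p2"),
                      state = c(0, 1))
  m2 <- build_count_matrix(rec, 2)
  support <- apply(as.matrix(m2$counts), 1, function(r) which(r != 0))
  expect_length(intersect(support[[1]], support[[2]]), 0)

  # conflicting state labels within one sample are a consistency error
  bad <- make_records(c("AAAA", "CCCC"), sample_id = "p1", state = c(0, 1))
  expect_error(build_count_matrix(bad, 2), "conflicting state")

  # several subsets require an explicit choice
  multi <- rbind(make_records("AAAA", "p1", 0, subset = "B1"),
                 make_records("CCCC", "p1", 0, subset = "B2"))
  expect_error(build_count_matrix(multi, 2), "subset")
})

test_that("dataset combination concatenates columns and checks alignment", {
  g <- small_benchmark(seed = 5, n_samples = 2, cells = 15)
  m2 <- build_count_matrix(g$records, 2)
  m3 <- build_count_matrix(g$records, 3)
  both <- combine_kmer_datasets(list(m2, m3))
  expect_equal(ncol(both$counts), 8400)
  expect_equal(both$feature_space$ks, c(2L, 3L))
  expect_equal(unname(both$counts[, "AA"]), unname(m2$counts[, "AA"]))
  expect_equal(unname(both$counts[, "AAA"]), unname(m3$counts[, "AAA"]))

  expect_identical(combine_kmer_datasets(list(m2)), m2)
  expect_error(combine_kmer_datasets(list(m2, m2)), "disjoint")

  m3_mis <- m3
  m3_mis$row_keys <- m3$row_keys[rev(seq_len(nrow(m3$row_keys))), ]
  expect_error(combine_kmer_datasets(list(m2, m3_mis)), "align")
})

test_that("seven_datasets builds every non-empty k combination", {
  g <- small_benchmark(seed = 6, n_samples = 2, cells = 10)
  ds <- seven_datasets(g$records, ks = c(2, 3, 4))
  expect_named(ds, c("kmer2", "kmer3", "kmer4", "kmer2_3", "kmer2_4",
                     "kmer3_4", "kmer2_3_4"))
  expect_equal(ncol(ds$kmer2_3_4$counts), 168400)
  expect_equal(length(seven_datasets(g$records, ks = c(2, 3))), 3)
  expect_equal(length(seven_datasets(g$records, ks = 2)), 1)
})

test_that("matrix export writes MatrixMarket plus aligned sidecars", {
  g <- small_benchmark(seed = 8, n_samples = 2, cells = 10)
  m <- build_count_matrix(g$records, 2)
  dir <- tempfile()
  paths <- export_count_matrix(m, dir)
  expect_true(all(file.exists(paths)))
  back <- Matrix::readMM(paths["counts"])
  expect_equal(as.matrix(back), unname(as.matrix(m$counts)))
  expect_equal(readLines(paths["columns"]), m$feature_space$columns)
  rows <- utils::read.csv(paths["rows"], stringsAsFactors = FALSE)
  expect_equal(rows$sample_id, m$row_keys$sample_id)
  expect_equal(rows$state, m$labels)
})
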