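#' Read per-cell CDR3 records from a repertoire table
#'
#' Reads an AIRR-rearrangement style table (TSV or CSV) of per-cell receptor
#' observations and returns cleaned CDR3 amino-acid records for one receptor
#' chain. Default column names follow the AIRR schema (`cell_id`, `locus`,
#' `junction_aa`); a `column_map` adapts other layouts.
#'
#' Cleaning rules:
#' * CDR3 strings are uppercased.
#' * Rows with empty or missing CDR3 are dropped and counted.
#' * Only rows for the requested `chain` are kept (locus `IGH` maps to the
#'   BCR heavy chain `BCRH`, `TRA` to the TCR alpha chain `TCRA`; literal
#'   `BCRH`/`TCRA` values are accepted too).
#' * Cells with several CDR3 entries keep the first occurrence; the surplus
#'   is counted.
#' * Sequences containing characters outside `alphabet` are kept by default
#'   (k-mers spanning such characters are skipped downstream); with
#'   `strict = TRUE` they are dropped instead.
#'
#' @param path path to a delimited table (`.tsv`/`.txt` tab, `.csv` comma).
#' @param chain receptor chain to load, `"BCRH"` or `"TCRA"`.
#' @param column_map named character vector mapping canonical names
#'   (`cell_barcode`, `chain`, `cdr3aa`) to source column names.
#' @param alphabet allowed amino-acid letters, default [AA_ALPHABET].
#' @param strict drop sequences containing non-alphabet characters.
#' @param dedupe_clonotypes collapse identical (cell-independent) CDR3
#'   sequences so each unique sequence appears once. Default `FALSE`: one
#'   record per cell.
#' @return A data.frame of records with columns `cell_barcode`, `chain`,
#'   `cdr3aa`, and a `load_report` attribute (named counts of input rows and
#'   every drop category).
#' @export
read_repertoire <- function(path, chain = c("BCRH", "TCRA"),
                            column_map = NULL, alphabet = AA_ALPHABET,
                            strict = FALSE, dedupe_clonotypes = FALSE) {
  chain <- match.arg(chain)
  tab <- .read_table_auto(path)
  cmap <- c(cell_barcode = "cell_id", chain = "locus", cdr3aa = "junction_aa")
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  missing_cols <- setdiff(unname(cmap), names(tab))
  if (length(missing_cols) > 0) {
    stop("repertoire table is missing required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (adjust column_map if the file uses different names)")
  }
  records_from_table(tab, chain = chain, column_map = cmap,
                     alphabet = alphabet, strict = strict,
                     dedupe_clonotypes = dedupe_clonotypes)
}

#' Build CDR3 records from an in-memory table
#'
#' Worker behind [read_repertoire()]; useful when the table is already loaded.
#'
#' @inheritParams read_repertoire
#' @param tab data.frame holding the repertoire table.
#' @return See [read_repertoire()].
#' @export
records_from_table <- function(tab, chain = c("BCRH", "TCRA"),
                               column_map = c(cell_barcode = "cell_id",
                                              chain = "locus",
                                              cdr3aa = "junction_aa"),
                               alphabet = AA_ALPHABET, strict = FALSE,
                               dedupe_clonotypes = FALSE) {
  chain <- match.arg(chain)
  n_input <- nrow(tab)
  chain_raw <- toupper(trimws(as.character(tab[[column_map[["chain"]]]])))
  locus_map <- c(IGH = "BCRH", TRA = "TCRA", BCRH = "BCRH", TCRA = "TCRA")
  chain_norm <- unname(locus_map[chain_raw])
  keep_chain <- !is.na(chain_norm) & chain_norm == chain
  n_other_chain <- sum(!keep_chain)

  rec <- data.frame(
    cell_barcode = as.character(tab[[column_map[["cell_barcode"]]]])[keep_chain],
    chain = chain,
    cdr3aa = toupper(trimws(as.character(tab[[column_map[["cdr3aa"]]]])[keep_chain])),
    stringsAsFactors = FALSE
  )

  empty <- is.na(rec$cdr3aa) | rec$cdr3aa == ""
  n_empty <- sum(empty)
  rec <- rec[!empty, , drop = FALSE]

  nonstd <- !grepl(paste0("^[", paste(alphabet, collapse = ""), "]*$"), rec$cdr3aa)
  n_nonstandard <- sum(nonstd)
  if (strict && n_nonstandard > 0) rec <- rec[!nonstd, , drop = FALSE]

  dup <- duplicated(rec$cell_barcode)
  n_dup_barcode <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]   # first entry wins

  if (dedupe_clonotypes) {
    dupseq <- duplicated(rec$cdr3aa)
    rec <- rec[!dupseq, , drop = FALSE]
  }
  rownames(rec) <- NULL
  attr(rec, "load_report") <- c(
    n_input = n_input, n_other_chain = n_other_chain,
    n_dropped_empty = n_empty, n_nonstandard = n_nonstandard,
    n_dropped_nonstandard = if (strict) n_nonstandard else 0L,
    n_duplicate_barcode = n_dup_barcode, n_records = nrow(rec)
  )
  rec
}

#' Join CDR3 records with cell annotations
#'
#' Inner-joins per-cell CDR3 records with a metadata table mapping cell
#' barcode to sample, cell-subset label and disease state. Only barcodes
#' present in both inputs survive; the number of unmatched barcodes on each
#' side is recorded in the `join_report` attribute.
#'
#' @param records data.frame from [read_repertoire()].
#' @param metadata data.frame with columns `barcode` (or `cell_barcode` /
#'   `cell_id`), `sample_id`, `subset`, `state`. Barcodes must be unique.
#' @param state_labels named map from state strings to classes 0/1/2, see
#'   [default_state_labels()]. Numeric states pass through unchanged.
#' @return A data.frame of annotated records (`cell_barcode`, `chain`,
#'   `cdr3aa`, `sample_id`, `subset`, `state`).
#' @export
join_annotations <- function(records, metadata,
                             state_labels = default_state_labels()) {
  bc_col <- intersect(c("barcode", "cell_barcode", "cell_id"), names(metadata))[1]
  if (is.na(bc_col)) stop("metadata must have a 'barcode' column")
  for (col in c("sample_id", "subset", "state")) {
    if (!col %in% names(metadata)) stop("metadata is missing column: ", col)
  }
  bc <- as.character(metadata[[bc_col]])
  if (anyDuplicated(bc)) {
    offenders <- unique(bc[duplicated(bc)])
    stop("duplicate barcode(s) in metadata: ",
         paste(utils::head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) sprintf(" (and %d more)", length(offenders) - 5))
  }
  idx <- match(records$cell_barcode, bc)
  matched <- !is.na(idx)
  out <- records[matched, , drop = FALSE]
  out$sample_id <- as.character(metadata$sample_id)[idx[matched]]
  out$subset <- as.character(metadata$subset)[idx[matched]]
  out$state <- encode_state(metadata$state[idx[matched]], state_labels)
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no barcodes shared between records and metadata")
  attr(out, "join_report") <- c(
    n_records_in = nrow(records),
    n_unmatched_records = sum(!matched),
    n_unmatched_metadata = length(bc) - length(unique(records$cell_barcode[matched])),
    n_joined = nrow(out)
  )
  attr(out, "load_report") <- attr(records, "load_report")
  out
}

#' CDR3 length distribution by group
#'
#' Tabulates CDR3 amino-acid sequence lengths per group (disease state by
#' default), in tidy long form ready for export or plotting. Frequencies
#' within a group sum to the number of records in that group.
#'
#' @param records annotated records data.frame.
#' @param by grouping column, default `"state"`.
#' @return data.frame with columns `group`, `length`, `count`.
#' @export
length_distribution <- function(records, by = "state") {
  if (nrow(records) == 0) {
    return(data.frame(group = character(0), length = integer(0),
                      count = integer(0)))
  }
  if (!by %in% names(records)) stop("grouping column not found: ", by)
  tt <- table(group = records[[by]], length = nchar(records$cdr3aa))
  out <- as.data.frame(tt, stringsAsFactors = FALSE)
  names(out) <- c("group", "length", "count")
  out$length <- as.integer(out$length)
  out$count <- as.integer(out$count)
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(out$group, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write records as an AIRR-style rearrangement TSV plus metadata CSV
#'
#' Emits the exact file pair that [read_repertoire()] and
#' [join_annotations()] read back, enabling round-trip tests and CLI
#' interchange.
#'
#' @param records annotated records data.frame.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths written.
#' @export
write_repertoire <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  locus <- ifelse(records$chain == "BCRH", "IGH", "TRA")
  airr <- data.frame(cell_id = records$cell_barcode, locus = locus,
                     junction_aa = records$cdr3aa, stringsAsFactors = FALSE)
  airr_path <- file.path(dir, "repertoire.tsv")
  utils::write.table(airr, airr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- unique(data.frame(barcode = records$cell_barcode,
                            sample_id = records$sample_id,
                            subset = records$subset,
                            state = records$state, stringsAsFactors = FALSE))
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(repertoire = airr_path, metadata = meta_path))
}
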