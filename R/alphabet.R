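#' Standard amino-acid alphabet
#'
#' The 20 standard amino-acid one-letter codes in lexicographic order. This
#' ordering defines the column order of every k-mer feature space built by
#' [enumerate_feature_space()].
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default mapping from disease-state labels to numeric classes
#'
#' The three-class coding used throughout the package: 0 = healthy/normal,
#' 1 = mild/moderate, 2 = severe. Matching is case-insensitive.
#'
#' @return Named integer vector mapping state strings to classes 0/1/2.
#' @export
default_state_labels <- function() {
  c(healthy = 0L, normal = 0L, control = 0L, h = 0L,
    mild = 1L, moderate = 1L, mild_moderate = 1L, m = 1L,
    severe = 2L, s = 2L)
}

#' Encode disease-state labels as numeric classes
#'
#' Accepts labels that are already numeric (0/1/2), numeric strings, or
#' descriptive strings resolvable through `label_map`.
#'
#' @param x character or numeric vector of state labels.
#' @param label_map named integer vector mapping lower-cased state strings to
#'   classes; see [default_state_labels()].
#' @return Integer vector of classes.
#' @export
encode_state <- function(x, label_map = default_state_labels()) {
  if (is.numeric(x)) return(as.integer(x))
  x_chr <- tolower(trimws(as.character(x)))
  out <- suppressWarnings(as.integer(x_chr))
  need <- is.na(out) & !is.na(x_chr)
  if (any(need)) {
    mapped <- unname(label_map[x_chr[need]])
    bad <- unique(x_chr[need][is.na(mapped)])
    if (length(bad) > 0) {
      stop("unrecognised state label(s): ", paste(bad, collapse = ", "))
    }
    out[need] <- mapped
  }
  out
}

# H/M/S display names for the numeric classes used in report tables
.state_display <- function(classes) {
  nm <- c(`0` = "H", `1` = "M", `2` = "S")
  out <- nm[as.character(classes)]
  out[is.na(out)] <- as.character(classes)[is.na(out)]
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read a delimited table, choosing the separator from the file extension
.read_table_auto <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(sub(".*\\.", "", basename(path)))
  sep <- if (ext %in% c("csv")) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}
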