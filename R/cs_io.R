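# Reading, writing and validating labelled chemical-shift fragment tables.
#
# The on-disk dialect is a UTF-8 TSV with a mandatory header and fixed
# column order:
#   protein_id  fragment_id  class  pos  aa  cs_C cs_CA cs_CB cs_HN cs_HA cs_N
# class is "hairpin" or "not_hairpin", pos is 1-based within the fragment,
# shifts are ppm with '.' decimal separator, missing values are "NA" or an
# empty cell.

.DIALECT_COLS <- c("protein_id", "fragment_id", "class", "pos", "aa",
                   paste0("cs_", c("C", "CA", "CB", "HN", "HA", "N")))

#' Construct a chemical-shift fragment dataset
#'
#' Builds a `cs_dataset` from a long per-residue data frame (one row per
#' residue, columns as in the TSV dialect) and checks the structural
#' invariants: unique `(fragment_id, pos)` pairs, contiguous 1..l
#' positions within each fragment, a single class label per fragment,
#' finite shift values, and standard one-letter residue codes ('X' is
#' allowed with a warning).
#'
#' @param rows Data frame with columns `protein_id`, `fragment_id`,
#'   `class`, `pos`, `aa` and the six shift columns `cs_C` ... `cs_N`
#'   (ppm, `NA` for missing).
#' @return A `cs_dataset`, a data frame in the same long layout ordered
#'   by fragment (first appearance) and position.
#' @seealso [read_fragment_table()], [write_fragment_table()]
#' @export
cs_dataset <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.DIALECT_COLS, names(rows))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- rows[.DIALECT_COLS]
  rows$protein_id <- as.character(rows$protein_id)
  rows$fragment_id <- as.character(rows$fragment_id)
  rows$class <- as.character(rows$class)
  rows$pos <- as.integer(rows$pos)
  rows$aa <- as.character(rows$aa)
  for (cc in .shift_cols()) rows[[cc]] <- as.numeric(rows[[cc]])

  if (nrow(rows) > 0L) {
    bad_class <- !rows$class %in% .LABELS
    if (any(bad_class)) {
      stop("invalid class value(s): ",
           paste(unique(rows$class[bad_class]), collapse = ", "),
           call. = FALSE)
    }
    if (anyNA(rows$pos) || any(rows$pos < 1L)) {
      stop("pos must be an integer >= 1", call. = FALSE)
    }
    key <- paste(rows$fragment_id, rows$pos, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop("duplicate (fragment_id, pos) row: ",
           gsub("\r", " pos ", dup, fixed = TRUE), call. = FALSE)
    }
    bad_aa <- !rows$aa %in% c(.AA20, "X")
    if (any(bad_aa)) {
      stop("invalid residue code(s): ",
           paste(unique(rows$aa[bad_aa]), collapse = ", "), call. = FALSE)
    }
    if (any(rows$aa == "X")) {
      warning("dataset contains 'X' (nonstandard) residues; they are ",
              "ignored by amino-acid-composition features", call. = FALSE)
    }
    for (cc in .shift_cols()) {
      v <- rows[[cc]]
      if (any(!is.na(v) & !is.finite(v))) {
        stop("non-finite shift value in column ", cc, call. = FALSE)
      }
    }
    # order by fragment first appearance, then position, and check
    # contiguity / label consistency per fragment
    frag <- factor(rows$fragment_id, levels = unique(rows$fragment_id))
    rows <- rows[order(as.integer(frag), rows$pos), , drop = FALSE]
    rownames(rows) <- NULL
    idx <- split(seq_len(nrow(rows)),
                 factor(rows$fragment_id, levels = unique(rows$fragment_id)))
    for (fid in names(idx)) {
      sel <- idx[[fid]]
      if (!identical(rows$pos[sel], seq_along(sel))) {
        stop("fragment '", fid, "' positions are not contiguous 1..l",
             call. = FALSE)
      }
      if (length(unique(rows$class[sel])) != 1L) {
        stop("fragment '", fid, "' carries more than one class label",
             call. = FALSE)
      }
      if (length(unique(rows$protein_id[sel])) != 1L) {
        stop("fragment '", fid, "' carries more than one protein_id",
             call. = FALSE)
      }
    }
  }
  class(rows) <- c("cs_dataset", "data.frame")
  rows
}

#' Read a chemical-shift fragment table
#'
#' Parses the TSV fragment dialect (see [cs_dataset()] for the layout)
#' into a validated `cs_dataset`.  "NA" or empty shift cells become
#' missing values; malformed headers, duplicate residue rows and
#' non-numeric shift cells raise errors that name the offending column or
#' line.
#'
#' @param source Path to a TSV file, or a connection.
#' @return A `cs_dataset`.
#' @export
#' @examples
#' d <- generate_dataset(default_config(separation = 2, n_hairpin = 3,
#'                                      n_not_hairpin = 3, seed = 1))$dataset
#' f <- tempfile(fileext = ".tsv")
#' write_fragment_table(d, f)
#' d2 <- read_fragment_table(f)
#' identical(as.data.frame(d), as.data.frame(d2))
read_fragment_table <- function(source) {
  raw <- utils::read.delim(source, header = TRUE, colClasses = "character",
                           na.strings = NULL, check.names = FALSE,
                           quote = "", comment.char = "")
  if (!identical(names(raw), .DIALECT_COLS)) {
    missing_cols <- setdiff(.DIALECT_COLS, names(raw))
    if (length(missing_cols) > 0L) {
      stop("malformed header: missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    stop("malformed header: columns must appear in the order ",
         paste(.DIALECT_COLS, collapse = ", "), call. = FALSE)
  }
  for (cc in .shift_cols()) {
    cell <- raw[[cc]]
    empty <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(num)
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' in column %s at line %d",
                   cell[which(bad)[1L]], cc, which(bad)[1L] + 1L),
           call. = FALSE)
    }
    num[empty] <- NA_real_
    raw[[cc]] <- num
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  if (nrow(raw) > 0L && anyNA(pos)) {
    stop(sprintf("non-integer pos value at line %d",
                 which(is.na(pos))[1L] + 1L), call. = FALSE)
  }
  raw$pos <- pos
  cs_dataset(raw)
}

#' Write a chemical-shift fragment table
#'
#' Emits the TSV dialect bit-exactly: fixed column order, missing shifts
#' as "NA", '.' decimal separator.  `read_fragment_table()` applied to
#' the output reproduces the input dataset.
#'
#' @param data A `cs_dataset`.
#' @param sink Output path or connection.
#' @return Invisibly, `sink`.
#' @export
write_fragment_table <- function(data, sink) {
  stopifnot(inherits(data, "cs_dataset"))
  out <- as.data.frame(data)
  for (cc in .shift_cols()) out[[cc]] <- .format_num(out[[cc]])
  lines <- c(paste(.DIALECT_COLS, collapse = "\t"),
             if (nrow(out) > 0L) do.call(paste, c(unname(out), sep = "\t")))
  writeLines(lines, sink, useBytes = TRUE)
  invisible(sink)
}

#' Per-class fragment counts
#'
#' @param data A `cs_dataset`.
#' @return Named integer vector with one count per class label.
#' @export
dataset_counts <- function(data) {
  stopifnot(inherits(data, "cs_dataset"))
  lab <- fragment_labels(data)
  out <- stats::setNames(integer(length(.LABELS)), .LABELS)
  tb <- table(factor(lab, levels = .LABELS))
  out[names(tb)] <- as.integer(tb)
  out
}

#' Fragment labels
#'
#' @param data A `cs_dataset`.
#' @return Named character vector: one class label per fragment, named by
#'   `fragment_id`, in dataset order.
#' @export
fragment_labels <- function(data) {
  stopifnot(inherits(data, "cs_dataset"))
  first <- !duplicated(data$fragment_id)
  stats::setNames(data$class[first], data$fragment_id[first])
}

#' Validation policy for fragment datasets
#'
#' Length bounds describe typical data rather than constraints of the
#' method, so they are a policy, not a parse error.  Defaults are the
#' ranges observed in curated hairpin/non-hairpin fragment sets: 7-38
#' residues for hairpins and 8-40 for the negative class.
#'
#' @param hairpin_length Integer length bounds `c(min, max)` for the
#'   hairpin class.
#' @param not_hairpin_length Bounds for the negative class.
#' @param min_coverage Minimum fraction of residues with a present shift,
#'   per nucleus, for a fragment to be considered complete.
#' @return A `cs_validation_policy` list.
#' @export
validation_policy <- function(hairpin_length = c(7L, 38L),
                              not_hairpin_length = c(8L, 40L),
                              min_coverage = 1) {
  stopifnot(length(hairpin_length) == 2L, length(not_hairpin_length) == 2L,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(hairpin_length = as.integer(hairpin_length),
                 not_hairpin_length = as.integer(not_hairpin_length),
                 min_coverage = min_coverage),
            class = "cs_validation_policy")
}

#' Validate a fragment dataset against a policy
#'
#' Reports, per fragment, length-range violations and per-nucleus shift
#' coverage (fraction of residues with a present value).  Validation is
#' pure: the input dataset is never modified.
#'
#' @param data A `cs_dataset`.
#' @param policy A [validation_policy()].
#' @return A `cs_validation` data frame with one row per fragment:
#'   `fragment_id`, `class`, `length`, `length_ok`, one `cov_<nucleus>`
#'   column per nucleus, and `coverage_ok`.
#' @export
validate_dataset <- function(data, policy = validation_policy()) {
  stopifnot(inherits(data, "cs_dataset"),
            inherits(policy, "cs_validation_policy"))
  labs <- fragment_labels(data)
  ids <- names(labs)
  if (length(ids) == 0L) {
    report <- data.frame(fragment_id = character(), class = character(),
                         length = integer(), length_ok = logical(),
                         coverage_ok = logical(), stringsAsFactors = FALSE)
    class(report) <- c("cs_validation", "data.frame")
    return(report)
  }
  len <- as.integer(table(factor(data$fragment_id, levels = ids)))
  bounds <- list(hairpin = policy$hairpin_length,
                 not_hairpin = policy$not_hairpin_length)
  length_ok <- vapply(seq_along(ids), function(i) {
    b <- bounds[[labs[[i]]]]
    len[i] >= b[1L] && len[i] <= b[2L]
  }, logical(1L))
  cov <- vapply(.NUCLEI, function(m) {
    present <- !is.na(data[[paste0("cs_", m)]])
    as.numeric(tapply(present, factor(data$fragment_id, levels = ids), mean))
  }, numeric(length(ids)))
  cov <- matrix(cov, nrow = length(ids),
                dimnames = list(NULL, paste0("cov_", .NUCLEI)))
  report <- data.frame(fragment_id = ids, class = unname(labs),
                       length = len, length_ok = length_ok,
                       cov, coverage_ok = apply(cov >= policy$min_coverage -
                                                  1e-12, 1L, all),
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  class(report) <- c("cs_validation", "data.frame")
  report
}
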