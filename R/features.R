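# Fragment-level feature construction: averaged chemical shifts over the
# residues of a fragment (the six-nuclei t_m vector), or 20-dimensional
# amino-acid composition.

#' Average the chemical shifts of a fragment
#'
#' For each requested nucleus m, computes t_m = (1/l) * sum_j CS_mj over
#' the l residues of the fragment, so the fragment collapses to one ppm
#' value per nucleus.  When some residues lack an assignment for m, the
#' mean is taken over the present values, provided their fraction reaches
#' `min_coverage`; below that the fragment has insufficient data for m.
#'
#' @param frag Rows of a single fragment (a `cs_dataset` subset, or any
#'   data frame in the same layout).
#' @param nuclei Subset of [cs_nuclei()] to average, in canonical order.
#' @param min_coverage Minimum fraction of residues with a present shift
#'   per nucleus; the default 1 demands complete assignments.
#' @return Named numeric vector of averaged shifts (ppm), one entry per
#'   requested nucleus.
#' @export
#' @examples
#' d <- generate_dataset(default_config(n_hairpin = 1, n_not_hairpin = 1,
#'                                      seed = 7))$dataset
#' average_shifts(d[d$fragment_id == d$fragment_id[1], ])
average_shifts <- function(frag, nuclei = cs_nuclei(), min_coverage = 1) {
  stopifnot(length(nuclei) >= 1L, all(nuclei %in% .NUCLEI),
            min_coverage > 0, min_coverage <= 1)
  nuclei <- .NUCLEI[.NUCLEI %in% nuclei]
  if (length(unique(frag$fragment_id)) != 1L) {
    stop("average_shifts expects the rows of exactly one fragment",
         call. = FALSE)
  }
  out <- stats::setNames(numeric(length(nuclei)), nuclei)
  for (m in nuclei) {
    v <- frag[[paste0("cs_", m)]]
    present <- !is.na(v)
    if (mean(present) < min_coverage - 1e-12) {
      stop(sprintf(
        "insufficient data for nucleus %s in fragment '%s': coverage %.3f < %.3f",
        m, frag$fragment_id[1L], mean(present), min_coverage), call. = FALSE)
    }
    out[[m]] <- mean(v[present])
  }
  out
}

#' Amino-acid composition of a fragment
#'
#' Fraction of each of the 20 standard residues in the fragment sequence.
#' Nonstandard residues ('X') are excluded from both numerator and
#' denominator, so the 20 fractions always sum to exactly 1.
#'
#' @param frag A fragment (rows with an `aa` column), or a character
#'   vector of one-letter residue codes.
#' @return Named numeric vector of 20 fractions in alphabetical
#'   one-letter order.
#' @export
#' @examples
#' aac_composition(c("A", "A", "G"))
aac_composition <- function(frag) {
  aa <- if (is.character(frag)) frag else frag$aa
  if (length(aa) == 1L && nchar(aa[1L]) > 1L) {
    aa <- strsplit(aa, "")[[1L]]
  }
  bad <- !aa %in% c(.AA20, "X")
  if (any(bad)) {
    stop("invalid residue code(s): ", paste(unique(aa[bad]), collapse = ", "),
         call. = FALSE)
  }
  aa <- aa[aa != "X"]
  if (length(aa) == 0L) {
    stop("insufficient data: fragment has no standard residues",
         call. = FALSE)
  }
  counts <- table(factor(aa, levels = .AA20))
  stats::setNames(as.numeric(counts) / length(aa), .AA20)
}

#' Build a per-fragment feature matrix
#'
#' Converts every fragment of a dataset into one feature row: either the
#' averaged-shift vector over a nucleus subset (`"cs6"`, the full six, or
#' any subset via `nuclei`) or the 20-dimensional amino-acid composition
#' (`"aac20"`).  Fragments that fail the coverage requirement are dropped
#' and listed with their reason; row order follows the dataset.
#'
#' @param data A `cs_dataset`.
#' @param features `"cs6"` or `"aac20"`.
#' @param nuclei For shift features, the nucleus subset to use (canonical
#'   order is enforced); a proper subset yields `kind = "cs_subset"`.
#' @param min_coverage Passed to [average_shifts()].
#' @return A `cs_features` object: list with `x` (numeric matrix, one row
#'   per retained fragment), `feature_names`, `labels` (factor),
#'   `fragment_id`, `kind`, and `dropped` (data frame of dropped
#'   fragments and reasons).
#' @export
build_feature_matrix <- function(data, features = c("cs6", "aac20"),
                                 nuclei = cs_nuclei(), min_coverage = 1) {
  stopifnot(inherits(data, "cs_dataset"))
  features <- match.arg(features)
  labs <- fragment_labels(data)
  if (length(labs) == 0L) stop("dataset is empty", call. = FALSE)
  ids <- names(labs)

  if (features == "cs6") {
    nuclei <- .NUCLEI[.NUCLEI %in% nuclei]
    if (length(nuclei) == 0L) stop("empty nucleus subset", call. = FALSE)
    feature_names <- nuclei
    kind <- if (length(nuclei) == 6L) "cs6" else "cs_subset"
    fn <- function(frag) average_shifts(frag, nuclei, min_coverage)
  } else {
    feature_names <- .AA20
    kind <- "aac20"
    fn <- aac_composition
  }

  rows <- vector("list", length(ids))
  reasons <- character(length(ids))
  frag_index <- split(seq_len(nrow(data)),
                      factor(data$fragment_id, levels = ids))
  for (i in seq_along(ids)) {
    res <- tryCatch(fn(data[frag_index[[i]], , drop = FALSE]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) reasons[i] <- res else rows[[i]] <- res
  }
  keep <- reasons == ""
  if (!any(keep)) {
    stop("all fragments were dropped; first reason: ", reasons[1L],
         call. = FALSE)
  }
  x <- do.call(rbind, rows[keep])
  dimnames(x) <- list(ids[keep], feature_names)
  structure(list(x = x,
                 feature_names = feature_names,
                 labels = .as_label(unname(labs[keep])),
                 fragment_id = ids[keep],
                 kind = kind,
                 dropped = data.frame(fragment_id = ids[!keep],
                                      reason = reasons[!keep],
                                      stringsAsFactors = FALSE)),
            class = "cs_features")
}

#' @export
print.cs_features <- function(x, ...) {
  cat(sprintf("<cs_features> %s: %d fragments x %d features (%d dropped)\n",
              x$kind, nrow(x$x), ncol(x$x), nrow(x$dropped)))
  tb <- table(x$labels)
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Export a feature matrix as TSV
#'
#' One row per fragment: `fragment_id`, `class`, then one column per
#' feature, for external inspection or plotting.
#'
#' @param features A `cs_features` object.
#' @param sink Output path or connection.
#' @return Invisibly, `sink`.
#' @export
write_feature_table <- function(features, sink) {
  stopifnot(inherits(features, "cs_features"))
  out <- data.frame(fragment_id = features$fragment_id,
                    class = as.character(features$labels),
                    features$x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, sink, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sink)
}
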