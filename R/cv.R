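# Cross-validation, leave-one-nucleus-out ablation, nucleus ranking and
# pluggable baseline comparison.

#' Assign cross-validation folds
#'
#' Randomly partitions samples into `k` folds of sizes differing by at
#' most one; with `stratified = TRUE` (default) the balance holds within
#' each class, preserving the class ratio per fold to within one
#' fragment.  Deterministic given `seed`; the caller's RNG state is
#' restored afterwards.
#'
#' @param labels Class labels (one per fragment).
#' @param k Number of folds, >= 2.
#' @param seed Optional integer seed.
#' @param stratified Balance folds within each class.
#' @return Integer vector of fold indices in 1..k, one per sample, with
#'   attributes `k`, `seed`, `stratified`.
#' @export
make_folds <- function(labels, k = 3L, seed = NULL, stratified = TRUE) {
  labels <- .as_label(labels)
  n <- length(labels)
  stopifnot(k >= 2L)
  if (stratified) {
    small <- table(labels) < k
    if (any(small)) {
      stop("infeasible folds: class '", names(which(small))[1L],
           "' has fewer than k = ", k, " members", call. = FALSE)
    }
  } else if (n < k) {
    stop("infeasible folds: fewer samples than folds", call. = FALSE)
  }
  .with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (lab in levels(labels)) {
        idx <- which(labels == lab)
        fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    structure(fold, k = k, seed = seed, stratified = stratified)
  })
}

.metrics_row <- function(counts) {
  m <- classification_metrics(counts)
  data.frame(tp = counts$tp, fn = counts$fn, fp = counts$fp,
             tn = counts$tn, sn = m$sn, sp = m$sp, acc = m$acc,
             mcc = m$mcc)
}

#' k-fold cross-validation of the quadratic discriminant
#'
#' For each fold: fit the discriminant on the remaining folds, predict
#' the held-out fragments, apply the error-allowed-scope correction with
#' threshold `r_max`, and tally confusion counts.  Metrics are reported
#' per fold, averaged over folds (arithmetic mean), and pooled (counts
#' summed before computing metrics) — both raw and corrected.
#'
#' @param data A `cs_dataset`.
#' @param features `"cs6"` or `"aac20"` (see [build_feature_matrix()]).
#' @param nuclei Nucleus subset for shift features.
#' @param k Number of folds (the conventional protocol uses 3).
#' @param seed Optional integer seed for the fold assignment.
#' @param r_max Error-allowed-scope threshold (protocol value 0.2).
#' @param epsilon Covariance ridge; `NULL` resolves to 0 for shift
#'   features and 1e-6 for compositional (aac20) features, whose
#'   covariance is rank-deficient because rows sum to 1.
#' @param min_coverage Passed to [build_feature_matrix()].
#' @param stratified Passed to [make_folds()].
#' @param unbiased Passed to [qda_fit()].
#' @param folds Optional precomputed fold assignment (as returned by
#'   [make_folds()] on this dataset's retained fragments); overrides
#'   `k`, `seed`, `stratified`.
#' @return A `cs_cv` report: `per_fold` data frame (raw and `_corr`
#'   metric columns), `averaged` and `pooled` (each with `raw` and
#'   `corrected` metric vectors), `folds`, `correction_log`, `dropped`,
#'   and the run `settings`.
#' @export
cross_validate <- function(data, features = "cs6", nuclei = cs_nuclei(),
                           k = 3L, seed = NULL, r_max = 0.2,
                           epsilon = NULL, min_coverage = 1,
                           stratified = TRUE, unbiased = FALSE,
                           folds = NULL) {
  fm <- build_feature_matrix(data, features, nuclei = nuclei,
                             min_coverage = min_coverage)
  if (is.null(epsilon)) epsilon <- if (fm$kind == "aac20") 1e-6 else 0
  if (is.null(folds)) {
    folds <- make_folds(fm$labels, k = k, seed = seed,
                        stratified = stratified)
  }
  if (length(folds) != nrow(fm$x)) {
    stop("fold assignment length does not match retained fragments",
         call. = FALSE)
  }
  k <- max(folds)
  per_fold <- vector("list", k)
  logs <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- tryCatch(
      qda_fit(fm$x[!test, , drop = FALSE], fm$labels[!test],
              epsilon = epsilon, unbiased = unbiased),
      error = function(e) {
        stop("fit failed in fold ", f, ": ", conditionMessage(e),
             call. = FALSE)
      })
    pred <- predict(model, fm$x[test, , drop = FALSE])
    pred$fragment_id <- fm$fragment_id[test]
    truth <- as.character(fm$labels[test])
    corr <- apply_r_correction(pred, truth, r_max = r_max)
    raw <- .metrics_row(confusion_counts(pred$predicted, truth))
    cor_row <- .metrics_row(confusion_counts(corr, truth))
    names(cor_row) <- paste0(names(cor_row), "_corr")
    per_fold[[f]] <- cbind(fold = f, n_test = sum(test), raw, cor_row,
                           n_corrected = sum(corr$corrected))
    lg <- attr(corr, "correction_log")
    if (nrow(lg) > 0L) logs[[f]] <- cbind(fold = f, lg)
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("sn", "sp", "acc", "mcc")
  averaged <- list(
    raw = colMeans(per_fold[metric_cols], na.rm = TRUE),
    corrected = stats::setNames(
      colMeans(per_fold[paste0(metric_cols, "_corr")], na.rm = TRUE),
      metric_cols))
  pool <- function(suffix = "") {
    cc <- lapply(c("tp", "fn", "fp", "tn"),
                 function(nm) sum(per_fold[[paste0(nm, suffix)]]))
    names(cc) <- c("tp", "fn", "fp", "tn")
    m <- classification_metrics(cc)
    unlist(m[metric_cols])
  }
  pooled <- list(raw = pool(), corrected = pool("_corr"))
  structure(list(per_fold = per_fold, averaged = averaged,
                 pooled = pooled, folds = folds,
                 fragment_id = fm$fragment_id,
                 correction_log = do.call(rbind, logs[!vapply(logs, is.null,
                                                              NA)]),
                 dropped = fm$dropped,
                 settings = list(features = fm$kind,
                                 feature_names = fm$feature_names,
                                 k = k, seed = seed, r_max = r_max,
                                 epsilon = epsilon,
                                 min_coverage = min_coverage,
                                 stratified = stratified,
                                 unbiased = unbiased)),
            class = "cs_cv")
}

#' @export
print.cs_cv <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<cs_cv> %s features, k = %d, r_max = %g, epsilon = %g\n",
              s$features, s$k, s$r_max, s$epsilon))
  fmt <- function(v) sprintf("Sn=%.1f%% Sp=%.1f%% Acc=%.1f%% MCC=%.3f",
                             v[["sn"]], v[["sp"]], v[["acc"]], v[["mcc"]])
  cat("  averaged raw:      ", fmt(x$averaged$raw), "\n")
  cat("  averaged corrected:", fmt(x$averaged$corrected), "\n")
  cat("  pooled corrected:  ", fmt(x$pooled$corrected), "\n")
  invisible(x)
}

#' Serialise a cross-validation report to JSON
#'
#' The JSON embeds the per-fold table, averaged and pooled metrics, the
#' fold assignment and the full settings (including seed), so the run
#' can be regenerated from the report alone.
#'
#' @param report A `cs_cv` report.
#' @param path Output file path.
#' @param input_checksum Optional checksum of the input dataset file,
#'   recorded in the JSON for provenance.
#' @return Invisibly, `path`.
#' @export
write_cv_report <- function(report, path, input_checksum = NULL) {
  stopifnot(inherits(report, "cs_cv"))
  doc <- list(per_fold = report$per_fold,
              averaged = lapply(report$averaged, as.list),
              pooled = lapply(report$pooled, as.list),
              folds = stats::setNames(as.integer(report$folds),
                                      report$fragment_id),
              settings = report$settings,
              input_checksum = input_checksum)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Leave-one-nucleus-out ablation
#'
#' Runs [cross_validate()] with the full six-nuclei feature vector and
#' with each of the six nuclei omitted in turn — seven reports sharing
#' one fold assignment, so performance drops are attributable to the
#' missing nucleus alone.  Only fragments with complete six-nuclei
#' coverage (under `min_coverage`) enter, keeping the sample identical
#' across runs.
#'
#' @inheritParams cross_validate
#' @return A `cs_ablation` list of `cs_cv` reports named `"full"`,
#'   `"omit_C"`, ..., `"omit_N"`.
#' @export
ablate_nuclei <- function(data, k = 3L, seed = NULL, r_max = 0.2,
                          epsilon = 0, min_coverage = 1,
                          stratified = TRUE) {
  fm <- build_feature_matrix(data, "cs6", min_coverage = min_coverage)
  folds <- make_folds(fm$labels, k = k, seed = seed,
                      stratified = stratified)
  run <- function(nuclei) {
    cross_validate(data, "cs6", nuclei = nuclei, r_max = r_max,
                   epsilon = epsilon, min_coverage = min_coverage,
                   folds = folds)
  }
  out <- c(list(full = run(.NUCLEI)),
           lapply(stats::setNames(.NUCLEI, paste0("omit_", .NUCLEI)),
                  function(m) run(setdiff(.NUCLEI, m))))
  structure(out, class = "cs_ablation")
}

#' Rank nuclei by leave-one-out importance
#'
#' Orders the six nuclei from most to least important: the lower the
#' averaged corrected accuracy when a nucleus is omitted, the larger its
#' contribution.  Ties are broken by the corrected MCC, then by
#' canonical nucleus order.
#'
#' @param ablation A `cs_ablation` from [ablate_nuclei()].
#' @return Character vector: the six nuclei, most important first.
#' @export
rank_nuclei <- function(ablation) {
  stopifnot(inherits(ablation, "cs_ablation"))
  acc <- vapply(.NUCLEI, function(m)
    ablation[[paste0("omit_", m)]]$averaged$corrected[["acc"]], 0)
  mcc <- vapply(.NUCLEI, function(m)
    ablation[[paste0("omit_", m)]]$averaged$corrected[["mcc"]], 0)
  .NUCLEI[order(acc, mcc, seq_along(.NUCLEI))]
}

#' Majority-class baseline classifier
#'
#' A pluggable fit/predict pair for [compare_classifiers()] that always
#' predicts the most frequent training class.
#'
#' @return List with `fit(x, labels)` and `predict(model, x)`.
#' @export
classifier_majority <- function() {
  list(fit = function(x, labels) names(which.max(table(labels))),
       predict = function(model, x) rep(model, nrow(x)))
}

#' Support-vector-machine baseline (requires e1071)
#'
#' @param ... Passed to [e1071::svm()].
#' @return A pluggable fit/predict pair for [compare_classifiers()].
#' @export
classifier_svm <- function(...) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("classifier_svm requires the e1071 package", call. = FALSE)
  }
  args <- list(...)
  list(fit = function(x, labels)
         do.call(e1071::svm, c(list(x = x, y = factor(labels)), args)),
       predict = function(model, x)
         as.character(stats::predict(model, x)))
}

#' Random-forest baseline (requires randomForest)
#'
#' @param ... Passed to [randomForest::randomForest()].
#' @return A pluggable fit/predict pair for [compare_classifiers()].
#' @export
classifier_rf <- function(...) {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    stop("classifier_rf requires the randomForest package", call. = FALSE)
  }
  args <- list(...)
  list(fit = function(x, labels)
         do.call(randomForest::randomForest,
                 c(list(x = x, y = factor(labels)), args)),
       predict = function(model, x)
         as.character(stats::predict(model, x)))
}

#' Compare the discriminant against pluggable classifiers
#'
#' Evaluates the internal quadratic discriminant and any number of
#' external fit/predict pairs on identical folds and features; external
#' classifiers are scored on raw predictions (the error-allowed-scope
#' correction is specific to the discriminant's eta scores and is
#' reported for it separately).
#'
#' @inheritParams cross_validate
#' @param classifiers Named list of fit/predict pairs, e.g.
#'   `list(svm = classifier_svm(), rf = classifier_rf())`.
#' @return Data frame with one row per classifier (`"qda"` first, plus
#'   `"qda_corrected"`): pooled `sn`, `sp`, `acc`, `mcc`, and an
#'   `error` column recording any per-classifier failure.
#' @export
compare_classifiers <- function(data, features = "cs6",
                                nuclei = cs_nuclei(), k = 3L,
                                seed = NULL, r_max = 0.2,
                                epsilon = NULL, min_coverage = 1,
                                classifiers = list()) {
  fm <- build_feature_matrix(data, features, nuclei = nuclei,
                             min_coverage = min_coverage)
  folds <- make_folds(fm$labels, k = k, seed = seed)
  qda_report <- cross_validate(data, features, nuclei = nuclei,
                               r_max = r_max, epsilon = epsilon,
                               min_coverage = min_coverage, folds = folds)
  rows <- list(
    data.frame(classifier = "qda", t(qda_report$pooled$raw),
               error = NA_character_, stringsAsFactors = FALSE),
    data.frame(classifier = "qda_corrected", t(qda_report$pooled$corrected),
               error = NA_character_, stringsAsFactors = FALSE))
  for (nm in names(classifiers)) {
    clf <- classifiers[[nm]]
    res <- tryCatch({
      pred <- character(length(folds))
      for (f in seq_len(max(folds))) {
        test <- folds == f
        model <- clf$fit(fm$x[!test, , drop = FALSE],
                         as.character(fm$labels[!test]))
        pred[test] <- clf$predict(model, fm$x[test, , drop = FALSE])
      }
      m <- classification_metrics(
        confusion_counts(pred, as.character(fm$labels)))
      data.frame(classifier = nm, sn = m$sn, sp = m$sp, acc = m$acc,
                 mcc = m$mcc, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(classifier = nm, sn = NA_real_, sp = NA_real_,
                 acc = NA_real_, mcc = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
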