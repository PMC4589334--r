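# Feature screening and evaluation statistics: two-group one-way ANOVA,
# P-P normality points, confusion counts and Sn/Sp/Acc/MCC.

#' Two-group one-way ANOVA
#'
#' Partitions the total mean square into between-group (`ms_b`) and
#' within-group (`ms_w`) components and reports the F ratio
#' `ms_b / ms_w` with degrees of freedom (1, n_a + n_b - 2).  For two
#' groups F is exactly the square of the pooled-variance t statistic.
#' The fit is delegated to [stats::lm()] / [stats::anova()].
#'
#' @param a,b Numeric vectors, at least two values each.
#' @return A `cs_anova` list: `ms_b`, `ms_w`, `f_value`, `df`
#'   (length-2 integer), `p_value`.  When `ms_w` is 0 but `ms_b` is
#'   positive, F is `Inf` with p = 0 and the result is flagged
#'   `degenerate = TRUE`.
#' @export
#' @examples
#' anova_two_group(c(1, 2, 3), c(4, 5, 6))  # F = 13.5 on (1, 4) df
anova_two_group <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  # anova.lm warns on essentially perfect fits; degeneracy is detected
  # and reported below instead
  tab <- withCallingHandlers(
    stats::anova(stats::lm(y ~ g)),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ms_b <- tab["g", "Mean Sq"]
  ms_w <- tab["Residuals", "Mean Sq"]
  df <- c(tab["g", "Df"], tab["Residuals", "Df"])
  # lm() leaves ~1e-30 residual mean squares on exactly constant groups;
  # treat within-group variance as zero relative to the data scale
  scale2 <- max(ms_b, ms_w, mean(y^2))
  if (scale2 == 0 || (ms_w <= 1e-12 * scale2 && ms_b <= 1e-12 * scale2)) {
    stop("degenerate input: no variance between or within groups",
         call. = FALSE)
  }
  degenerate <- ms_w <= 1e-12 * scale2
  f_value <- if (degenerate) Inf else ms_b / ms_w
  p_value <- if (degenerate) 0 else
    stats::pf(f_value, df[1L], df[2L], lower.tail = FALSE)
  structure(list(ms_b = ms_b, ms_w = ms_w, f_value = f_value,
                 df = as.integer(df), p_value = p_value,
                 degenerate = degenerate),
            class = "cs_anova")
}

#' Per-feature ANOVA screen of a feature matrix
#'
#' Runs [anova_two_group()] on every feature column, comparing the
#' hairpin and non-hairpin fragment values, in the matrix's (canonical)
#' feature order.
#'
#' @param features A `cs_features` object with both classes present.
#' @return Data frame with one row per feature: `feature`, `ms_b`,
#'   `ms_w`, `f_value`, `df1`, `df2`, `p_value`.
#' @export
anova_by_nucleus <- function(features) {
  stopifnot(inherits(features, "cs_features"))
  counts <- table(features$labels)
  if (any(counts == 0L)) {
    stop("missing class: no samples labelled '",
         names(counts)[counts == 0L][1L], "'", call. = FALSE)
  }
  is_pos <- features$labels == .POSITIVE
  res <- lapply(features$feature_names, function(fn) {
    r <- anova_two_group(features$x[is_pos, fn], features$x[!is_pos, fn])
    data.frame(feature = fn, ms_b = r$ms_b, ms_w = r$ms_w,
               f_value = r$f_value, df1 = r$df[1L], df2 = r$df[2L],
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' P-P plot points against a fitted normal
#'
#' Sorts the sample and pairs the empirical cumulative probability
#' i/(n+1) of each rank with the cumulative probability of a normal
#' distribution fitted by moments (sample mean and SD).  Under
#' normality the points fall near the diagonal; the maximum absolute
#' diagonal deviation is attached for a one-number summary.
#'
#' @param values Numeric vector, at least 3 values, non-zero variance.
#' @return Data frame `value`, `empirical`, `theoretical` (class
#'   `cs_pp`), with attributes `max_deviation`, `mean`, `sd`.
#' @export
#' @examples
#' pp <- pp_plot_points(rnorm(100))
#' attr(pp, "max_deviation")
pp_plot_points <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  v <- sort(values)
  n <- length(v)
  emp <- seq_len(n) / (n + 1)
  theo <- stats::pnorm(v, mean = mean(v), sd = s)
  out <- data.frame(value = v, empirical = emp, theoretical = theo)
  attr(out, "max_deviation") <- max(abs(emp - theo))
  attr(out, "mean") <- mean(v)
  attr(out, "sd") <- s
  class(out) <- c("cs_pp", "data.frame")
  out
}

#' Confusion counts for two-class predictions
#'
#' Tallies TP/FN/FP/TN with the hairpin class as positive.  Samples
#' flagged `corrected = TRUE` (error-allowed-scope correction) count as
#' correct for their true class.
#'
#' @param pred A `cs_predictions` data frame, or a character vector of
#'   predicted labels.
#' @param truth True labels, same length.
#' @param corrected Optional logical vector overriding the `corrected`
#'   column (defaults to all-`FALSE` for plain label vectors).
#' @return A `cs_confusion` list: `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_counts <- function(pred, truth, corrected = NULL) {
  if (inherits(pred, "cs_predictions") || is.data.frame(pred)) {
    if (is.null(corrected)) corrected <- pred$corrected
    pred <- pred$predicted
  }
  pred <- as.character(.as_label(pred, "pred"))
  truth <- as.character(.as_label(truth, "truth"))
  if (length(pred) != length(truth)) {
    stop("pred and truth lengths differ", call. = FALSE)
  }
  if (is.null(corrected)) corrected <- rep(FALSE, length(pred))
  stopifnot(length(corrected) == length(pred))
  correct <- pred == truth | corrected
  pos <- truth == .POSITIVE
  structure(list(tp = sum(pos & correct), fn = sum(pos & !correct),
                 fp = sum(!pos & !correct), tn = sum(!pos & correct)),
            class = "cs_confusion")
}

#' @export
print.cs_confusion <- function(x, ...) {
  cat(sprintf("<cs_confusion> TP=%d FN=%d FP=%d TN=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP) and Acc = (TP+TN)/n are reported as
#' percentages; the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) is
#' reported on its natural [-1, 1] scale.  A metric whose marginal is
#' empty is returned as `NA` and named in the `undefined` attribute —
#' never silently zeroed.
#'
#' @param counts A `cs_confusion`, or a list with `tp`, `fn`, `fp`, `tn`.
#' @return A `cs_metrics` list: `sn`, `sp`, `acc` (percent), `mcc`.
#' @export
#' @examples
#' classification_metrics(list(tp = 9, fn = 1, fp = 2, tn = 8))
classification_metrics <- function(counts) {
  # doubles throughout: the MCC denominator overflows 32-bit integers
  # at a few hundred samples per class
  tp <- as.numeric(counts$tp); fn <- as.numeric(counts$fn)
  fp <- as.numeric(counts$fp); tn <- as.numeric(counts$tn)
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  n <- tp + fn + fp + tn
  if (n == 0L) stop("empty confusion table", call. = FALSE)
  undefined <- character()
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else
    { undefined <- c(undefined, "sn"); NA_real_ }
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else
    { undefined <- c(undefined, "sp"); NA_real_ }
  acc <- 100 * (tp + tn) / n
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else
    { undefined <- c(undefined, "mcc"); NA_real_ }
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc),
            undefined = undefined, class = "cs_metrics")
}

#' @export
print.cs_metrics <- function(x, ...) {
  cat(sprintf("<cs_metrics> Sn=%.1f%% Sp=%.1f%% Acc=%.1f%% MCC=%.3f\n",
              x$sn, x$sp, x$acc, x$mcc))
  u <- attr(x, "undefined")
  if (length(u) > 0L) cat("  undefined:", paste(u, collapse = ", "), "\n")
  invisible(x)
}
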