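# Two-class quadratic discriminant on fragment feature vectors.
#
# Each class v is modelled by a Gaussian with mean mu_v and covariance
# Sigma_v estimated on the training set (maximum-likelihood divisor p_v,
# the class sample count).  A test vector x is scored per class with
#
#   eta_v = ln p_v - delta_v / 2 - (1/2) ln |Sigma_v|
#
# where delta_v = (x - mu_v)' Sigma_v^{-1} (x - mu_v) is the squared
# Mahalanobis distance.  eta_v equals the Bayes log-posterior up to an
# additive constant shared by both classes (the -d/2 ln(2*pi) term and
# the total-count normalisation), so argmax eta is the Bayes rule under
# the fitted Gaussians with priors proportional to class counts.  The
# difference xi = eta_hairpin - eta_not_hairpin is the two-class
# discriminant function.
#
# The error-allowed-scope coefficient R = (eta_corr - eta_wro)/eta_corr
# measures, for a misclassified sample, how close the true class's score
# came to the winning (wrong) one; samples with R below a threshold
# (0.2 by convention) are re-counted as correct at evaluation time.  R
# requires the true label, so it is strictly an evaluation device and is
# never applied when predicting unlabelled data.

.MODEL_FORMAT_VERSION <- "1.0"
.TIE_TOL <- 1e-12

#' Fit the two-class quadratic discriminant
#'
#' Estimates, per class, the sample count `p`, mean vector `mu` and
#' covariance `sigma` of the feature vectors.  The covariance uses the
#' maximum-likelihood divisor `p` (set `unbiased = TRUE` for `p - 1`).
#' A ridge `epsilon` added to the diagonal keeps the covariance
#' invertible when the features are linearly dependent, e.g. for
#' compositional amino-acid vectors whose entries sum to 1.
#'
#' @param x A `cs_features` object, or a numeric matrix (one row per
#'   sample, named columns).
#' @param labels Class labels per row (ignored when `x` is
#'   `cs_features`); values in [cs_labels()].
#' @param epsilon Non-negative ridge added to the covariance diagonal.
#' @param unbiased Use divisor `p - 1` instead of `p`.
#' @return A `cs_qda` model: per-class list(`label`, `p`, `mu`, `sigma`,
#'   `log_det`, `epsilon`), feature names and fit metadata.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' colnames(x) <- c("f1", "f2")
#' labels <- rep(cs_labels(), each = 20)
#' m <- qda_fit(x, labels)
#' predict(m, x)[1:3, ]
qda_fit <- function(x, labels = NULL, epsilon = 0, unbiased = FALSE) {
  if (inherits(x, "cs_features")) {
    labels <- x$labels
    x <- x$x
  }
  stopifnot(is.matrix(x), is.numeric(x), !is.null(colnames(x)),
            length(epsilon) == 1L, epsilon >= 0)
  labels <- .as_label(labels)
  if (length(labels) != nrow(x)) {
    stop("labels length does not match the number of rows", call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts == 0L)) {
    stop("missing class: no samples labelled '",
         names(counts)[counts == 0L][1L], "'", call. = FALSE)
  }
  if (any(counts < 2L)) {
    stop("each class needs at least 2 samples to estimate a covariance",
         call. = FALSE)
  }
  d <- ncol(x)
  classes <- lapply(.LABELS, function(lab) {
    xv <- x[labels == lab, , drop = FALSE]
    p <- nrow(xv)
    if (p < d) {
      warning(sprintf(
        "class '%s' has fewer samples (%d) than features (%d); covariance is rank-deficient",
        lab, p, d), call. = FALSE)
    }
    mu <- colMeans(xv)
    centred <- sweep(xv, 2L, mu)
    sigma <- crossprod(centred) / (if (unbiased) p - 1L else p)
    sigma_r <- sigma + diag(epsilon, d)
    ch <- tryCatch(chol(sigma_r), error = function(e) NULL)
    if (is.null(ch)) {
      if (epsilon == 0) {
        stop(sprintf(
          "covariance of class '%s' is singular; refit with a small ridge (epsilon > 0)",
          lab), call. = FALSE)
      }
      stop(sprintf(
        "covariance of class '%s' is not positive definite even with epsilon = %g",
        lab, epsilon), call. = FALSE)
    }
    list(label = lab, p = p, mu = mu, sigma = sigma,
         epsilon = epsilon, chol = ch,
         log_det = 2 * sum(log(diag(ch))))
  })
  names(classes) <- .LABELS
  structure(list(classes = classes, feature_names = colnames(x),
                 epsilon = epsilon, unbiased = unbiased,
                 n_train = nrow(x)),
            class = "cs_qda")
}

#' @export
print.cs_qda <- function(x, ...) {
  cat(sprintf(
    "<cs_qda> %d features (%s); n = %d (%s); epsilon = %g, divisor = %s\n",
    length(x$feature_names), paste(x$feature_names, collapse = ", "),
    x$n_train,
    paste(sprintf("%s %d", .LABELS, vapply(x$classes, `[[`, 0L, "p")),
          collapse = ", "),
    x$epsilon, if (x$unbiased) "p-1" else "p"))
  invisible(x)
}

# Align a matrix/vector of feature values with the model's feature order.
.align_features <- function(model, x) {
  if (inherits(x, "cs_features")) x <- x$x
  if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1L,
                dimnames = list(NULL, names(x)))
  }
  fn <- model$feature_names
  if (is.null(colnames(x))) {
    if (ncol(x) != length(fn)) {
      stop("feature dimension mismatch: expected ", length(fn),
           ", got ", ncol(x), call. = FALSE)
    }
    colnames(x) <- fn
    return(x)
  }
  if (!setequal(colnames(x), fn) || ncol(x) != length(fn)) {
    stop("feature names do not match the model (expected ",
         paste(fn, collapse = ", "), ")", call. = FALSE)
  }
  x[, fn, drop = FALSE]
}

#' Squared Mahalanobis distance to a class centre
#'
#' delta_v = (x - mu_v)' Sigma_v^{-1} (x - mu_v), evaluated through the
#' Cholesky factor of the (ridged) class covariance — no explicit matrix
#' inverse is formed.
#'
#' @param class_model One element of `model$classes` from [qda_fit()].
#' @param x Numeric vector, or matrix with one row per point.
#' @return Non-negative numeric vector of squared distances.
#' @export
mahalanobis_sq <- function(class_model, x) {
  mu <- class_model$mu
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(mu)) {
    stop("dimension mismatch: expected ", length(mu), " features, got ",
         ncol(x), call. = FALSE)
  }
  z <- forwardsolve(t(class_model$chol), t(sweep(x, 2L, mu)))
  colSums(z^2)
}

#' Per-class discriminant score
#'
#' eta_v = ln p_v - delta_v/2 - (1/2) ln |Sigma_v|, with natural
#' logarithms and the raw class sample count p_v.
#'
#' @inheritParams mahalanobis_sq
#' @return Numeric vector of scores.
#' @export
eta_score <- function(class_model, x) {
  log(class_model$p) - mahalanobis_sq(class_model, x) / 2 -
    class_model$log_det / 2
}

#' Classify feature vectors with a fitted discriminant
#'
#' Scores each point with [eta_score()] for both classes and predicts
#' the class with the larger score; ties within 1e-12 go to the positive
#' (hairpin) class.  `xi = eta_hairpin - eta_not_hairpin` is the
#' two-class discriminant value.
#'
#' @param object A `cs_qda` model.
#' @param newdata A `cs_features` object or numeric matrix; column names
#'   must match the model's features.
#' @param ... Unused.
#' @return A `cs_predictions` data frame: `fragment_id`, `eta_hairpin`,
#'   `eta_not_hairpin`, `xi`, `predicted`, `corrected` (all `FALSE`; see
#'   [apply_r_correction()]), `r_value` (`NA` until correction).
#' @export
predict.cs_qda <- function(object, newdata, ...) {
  ids <- if (inherits(newdata, "cs_features")) newdata$fragment_id else NULL
  x <- .align_features(object, newdata)
  if (is.null(ids)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  }
  eta_h <- eta_score(object$classes$hairpin, x)
  eta_n <- eta_score(object$classes$not_hairpin, x)
  xi <- eta_h - eta_n
  predicted <- ifelse(xi > -.TIE_TOL, .POSITIVE, "not_hairpin")
  out <- data.frame(fragment_id = ids, eta_hairpin = eta_h,
                    eta_not_hairpin = eta_n, xi = xi,
                    predicted = predicted, corrected = FALSE,
                    r_value = NA_real_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cs_predictions", "data.frame")
  out
}

#' Error-allowed-scope coefficient
#'
#' R = (eta_corr - eta_wro) / eta_corr, where `eta_corr` is the score of
#' the sample's true class and `eta_wro` the score of the (wrong)
#' predicted class.  Undefined when `eta_corr` is 0.
#'
#' @param eta_corr Score of the true class.
#' @param eta_wro Score of the wrongly predicted class.
#' @return Numeric vector of R values (`NA` where `eta_corr == 0`).
#' @export
#' @examples
#' r_coefficient(2, 1)    #  0.5
#' r_coefficient(-2, -1)  # -0.5
r_coefficient <- function(eta_corr, eta_wro) {
  ifelse(eta_corr == 0, NA_real_, (eta_corr - eta_wro) / eta_corr)
}

#' Apply the error-allowed-scope correction
#'
#' For every misclassified sample, computes [r_coefficient()] with the
#' true class's score as `eta_corr` and the predicted class's score as
#' `eta_wro`; samples with a defined R below `r_max` are marked
#' `corrected = TRUE` and count as correct in downstream confusion
#' counts.  Correctly classified samples are untouched.  Requires true
#' labels, so this is an evaluation-time device only.
#'
#' @param pred A `cs_predictions` data frame.
#' @param truth True class labels, same length/order as `pred`.
#' @param r_max Correction threshold; a misclassification is forgiven
#'   when `R < r_max`.  The conventional protocol value is 0.2.
#' @return `pred` with `corrected` and `r_value` filled in; the
#'   `"correction_log"` attribute lists every misclassified sample with
#'   its R, whether it was corrected, and any undefined-R condition.
#' @export
apply_r_correction <- function(pred, truth, r_max = 0.2) {
  stopifnot(inherits(pred, "cs_predictions"))
  truth <- .as_label(truth, "truth")
  if (length(truth) != nrow(pred)) {
    stop("truth length (", length(truth),
         ") does not match predictions (", nrow(pred), ")", call. = FALSE)
  }
  truth <- as.character(truth)
  mis <- which(pred$predicted != truth)
  log <- data.frame(fragment_id = character(), truth = character(),
                    predicted = character(), r_value = numeric(),
                    corrected = logical(), note = character(),
                    stringsAsFactors = FALSE)
  if (length(mis) > 0L) {
    eta <- cbind(hairpin = pred$eta_hairpin,
                 not_hairpin = pred$eta_not_hairpin)
    eta_corr <- eta[cbind(mis, match(truth[mis], colnames(eta)))]
    eta_wro <- eta[cbind(mis, match(pred$predicted[mis], colnames(eta)))]
    r <- r_coefficient(eta_corr, eta_wro)
    corrected <- !is.na(r) & r < r_max
    pred$r_value[mis] <- r
    pred$corrected[mis] <- corrected
    log <- data.frame(fragment_id = pred$fragment_id[mis],
                      truth = truth[mis], predicted = pred$predicted[mis],
                      r_value = r, corrected = corrected,
                      note = ifelse(is.na(r),
                                    "R undefined (eta_corr = 0); left uncorrected",
                                    ""),
                      stringsAsFactors = FALSE)
  }
  attr(pred, "correction_log") <- log
  attr(pred, "r_max") <- r_max
  pred
}

#' Serialise a fitted model to JSON
#'
#' Writes a versioned JSON document holding feature names and, per
#' class, the sample count, mean, covariance (row-major) and ridge, with
#' enough digits for a bit-faithful round trip via [read_qda_model()].
#'
#' @param model A `cs_qda` model.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_qda_model <- function(model, path) {
  stopifnot(inherits(model, "cs_qda"))
  doc <- list(
    version = .MODEL_FORMAT_VERSION,
    feature_names = model$feature_names,
    epsilon = model$epsilon,
    unbiased = model$unbiased,
    n_train = model$n_train,
    classes = lapply(unname(model$classes), function(cm) {
      list(label = cm$label, p = cm$p, mu = unname(cm$mu),
           sigma = unname(cm$sigma), epsilon = cm$epsilon)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a model serialised by [write_qda_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `cs_qda` model.
#' @export
read_qda_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed model file: ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (!identical(doc$version, .MODEL_FORMAT_VERSION)) {
    stop("model file version mismatch: expected ", .MODEL_FORMAT_VERSION,
         ", found ", if (is.null(doc$version)) "<none>" else
           as.character(doc$version), call. = FALSE)
  }
  fn <- unlist(doc$feature_names)
  d <- length(fn)
  classes <- lapply(doc$classes, function(row) {
    sigma <- do.call(rbind, lapply(row$sigma, function(r) unlist(r)))
    if (!identical(dim(sigma), c(d, d))) {
      stop("malformed model file: covariance is not ", d, "x", d,
           call. = FALSE)
    }
    dimnames(sigma) <- list(fn, fn)
    eps <- as.numeric(row$epsilon)
    ch <- chol(sigma + diag(eps, d))
    list(label = row$label, p = as.integer(row$p),
         mu = stats::setNames(unlist(row$mu), fn), sigma = sigma,
         epsilon = eps, chol = ch,
         log_det = 2 * sum(log(diag(ch))))
  })
  names(classes) <- vapply(classes, `[[`, "", "label")
  if (!setequal(names(classes), .LABELS)) {
    stop("malformed model file: expected classes ",
         paste(.LABELS, collapse = ", "), call. = FALSE)
  }
  structure(list(classes = classes[.LABELS], feature_names = fn,
                 epsilon = doc$epsilon, unbiased = isTRUE(doc$unbiased),
                 n_train = doc$n_train),
            class = "cs_qda")
}
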