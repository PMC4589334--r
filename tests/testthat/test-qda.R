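# The quadratic discriminant: fitting, scoring, classification, the
# error-allowed-scope correction, and model serialisation.

fit_toy <- function() {
  x <- rbind(c(0, 0), c(2, 2), c(5, 1), c(7, 3), c(6, 1), c(5, 2))
  colnames(x) <- c("f1", "f2")
  labels <- c("hairpin", "hairpin", rep("not_hairpin", 4))
  list(x = x, labels = labels)
}

test_that("fit reproduces hand-computed means and ML covariance", {
  toy <- fit_toy()
  expect_error(qda_fit(toy$x, toy$labels, epsilon = 0), "singular")
  m <- suppressWarnings(qda_fit(toy$x, toy$labels, epsilon = 1e-6))
  h <- m$classes$hairpin
  expect_equal(h$p, 2L)
  expect_equal(unname(h$mu), c(1, 1))
  # divisor p: [[1,1],[1,1]] for rows (0,0),(2,2)
  expect_equal(unname(h$sigma), matrix(1, 2, 2))
  expect_true(is.finite(h$log_det))
})

test_that("fitted moments match a brute-force double-loop oracle", {
  withr::local_seed(403)
  for (i in 1:5) {
    d <- sample(2:6, 1)
    tc <- rand_two_class(sample(10:30, 1), d, delta = 1)
    m <- qda_fit(tc$x, tc$labels)
    for (lab in cs_labels()) {
      ref <- oracle_mean_cov(tc$x[tc$labels == lab, , drop = FALSE])
      expect_equal(unname(m$classes[[lab]]$mu), ref$mu, tolerance = 1e-10)
      expect_equal(unname(m$classes[[lab]]$sigma), ref$sigma,
                   tolerance = 1e-10)
    }
  }
})

test_that("duplicating every sample leaves mu and sigma unchanged", {
  withr::local_seed(404)
  tc <- rand_two_class(15, 3, delta = 1)
  m1 <- qda_fit(tc$x, tc$labels)
  m2 <- qda_fit(rbind(tc$x, tc$x), c(tc$labels, tc$labels))
  for (lab in cs_labels()) {
    expect_equal(m1$classes[[lab]]$mu, m2$classes[[lab]]$mu)
    expect_equal(m1$classes[[lab]]$sigma, m2$classes[[lab]]$sigma)
    expect_equal(m2$classes[[lab]]$p, 2L * m1$classes[[lab]]$p)
  }
})

test_that("fit guards: missing class, too-few samples, p < d warning", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(qda_fit(x, rep("hairpin", 10)), "missing class")
  expect_error(qda_fit(x, c("hairpin", rep("not_hairpin", 9))),
               "at least 2")
  wide <- matrix(rnorm(32), 8, 4, dimnames = list(NULL, letters[1:4]))
  expect_warning(
    qda_fit(wide, rep(cs_labels(), c(3, 5)), epsilon = 1e-3),
    "class 'hairpin' has fewer samples")
})

test_that("mahalanobis distance matches closed forms and an explicit-inverse oracle", {
  withr::local_seed(405)
  d <- 4
  sigma <- rand_spd(d)
  x <- sweep(matrix(rnorm(50 * d), ncol = d) %*% chol(sigma), 2, 1:4, `+`)
  colnames(x) <- paste0("f", 1:d)
  m <- qda_fit(rbind(x, x + 5), rep(cs_labels(), each = 50))
  cm <- m$classes$hairpin
  # x = mu -> 0
  expect_equal(mahalanobis_sq(cm, matrix(cm$mu, 1)), 0, tolerance = 1e-18)
  # matches stats::mahalanobis (explicit inverse) on random points
  pts <- matrix(rnorm(20 * d, 1), ncol = d)
  expect_equal(mahalanobis_sq(cm, pts),
               unname(stats::mahalanobis(pts, cm$mu, cm$sigma)),
               tolerance = 1e-8)
  expect_true(all(mahalanobis_sq(cm, pts) >= 0))
  # identity covariance -> squared Euclidean distance
  id <- qda_fit(rbind(diag(2) * 0, diag(2), -diag(2), 2 * diag(2)) +
                  matrix(rnorm(16, sd = 1e-6), 8, 2,
                         dimnames = list(NULL, c("u", "v"))),
                rep(cs_labels(), each = 4))
  cmu <- id$classes$hairpin
  cmu$mu <- c(u = 0, v = 0)
  cmu$chol <- chol(diag(2))
  cmu$log_det <- 0
  pt <- matrix(c(3, 4), 1)
  expect_equal(mahalanobis_sq(cmu, pt), 25)
})

test_that("eta is exactly ln p - delta/2 - log|Sigma|/2", {
  withr::local_seed(406)
  tc <- rand_two_class(30, 3, delta = 2)
  m <- qda_fit(tc$x, tc$labels)
  cm <- m$classes$hairpin
  # all terms vanish for p = 1, Sigma = I, x = mu
  unit <- list(p = 1L, mu = c(a = 0, b = 0), sigma = diag(2),
               epsilon = 0, chol = chol(diag(2)), log_det = 0)
  expect_equal(eta_score(unit, matrix(0, 1, 2)), 0)
  # doubling delta lowers eta by delta/2
  pt <- matrix(rnorm(3), 1)
  delta <- mahalanobis_sq(cm, pt)
  eta1 <- eta_score(cm, pt)
  pt2 <- matrix(cm$mu + sqrt(2) * (pt - cm$mu), 1)  # delta doubles
  expect_equal(mahalanobis_sq(cm, pt2), 2 * delta, tolerance = 1e-10)
  expect_equal(eta_score(cm, pt2), eta1 - delta / 2, tolerance = 1e-10)
})

test_that("eta_i - eta_j equals the independently expanded discriminant", {
  withr::local_seed(407)
  for (i in 1:10) {
    d <- sample(2:6, 1)
    tc <- rand_two_class(sample(15:60, 1), d, delta = 1)
    m <- qda_fit(tc$x, tc$labels)
    ci <- m$classes$hairpin
    cj <- m$classes$not_hairpin
    x <- matrix(rnorm(40 * d), ncol = d)
    xi_direct <- eta_score(ci, x) - eta_score(cj, x)
    # expansion: ln(p_i/p_j) - (delta_i - delta_j)/2 - ln(|S_i|/|S_j|)/2
    # with explicit determinants and inverses
    di <- unname(stats::mahalanobis(x, ci$mu, ci$sigma))
    dj <- unname(stats::mahalanobis(x, cj$mu, cj$sigma))
    xi_expanded <- log(ci$p / cj$p) - (di - dj) / 2 -
      0.5 * log(det(ci$sigma) / det(cj$sigma))
    expect_equal(xi_direct, xi_expanded, tolerance = 1e-10)
  }
})

test_that("prediction is the eta argmax with hairpin winning exact ties", {
  withr::local_seed(408)
  tc <- rand_two_class(40, 3, delta = 3)
  m <- qda_fit(tc$x, tc$labels)
  pred <- predict(m, tc$x)
  expect_equal(pred$xi, pred$eta_hairpin - pred$eta_not_hairpin)
  expect_equal(pred$predicted,
               ifelse(pred$xi > -1e-12, "hairpin", "not_hairpin"))
  # symmetric model, midpoint -> tie -> hairpin by convention
  sym <- m
  sym$classes$not_hairpin <- sym$classes$hairpin
  sym$classes$not_hairpin$mu <- -sym$classes$hairpin$mu
  mid <- matrix(0, 1, 3, dimnames = list(NULL, colnames(tc$x)))
  tie <- predict(sym, mid)
  expect_lt(abs(tie$xi), 1e-12)
  expect_equal(tie$predicted, "hairpin")
})

test_that("prediction agrees exactly with a dense log-posterior oracle", {
  withr::local_seed(409)
  for (i in 1:10) {
    d <- sample(2:8, 1)
    tc <- rand_two_class(sample(12:80, 1), d, delta = runif(1, 0, 2))
    m <- qda_fit(tc$x, tc$labels)
    x <- matrix(rnorm(200 * d, sd = 2), ncol = d,
                dimnames = list(NULL, colnames(tc$x)))
    expect_identical(predict(m, x)$predicted, oracle_predict(m, x))
  }
})

test_that("equal-covariance equal-prior fits give a linear decision boundary", {
  withr::local_seed(410)
  d <- 3
  sigma <- rand_spd(d)
  # force exactly equal fitted covariances/priors: mirror the same cloud
  a <- matrix(rnorm(60 * d), ncol = d) %*% chol(sigma)
  mu_sep <- c(2, -1, 1)
  x <- rbind(sweep(a, 2, mu_sep, `+`), sweep(a, 2, -mu_sep, `+`))
  colnames(x) <- paste0("f", 1:d)
  m <- qda_fit(x, rep(cs_labels(), each = 60))
  ch <- m$classes$hairpin
  cn <- m$classes$not_hairpin
  expect_equal(ch$sigma, cn$sigma)  # same centred cloud by construction
  # closed-form linear discriminant: w'x + b with w = S^-1 (mu1 - mu0)
  s_inv <- solve(ch$sigma)
  w <- s_inv %*% (ch$mu - cn$mu)
  b <- -0.5 * drop(t(ch$mu) %*% s_inv %*% ch$mu) +
    0.5 * drop(t(cn$mu) %*% s_inv %*% cn$mu)
  pts <- matrix(rnorm(1000 * d, sd = 3), ncol = d,
                dimnames = list(NULL, colnames(x)))
  lin <- drop(pts %*% w) + b
  expect_identical(predict(m, pts)$predicted,
                   ifelse(lin > -1e-12, "hairpin", "not_hairpin"))
})

test_that("feature-name mismatches are contract errors, permutations are aligned", {
  withr::local_seed(411)
  tc <- rand_two_class(20, 3)
  m <- qda_fit(tc$x, tc$labels)
  x <- tc$x[1:5, c(3, 1, 2)]
  expect_equal(predict(m, x)$eta_hairpin,
               predict(m, tc$x[1:5, ])$eta_hairpin)
  colnames(x) <- c("bad", "names", "here")
  expect_error(predict(m, x), "feature names")
})

test_that("the R coefficient follows its definition in both sign regimes", {
  expect_equal(r_coefficient(2, 2), 0)
  expect_equal(r_coefficient(2, 1), 0.5)
  # negative-eta regime: R = 1 - eta_wro/eta_corr
  expect_equal(r_coefficient(-2, -1), 0.5)
  expect_equal(r_coefficient(-2, -4), -1)
  expect_true(is.na(r_coefficient(0, 1)))
})

test_that("the correction forgives near-misses below r_max only", {
  pred <- data.frame(fragment_id = c("a", "b", "c", "d"),
                     eta_hairpin = c(-10, -10, -5, 0),
                     eta_not_hairpin = c(-9, -4, -6, 1),
                     xi = c(-1, -6, 1, -1),
                     predicted = c("not_hairpin", "not_hairpin",
                                   "hairpin", "not_hairpin"),
                     corrected = FALSE, r_value = NA_real_,
                     stringsAsFactors = FALSE)
  class(pred) <- c("cs_predictions", "data.frame")
  truth <- c("hairpin", "hairpin", "hairpin", "hairpin")
  out <- apply_r_correction(pred, truth, r_max = 0.2)
  # a: R = (-10 - -9)/-10 = 0.1 < 0.2 -> corrected
  expect_true(out$corrected[1])
  expect_equal(out$r_value[1], 0.1)
  # b: R = (-10 - -4)/-10 = 0.6 -> not corrected
  expect_false(out$corrected[2])
  # c: correctly classified -> untouched
  expect_false(out$corrected[3])
  expect_true(is.na(out$r_value[3]))
  # d: eta_corr = 0 -> undefined R, reported and left uncorrected
  expect_false(out$corrected[4])
  log <- attr(out, "correction_log")
  expect_equal(nrow(log), 3L)
  expect_match(log$note[log$fragment_id == "d"], "undefined")
  # r_max = 0: none of these negative-eta misses qualifies (R >= 0)
  out0 <- apply_r_correction(pred, truth, r_max = 0)
  expect_false(any(out0$corrected))
  expect_error(apply_r_correction(pred, truth[1:2]), "length")
})

test_that("model serialisation round-trips to full precision", {
  withr::local_seed(412)
  tc <- rand_two_class(40, 6)
  colnames(tc$x) <- cs_nuclei()
  m <- qda_fit(tc$x, tc$labels, epsilon = 1e-6)
  f <- tempfile(fileext = ".json")
  write_qda_model(m, f)
  m2 <- read_qda_model(f)
  expect_equal(m2$epsilon, 1e-6)
  pts <- matrix(rnorm(100 * 6), ncol = 6,
                dimnames = list(NULL, cs_nuclei()))
  expect_identical(eta_score(m$classes$hairpin, pts),
                   eta_score(m2$classes$hairpin, pts))
  expect_identical(predict(m, pts)$xi, predict(m2, pts)$xi)
  # truncated file is a format error
  txt <- readLines(f)
  f2 <- tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 50), f2)
  expect_error(read_qda_model(f2), "malformed model file")
})
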