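# Independent oracles and fixture builders used across the test files.
# Every oracle deliberately takes a different computational path from the
# implementation it checks (explicit inverses, double loops, closed
# forms), so agreement is evidence rather than tautology.

# random symmetric positive-definite matrix
rand_spd <- function(d) {
  a <- matrix(stats::rnorm(d * d), d, d)
  crossprod(a) / d + diag(0.5, d)
}

# full Gaussian log-posterior (up to the shared normalising constant of
# the total count) via explicit matrix inverse and determinant
oracle_log_posterior <- function(class_model, x) {
  mu <- class_model$mu
  sigma <- class_model$sigma + diag(class_model$epsilon, length(mu))
  inv <- solve(sigma)
  apply(x, 1L, function(r) {
    d <- r - mu
    log(class_model$p) - 0.5 * length(mu) * log(2 * pi) -
      0.5 * log(det(sigma)) - 0.5 * drop(t(d) %*% inv %*% d)
  })
}

# class argmax under the dense log-posterior oracle
oracle_predict <- function(model, x) {
  lp <- cbind(hairpin = oracle_log_posterior(model$classes$hairpin, x),
              not_hairpin = oracle_log_posterior(model$classes$not_hairpin,
                                                 x))
  colnames(lp)[max.col(lp, ties.method = "first")]
}

# mean and maximum-likelihood covariance by brute-force double loop
oracle_mean_cov <- function(x) {
  n <- nrow(x)
  d <- ncol(x)
  mu <- numeric(d)
  for (i in seq_len(n)) mu <- mu + unname(x[i, ])
  mu <- mu / n
  sigma <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      s <- 0
      for (r in seq_len(n)) s <- s + (x[r, i] - mu[i]) * (x[r, j] - mu[j])
      sigma[i, j] <- s / n
    }
  }
  list(mu = mu, sigma = sigma)
}

# pooled-variance two-sample t statistic
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# random labelled residue-level dataset for I/O round-trip properties
rand_dataset <- function(n_frag = 6L, max_len = 12L, missing_rate = 0.1) {
  frames <- lapply(seq_len(n_frag), function(i) {
    l <- sample(3:max_len, 1L)
    shifts <- matrix(round(stats::rnorm(l * 6L, 50, 20), 3L), l, 6L)
    shifts[matrix(stats::runif(l * 6L) < missing_rate, l, 6L)] <- NA
    colnames(shifts) <- paste0("cs_", cs_nuclei())
    data.frame(protein_id = sprintf("P%02d", i),
               fragment_id = sprintf("F%02d", i),
               class = sample(cs_labels(), 1L),
               pos = seq_len(l),
               aa = sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], l,
                           replace = TRUE),
               shifts, stringsAsFactors = FALSE)
  })
  cs_dataset(do.call(rbind, frames))
}

# labelled feature matrix drawn from two Gaussians, as a cs-features-like
# plain matrix + labels (for direct qda_fit tests)
rand_two_class <- function(n_per_class, d, delta = 0) {
  sigma <- rand_spd(d)
  mu <- stats::rnorm(d)
  x <- rbind(sweep(matrix(stats::rnorm(n_per_class * d), ncol = d) %*%
                     chol(sigma), 2L, mu, `+`),
             sweep(matrix(stats::rnorm(n_per_class * d), ncol = d) %*%
                     chol(sigma), 2L, mu + delta, `+`))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, labels = rep(cs_labels(), each = n_per_class))
}
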