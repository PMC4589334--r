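# Internal helpers shared across modules.

.LABELS <- c("hairpin", "not_hairpin")
.POSITIVE <- "hairpin"
.NUCLEI <- c("C", "CA", "CB", "HN", "HA", "N")
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Canonical nucleus order
#'
#' The six backbone/side-chain nuclei used as chemical-shift features, in
#' the fixed order used for every vector and covariance index in the
#' package: carbonyl C, C-alpha, C-beta, amide proton HN, H-alpha, amide
#' nitrogen N.
#'
#' @return Character vector of the six nucleus codes.
#' @export
#' @examples
#' cs_nuclei()
cs_nuclei <- function() .NUCLEI

#' Class labels
#'
#' The two fragment classes recognised throughout the package.  The
#' positive class ("hairpin") always comes first.
#'
#' @return Character vector `c("hairpin", "not_hairpin")`.
#' @export
cs_labels <- function() .LABELS

.shift_cols <- function(nuclei = .NUCLEI) paste0("cs_", nuclei)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  `seed = NULL` evaluates expr untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.as_label <- function(x, arg = "label") {
  x <- as.character(x)
  bad <- !x %in% .LABELS
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s (expected %s)", arg,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(.LABELS, collapse = " or ")), call. = FALSE)
  }
  factor(x, levels = .LABELS)
}

# Minimal decimal rendering that survives a read-back bit-exactly: use R's
# default 15-significant-digit formatting where it round-trips, fall back
# to 17 digits otherwise.
.format_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  ok <- !is.na(x)
  s <- vapply(x[ok], function(v) {
    r <- format(v, digits = 15L, scientific = FALSE, trim = TRUE)
    if (as.numeric(r) == v) r else sprintf("%.17g", v)
  }, character(1L))
  out[ok] <- s
  out
}
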