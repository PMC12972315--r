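#' Quadrant counts of a paired sample after a median split
#'
#' Splits the plane at the sample medians of `x` and `y` and assigns each
#' observation to exactly one of the four quadrants (I: high/high, II:
#' low/high, III: low/low, IV: high/low). Points lying exactly on a median
#' line are assigned to the concordant quadrant for the hypothesized
#' direction (I/III when `direction = "positive"`, II/IV when `"negative"`)
#' and their number is reported separately, so the four counts always
#' partition the sample.
#'
#' @param x,y numeric vectors of equal length (pairs with missing values are
#'   dropped with a message).
#' @param direction the hypothesized association direction governing where
#'   boundary points fall.
#' @return object of class `quadrant_counts`: list with `n_i`, `n_ii`,
#'   `n_iii`, `n_iv`, `boundary_count`, `n`.
#' @export
quadrant_counts <- function(x, y, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  s <- paired_clean(x, y)
  x <- s$x; y <- s$y; n <- s$n
  if (n < 2L) stop("need at least 2 paired observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("association undefined: `x` or `y` is constant", call. = FALSE)
  }
  dx <- x - median(x)
  dy <- y - median(y)
  on_boundary <- dx == 0 | dy == 0
  q <- integer(n)
  q[dx > 0 & dy > 0] <- 1L
  q[dx < 0 & dy > 0] <- 2L
  q[dx < 0 & dy < 0] <- 3L
  q[dx > 0 & dy < 0] <- 4L
  if (direction == "positive") {
    q[on_boundary & dx >= 0 & dy >= 0] <- 1L
    q[on_boundary & q == 0L] <- 3L
  } else {
    q[on_boundary & dx <= 0 & dy >= 0] <- 2L
    q[on_boundary & q == 0L] <- 4L
  }
  structure(
    list(n_i = sum(q == 1L), n_ii = sum(q == 2L), n_iii = sum(q == 3L),
         n_iv = sum(q == 4L), boundary_count = sum(on_boundary), n = n),
    class = "quadrant_counts"
  )
}

#' @exportS3Method base::print
print.quadrant_counts <- function(x, ...) {
  cat("Quadrant counts (n =", x$n, "):",
      "I =", x$n_i, " II =", x$n_ii, " III =", x$n_iii, " IV =", x$n_iv, "\n")
  if (x$boundary_count > 0L) {
    cat("  points on a median line:", x$boundary_count, "\n")
  }
  invisible(x)
}

#' Quadrant count ratio (QCR)
#'
#' The fraction of observations in the direction-concordant quadrants after a
#' median split: `QCR+ = (n_I + n_III)/n` for a hypothesized positive
#' monotone association, `QCR- = (n_II + n_IV)/n` for a negative one. Values
#' near 1 indicate strong concordance; values near 0.5 indicate no
#' directional preference. Invariant under strictly monotone transforms of
#' either variable.
#'
#' @inheritParams quadrant_counts
#' @return a value in `[0, 1]`.
#' @export
qcr <- function(x, y, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  qc <- quadrant_counts(x, y, direction)
  if (direction == "positive") (qc$n_i + qc$n_iii) / qc$n
  else (qc$n_ii + qc$n_iv) / qc$n
}

#' Pearson and Spearman correlation of a paired sample
#'
#' Thin validating wrappers around [stats::cor()]: product-moment
#' correlation, and rank correlation with average ranks for ties. Both
#' require at least 3 complete pairs and nonzero variance in each variable.
#'
#' @inheritParams quadrant_counts
#' @return a value in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  s <- paired_clean(x, y)
  check_correlatable(s)
  cor(s$x, s$y, method = "pearson")
}

#' @rdname pearson_r
#' @export
spearman_rho <- function(x, y) {
  s <- paired_clean(x, y)
  check_correlatable(s)
  cor(s$x, s$y, method = "spearman")
}

# Drop incomplete pairs (with a message) and validate lengths.
paired_clean <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) {
    message("dropping ", sum(!ok), " incomplete pair(s)")
  }
  list(x = x[ok], y = y[ok], n = sum(ok))
}

check_correlatable <- function(s) {
  if (s$n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(s$x) == 0 || stats::var(s$y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  invisible(s)
}
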