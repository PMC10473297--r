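#' Lin's concordance between two vectors
#'
#' `C = 2 Cov(x, y) / (Var(x) + Var(y) + (mean(x) - mean(y))^2)`, with
#' population (1/n) moments.  Concordance equals the Pearson correlation
#' when the two vectors share mean and variance and is otherwise strictly
#' smaller in magnitude, which makes it sensitive to amplitude differences
#' between co-fluctuation patterns — two identical patterns at different
#' scales correlate at 1 but are far from concordant.
#'
#' Degenerate conventions: two equal constant vectors have concordance 1;
#' two unequal constant vectors, 0.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Scalar in `[-1, 1]`.
#' @export
lin_concordance <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("x and y must have equal length >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  mx <- mean(x); my <- mean(y)
  vx <- mean(x^2) - mx^2; vy <- mean(y^2) - my^2
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(if (isTRUE(all.equal(mx, my))) 1 else 0)
  num <- 2 * (mean(x * y) - mx * my)
  max(-1, min(1, num / den))
}

# Pairwise Lin's concordance over the rows of a matrix (vectorized).
lin_concordance_matrix <- function(X) {
  E <- ncol(X)
  m <- rowMeans(X)
  v <- rowMeans(X^2) - m^2
  G <- tcrossprod(X) / E - tcrossprod(m)          # population covariances
  D <- outer(v, v, "+") + outer(m, m, "-")^2
  C <- ifelse(D == 0, 1, 2 * G / pmax(D, .Machine$double.xmin))
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  C
}

#' Pairwise concordance matrix of peak co-fluctuation patterns
#'
#' @param patterns a `cofluct_patterns` object (or plain patterns x edges
#'   matrix) with at least 2 rows.
#' @return Symmetric P x P concordance matrix with unit diagonal, carrying
#'   the pattern metadata as attribute `meta` when available.
#' @export
concordance_matrix <- function(patterns) {
  X <- if (inherits(patterns, "cofluct_patterns")) patterns$edges else as.matrix(patterns)
  if (nrow(X) < 2L) stop("need at least 2 patterns")
  C <- lin_concordance_matrix(X)
  if (inherits(patterns, "cofluct_patterns")) attr(C, "meta") <- patterns$meta
  C
}
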