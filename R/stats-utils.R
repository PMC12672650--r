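## Small shared statistics helpers used by the MR, pool and abundance stages.

#' Fisher combination of independent p-values
#'
#' Combines k p-values with Fisher's method: -2 * sum(log p) is chi-square
#' distributed with 2k degrees of freedom under the joint null. Zero
#' p-values are clamped to the smallest positive double with a warning.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return the combined p-value.
#' @export
fisher_combine <- function(p) {
  stopifnot(length(p) >= 1, all(is.finite(p)), all(p >= 0), all(p <= 1))
  if (any(p == 0)) {
    warning("p-value of 0 clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  stat <- -2 * sum(log(p))
  stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

#' Cosine similarity of two non-negative profiles
#'
#' @param x,y numeric vectors of equal length, not both zero.
#' @return cosine of the angle between x and y.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

## Orthonormal basis of the sum-zero subspace of R^k (k x (k-1) matrix).
## Delta profiles live in this subspace because they are differences of
## two sum-1 vectors.
sum_zero_basis <- function(k) {
  h <- stats::contr.helmert(k)           # columns orthogonal, sum to 0
  sweep(h, 2, sqrt(colSums(h^2)), "/")
}

## Paired two-tailed t-test p-value via closed form; NA if fewer than two
## complete pairs or zero variance of the differences.
paired_t_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2) return(NA_real_)
  sd_d <- stats::sd(d)
  if (sd_d == 0) return(if (all(d == 0)) 1 else 0)
  tt <- mean(d) / (sd_d / sqrt(n))
  2 * stats::pt(abs(tt), df = n - 1, lower.tail = FALSE)
}

## Two-sample pooled-variance (Student) t statistic and p-value.
student_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (mean(a) - mean(b)) / se
  list(t = tt, p = 2 * stats::pt(abs(tt), df = na + nb - 2,
                                 lower.tail = FALSE), se = se)
}
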