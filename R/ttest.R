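#' Unpaired two-sample t-test (pooled variance)
#'
#' Classical Student t-test with pooled variance, two-sided, on
#' \code{n_a + n_b - 2} degrees of freedom. Degenerate inputs are given
#' defined answers rather than errors: zero pooled variance with equal
#' means yields \code{t = 0, p = 1}; zero pooled variance with unequal
#' means yields \code{p = 0} with a warning (the data claim an effect with
#' no measured noise).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch if \code{TRUE}, use the Welch (unequal-variance) form with
#'   Satterthwaite degrees of freedom instead of the pooled form.
#' @return List with \code{t}, \code{p} (two-sided) and \code{df}.
#' @export
unpaired_ttest <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 observations")
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- if (se2 > 0)
      se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    else na + nb - 2
    se <- sqrt(se2)
  } else {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  }
  if (se == 0) {
    if (ma == mb) return(list(t = 0, p = 1, df = df))
    warning("zero variance with unequal means: p = 0")
    return(list(t = sign(ma - mb) * Inf, p = 0, df = df))
  }
  t <- (ma - mb) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# Vectorized pooled t-test over matrix rows: x is values, ctrl/trt column
# index vectors; returns per-row two-sided p (and t). Degenerate rows get
# the same semantics as unpaired_ttest, without per-row warnings.
row_pooled_ttest <- function(x, ctrl, trt) {
  na <- length(ctrl); nb <- length(trt)
  a <- x[, ctrl, drop = FALSE]; b <- x[, trt, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (mb - ma) / se           # treated minus control
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se == 0
  if (any(zero)) {
    eq <- zero & (ma == mb)
    t[eq] <- 0; p[eq] <- 1
    ne <- zero & (ma != mb)
    t[ne] <- sign(mb - ma)[ne] * Inf; p[ne] <- 0
  }
  list(t = t, p = p, df = df)
}
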