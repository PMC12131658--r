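## stats_core: the statistical procedures behind the screening cascade,
## implemented in-package. Multiplicity-adjusted p-values (Dunnett,
## Tukey) are computed by deterministic quadrature over the classical
## one-factor reductions; see stats-mcp.R.

.as_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  lapply(groups, function(v) {
    v <- as.numeric(v)
    if (any(!is.finite(v))) stop("non-finite values in group sample",
                                 call. = FALSE)
    v
  })
}

.pooled_var <- function(groups) {
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop("every group entering a variance computation needs n >= 2",
                        call. = FALSE)
  df <- sum(n - 1L)
  ss <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1.0))
  list(s2 = ss / df, df = df, n = n)
}

#' One-way fixed-effects analysis of variance
#'
#' Classical between/within F-ratio; the p-value is evaluated through the
#' regularized incomplete beta function (the F tail in closed form).
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return List with `F`, `df_between`, `df_within`, `p`, and `degenerate`
#'   (TRUE when the within-group variance is zero: `F = 0, p = 1` if the
#'   group means also coincide, else complete separation with `p` below
#'   machine epsilon).
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
one_way_anova <- function(groups) {
  groups <- .as_groups(groups)
  k <- length(groups)
  stopifnot(k >= 2)
  n <- vapply(groups, length, 1L)
  N <- sum(n)
  if (N <= k) stop("total n must exceed the number of groups", call. = FALSE)
  means <- vapply(groups, mean, 1.0)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1.0))
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) {
      return(list(F = 0, df_between = df1, df_within = df2, p = 1,
                  degenerate = TRUE))
    }
    return(list(F = Inf, df_between = df1, df_within = df2, p = 0,
                degenerate = TRUE))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  ## P(F > f) = I_{df2/(df2 + df1 f)}(df2/2, df1/2)
  p <- stats::pbeta(df2 / (df2 + df1 * Fstat), df2 / 2, df1 / 2)
  list(F = Fstat, df_between = df1, df_within = df2, p = p,
       degenerate = FALSE)
}

#' Welch two-sample t-test (unequal variances)
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df` (Satterthwaite), `p` (two-sided), and
#'   `degenerate` (both variances zero).
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = na + nb - 2, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0,
                degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       degenerate = FALSE)
}

#' Step-down Sidak (Holm-Sidak) multiple-testing adjustment
#'
#' Sorts the raw p-values ascending and applies the Sidak bound with a
#' shrinking multiplicity at each step,
#' `adj_(i) = max_{j <= i} 1 - (1 - p_(j))^(m - j + 1)`, clipped at 1;
#' results are returned in the original order. Adjusted values dominate
#' the raw ones and are monotone along the sorted sequence.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same order as `p`.
#' @examples
#' holm_sidak(c(0.01, 0.04))  # c(1 - 0.99^2, 0.04)
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric())
  ord <- order(p)
  step <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(step), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Holm (Bonferroni step-down) adjustment
#'
#' Available as the alternative correction behind the tertiary tier;
#' delegates to [stats::p.adjust()].
#'
#' @inheritParams holm_sidak
#' @return Adjusted p-values in the original order.
#' @export
bonferroni_holm <- function(p) stats::p.adjust(p, method = "holm")

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normalizing transforms of sample skewness (D'Agostino)
#' and kurtosis (Anscombe-Glynn) into `K2 = Z1^2 + Z2^2`, referred to a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param x Numeric vector, `n >= 8` (the kurtosis transform is undefined
#'   below that).
#' @return List with `K2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance: normality test undefined",
                               call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  ## skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)
  ## kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(K2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}
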