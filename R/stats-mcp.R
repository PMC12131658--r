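## Many-to-one (Dunnett) and all-pairs (Tukey) adjusted p-values by
## deterministic quadrature.
##
## Both joint distributions admit a one-factor reduction: conditionally
## on the pooled-SD variate S = s_p/sigma (a scaled chi with the error
## df) and on a single shared standard-normal variate, the component
## t-statistics are independent, and the joint CDF is an expectation of
## a product of univariate normal probabilities. The outer integral over
## S is evaluated by Gauss-Legendre on the probability scale (substituting
## S through its quantile function), the inner normal expectation by
## Gauss-Hermite. Node counts are refined until successive evaluations
## agree below 1e-7, giving deterministic p-values (Monte-Carlo is used
## only as an independent oracle in the test suite).

.gauss_legendre_01 <- function(n) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  list(x = gl$x, w = gl$w)
}

.gauss_hermite_prob <- function(n) {
  ## nodes/weights for E[f(Z)], Z ~ N(0,1)
  gh <- pracma::gaussHermite(n)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

## P(max_j |T_j| <= t) for the Dunnett statistic, vectorized over t.
## lambda_j = sqrt(n_j / (n_j + n0)) encodes the correlation structure
## rho_ij = lambda_i * lambda_j. df = Inf gives the known-variance case.
.dunnett_pmaxabs_nodes <- function(t, lambda, df, n_gl, n_gh) {
  t <- abs(t)
  lam <- sort(unique(lambda))
  counts <- vapply(lam, function(l) sum(lambda == l), 1L)
  gh <- .gauss_hermite_prob(n_gh)
  if (is.finite(df)) {
    gl <- .gauss_legendre_01(n_gl)
    s <- sqrt(stats::qchisq(gl$x, df) / df)
    ws <- gl$w
  } else {
    s <- 1
    ws <- 1
  }
  ns <- length(s); nz <- length(gh$x); nt <- length(t)
  ## node grid: rows = (s, z0) pairs, cols = t
  sv <- rep(s, times = nz)
  zv <- rep(gh$x, each = ns)
  wv <- rep(ws, times = nz) * rep(gh$w, each = ns)
  logprod <- matrix(0, ns * nz, nt)
  for (i in seq_along(lam)) {
    a <- sqrt(1 - lam[i]^2)
    upper <- outer(sv, t) + lam[i] * zv       # (t*s + lambda*z0)
    lower <- -outer(sv, t) + lam[i] * zv
    f <- stats::pnorm(upper / a) - stats::pnorm(lower / a)
    f[f < 0] <- 0
    logprod <- logprod + counts[i] * log(f)
  }
  as.vector(wv %*% exp(logprod))
}

.refine <- function(fun, n0 = 32L, tol = 1e-7, max_doublings = 3L) {
  prev <- fun(n0)
  n <- n0
  for (i in seq_len(max_doublings)) {
    n <- n * 2L
    cur <- fun(n)
    if (max(abs(cur - prev)) < tol) return(cur)
    prev <- cur
  }
  prev
}

#' Joint CDF of the maximum absolute Dunnett statistic
#'
#' `P(max_j |T_j| <= t)` for `k` treatment-vs-control t-statistics
#' sharing a control of size `n0` and a pooled SD with `df` degrees of
#' freedom. Exposed for diagnostics and oracle comparisons.
#'
#' @param t Quantile(s).
#' @param n_treat Integer vector of treatment group sizes.
#' @param n_control Control group size.
#' @param df Error degrees of freedom (may be `Inf`).
#' @param tol Successive-refinement tolerance on the CDF.
#' @return Numeric vector, same length as `t`.
#' @export
pdunnett_maxabs <- function(t, n_treat, n_control, df, tol = 1e-7) {
  lambda <- sqrt(n_treat / (n_treat + n_control))
  .refine(function(n) .dunnett_pmaxabs_nodes(t, lambda, df, n, n), tol = tol)
}

#' Dunnett many-to-one comparisons against a shared control
#'
#' Computes the pooled-variance t-statistic of every treatment against
#' the control and adjusts two-sidedly for the family by referring each
#' `|t_i|` to the joint distribution of the maximum absolute statistic
#' (single-step Dunnett), evaluated by quadrature to `tol`. Directional
#' decisions (e.g. keeping only better-than-control survival) are the
#' caller's concern; see [call_secondary()].
#'
#' @param treatments Named list of numeric vectors, one per treatment.
#' @param control Numeric vector of control values.
#' @param tol Absolute tolerance of the adjusted p-values.
#' @return data.frame with one row per treatment: `label`, `estimate`
#'   (mean difference vs control), `statistic`, `df`, `p_raw`
#'   (unadjusted two-sided t), `p_adj`, `method`.
#' @examples
#' dunnett_adjusted(list(a = c(5, 6, 7)), control = c(1, 2, 3))
#' @export
dunnett_adjusted <- function(treatments, control, tol = 1e-7) {
  if (length(treatments) == 0L) {
    return(data.frame(label = character(), estimate = numeric(),
                      statistic = numeric(), df = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      method = character(), stringsAsFactors = FALSE))
  }
  treatments <- .as_groups(treatments)
  control <- as.numeric(control)
  if (any(!is.finite(control))) stop("non-finite control values", call. = FALSE)
  pv <- .pooled_var(c(treatments, list(.control = control)))
  if (pv$s2 <= 0) stop("pooled within-group variance is zero", call. = FALSE)
  n0 <- length(control)
  ni <- vapply(treatments, length, 1L)
  m0 <- mean(control)
  est <- vapply(treatments, mean, 1.0) - m0
  se <- sqrt(pv$s2 * (1 / ni + 1 / n0))
  tstat <- est / se
  lambda <- sqrt(ni / (ni + n0))
  p_raw <- 2 * stats::pt(-abs(tstat), pv$df)
  if (length(treatments) == 1L) {
    ## a single comparison is exactly the pooled two-sided t-test
    p_adj <- p_raw
  } else {
    pmax_cdf <- .refine(
      function(n) .dunnett_pmaxabs_nodes(abs(tstat), lambda, pv$df, n, n),
      n0 = if (tol >= 1e-4) 16L else 32L, tol = tol
    )
    p_adj <- pmin(pmax(1 - pmax_cdf, p_raw), 1)
  }
  data.frame(label = names(treatments), estimate = est, statistic = tstat,
             df = pv$df, p_raw = p_raw, p_adj = p_adj,
             method = "dunnett_two_sided", row.names = NULL,
             stringsAsFactors = FALSE)
}

## Studentized range CDF: P(Q_{k,df} <= q) by the classical double
## integral, with the inner normal expectation under Gauss-Hermite and
## the outer pooled-SD integral on the probability scale.
.tukey_cdf_nodes <- function(q, k, df, n_gl, n_gh) {
  gh <- .gauss_hermite_prob(n_gh)
  if (is.finite(df)) {
    gl <- .gauss_legendre_01(n_gl)
    s <- sqrt(stats::qchisq(gl$x, df) / df)
    ws <- gl$w
  } else {
    s <- 1
    ws <- 1
  }
  vapply(q, function(qq) {
    if (qq <= 0) return(0)
    ## range probability at width w: k * E_Z[(pnorm(Z) - pnorm(Z - w))^(k-1)]
    inner <- vapply(s, function(sv) {
      w <- qq * sv
      sum(gh$w * (stats::pnorm(gh$x) - stats::pnorm(gh$x - w))^(k - 1))
    }, 1.0)
    sum(ws * k * inner)
  }, 1.0)
}

#' Studentized range distribution function (in-package evaluation)
#'
#' @param q Quantile(s) of the studentized range.
#' @param k Number of groups.
#' @param df Error degrees of freedom (may be `Inf`).
#' @param tol Refinement tolerance.
#' @return `P(Q <= q)`.
#' @export
ptukey_range <- function(q, k, df, tol = 1e-7) {
  .refine(function(n) .tukey_cdf_nodes(q, k, df, n, n), tol = tol)
}

#' Tukey honestly-significant-difference all-pairs comparisons
#'
#' Pairwise mean differences on the pooled within-group SD, referred to
#' the studentized range distribution with `k` groups and the pooled df;
#' unbalanced pairs use the Tukey-Kramer form
#' `q = |diff| / sqrt(s2/2 * (1/n_i + 1/n_j))`.
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param tol Absolute tolerance of adjusted p-values.
#' @return data.frame with one row per unordered pair: `label`
#'   (`"a-b"`), `estimate`, `statistic` (q), `df`, `p_raw` (pooled
#'   two-sided t), `p_adj`, `method`.
#' @export
tukey_hsd <- function(groups, tol = 1e-7) {
  groups <- .as_groups(groups)
  k <- length(groups)
  stopifnot(k >= 2)
  pv <- .pooled_var(groups)
  if (pv$s2 <= 0) stop("pooled within-group variance is zero", call. = FALSE)
  labs <- names(groups)
  means <- vapply(groups, mean, 1.0)
  n <- pv$n
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    diff <- means[i] - means[j]
    q <- abs(diff) / sqrt(pv$s2 / 2 * (1 / n[i] + 1 / n[j]))
    tt <- diff / sqrt(pv$s2 * (1 / n[i] + 1 / n[j]))
    data.frame(label = paste(labs[i], labs[j], sep = "-"),
               estimate = diff, statistic = q, df = pv$df,
               p_raw = 2 * stats::pt(-abs(tt), pv$df),
               method = "tukey_hsd", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (k == 2L) {
    ## q = |t| * sqrt(2): the range of two groups is exactly the t-test
    out$p_adj <- out$p_raw
  } else {
    p_adj <- 1 - ptukey_range(out$statistic, k, pv$df, tol = tol)
    out$p_adj <- pmin(pmax(p_adj, out$p_raw), 1)
  }
  rownames(out) <- NULL
  out[c("label", "estimate", "statistic", "df", "p_raw", "p_adj", "method")]
}
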