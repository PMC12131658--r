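test_that("one-way ANOVA matches the classical F and handles degeneracy", {
  # identical groups: no between-group variance
  r0 <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # complete separation with zero within-group variance
  rs <- one_way_anova(list(a = c(0, 0, 0), b = c(1, 1, 1)))
  expect_true(rs$degenerate)
  expect_lt(rs$p, .Machine$double.eps)
  # random 3-group fixture against the independent linear-model fit
  set.seed(5)
  g <- list(a = rnorm(6, 0), b = rnorm(4, 0.8), c = rnorm(7, -0.3))
  mine <- one_way_anova(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  ref <- anova(lm(y ~ grp, data = df))
  expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(mine$df_between, ref$Df[1])
  expect_equal(mine$df_within, ref$Df[2])
})

test_that("Welch t matches the reference implementation", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  rd <- welch_t(c(0, 0), c(1, 1))
  expect_true(rd$degenerate)
  expect_lt(rd$p, .Machine$double.eps)
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(sample(3:10, 1), 0, 1)
    b <- rnorm(sample(3:10, 1), 0.5, 2)
    mine <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("step-down Sidak adjustment follows the closed form", {
  expect_equal(holm_sidak(0.03), 0.03)
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  # order preserved, dominance and step-down monotonicity
  set.seed(9)
  for (i in 1:10) {
    p <- runif(sample(1:20, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("D'Agostino-Pearson omnibus test behaves under null and skew", {
  # frozen oracle value (computed independently from the published
  # normalizing transforms on this fixed sample)
  x <- c(2.1, 3.4, 1.9, 2.8, 3.1, 2.5, 2.2, 3.9, 2.7, 3.0,
         1.5, 2.9, 3.3, 2.4, 2.6, 3.6, 2.0, 2.85, 3.2, 2.55)
  r <- dagostino_pearson(x)
  expect_equal(r$K2, 0.02797979, tolerance = 1e-6)
  expect_equal(r$p, 0.98610751, tolerance = 1e-6)
  # null calibration: p approximately uniform
  set.seed(10)
  p0 <- replicate(200, dagostino_pearson(rnorm(100))$p)
  expect_gt(mean(p0 < 0.5), 0.35)
  expect_lt(mean(p0 < 0.5), 0.65)
  expect_lte(mean(p0 < 0.05), 0.12)
  # power against strong skew
  set.seed(11)
  p1 <- replicate(40, dagostino_pearson(rexp(200))$p)
  expect_gte(mean(p1 < 0.01), 0.95)
  expect_error(dagostino_pearson(rep(1, 20)), "variance")
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("Dunnett comparisons agree with the multivariate-t reference", {
  skip_if_not_installed("mvtnorm")
  set.seed(12)
  for (case in list(list(k = 2, n = c(4, 4), n0 = 5),
                    list(k = 3, n = c(3, 5, 4), n0 = 6),
                    list(k = 5, n = rep(4, 5), n0 = 4))) {
    groups <- lapply(seq_len(case$k),
                     function(j) rnorm(case$n[j], 0.5 * (j %% 2)))
    names(groups) <- paste0("t", seq_len(case$k))
    control <- rnorm(case$n0)
    res <- dunnett_adjusted(groups, control)
    df <- sum(case$n - 1) + case$n0 - 1
    lam <- sqrt(case$n / (case$n + case$n0))
    R <- outer(lam, lam)
    diag(R) <- 1
    for (i in seq_len(case$k)) {
      ref <- 1 - mvtnorm::pmvt(lower = rep(-abs(res$statistic[i]), case$k),
                               upper = rep(abs(res$statistic[i]), case$k),
                               df = df, corr = R,
                               algorithm = mvtnorm::GenzBretz(abseps = 1e-6))
      # GenzBretz is itself Monte-Carlo; its realized error dominates
      expect_equal(res$p_adj[i], as.numeric(ref), tolerance = 1e-3)
    }
    expect_true(all(res$p_adj >= res$p_raw))
  }
})

test_that("a single Dunnett comparison is exactly the pooled t-test", {
  set.seed(13)
  a <- rnorm(5, 1)
  ctrl <- rnorm(6)
  res <- dunnett_adjusted(list(a = a), ctrl)
  df <- data.frame(y = c(a, ctrl),
                   g = rep(c("a", "c"), c(length(a), length(ctrl))))
  ref <- t.test(y ~ g, data = df, var.equal = TRUE)
  expect_equal(res$p_adj, ref$p.value, tolerance = 1e-9)
  expect_equal(res$p_raw, ref$p.value, tolerance = 1e-12)
  expect_equal(dunnett_adjusted(list(), numeric())$label, character())
})

test_that("the studentized range CDF matches stats::ptukey", {
  for (k in c(3, 5, 8)) {
    for (df in c(5, 20, 100)) {
      q <- c(1.5, 2.5, 3.5, 4.5)
      expect_equal(ptukey_range(q, k, df), ptukey(q, k, df),
                   tolerance = 2e-6)
    }
  }
})

test_that("Tukey HSD reduces to the t-test at k = 2 and matches TukeyHSD", {
  set.seed(14)
  a <- rnorm(6, 0.4)
  b <- rnorm(5)
  res2 <- tukey_hsd(list(a = a, b = b))
  ref2 <- t.test(a, b, var.equal = TRUE)
  expect_equal(res2$p_adj, ref2$p.value, tolerance = 1e-9)
  # q = |t| * sqrt(2) identity
  expect_equal(res2$statistic, abs(unname(ref2$statistic)) * sqrt(2),
               tolerance = 1e-12)

  g <- list(a = rnorm(6), b = rnorm(4, 0.8), c = rnorm(5, -0.4))
  mine <- tukey_hsd(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  ref <- TukeyHSD(aov(y ~ grp, data = df))$grp
  ref_lab <- rownames(ref)
  for (i in seq_len(nrow(mine))) {
    parts <- strsplit(mine$label[i], "-")[[1]]
    j <- which(ref_lab == mine$label[i] |
                 ref_lab == paste(parts[2], parts[1], sep = "-"))
    expect_length(j, 1)
    expect_equal(mine$p_adj[i], unname(ref[j, "p adj"]), tolerance = 1e-4)
  }
  # identical groups: all adjusted p near 1
  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_true(all(same$p_adj > 1 - 1e-6))
})
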