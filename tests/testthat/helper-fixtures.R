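# shared fixtures and independent Monte-Carlo oracles

# minimal well table; survival s encoded with 1000 nuclei per well
make_wells <- function(treatment, klass, survival, run_id = "R1",
                       plate_id = "P1", n = 1000L) {
  k <- length(treatment)
  data.frame(
    plate_id = rep_len(plate_id, k), run_id = rep_len(run_id, k),
    row = (seq_len(k) - 1L) %% 16L, col = (seq_len(k) - 1L) %/% 16L,
    treatment = treatment, klass = klass,
    n_nuclei = rep_len(n, k),
    n_pi_pos = as.integer(round(rep_len(n, k) * (1 - survival))),
    stringsAsFactors = FALSE
  )
}

make_dataset <- function(...) screen_dataset(make_wells(...), validate = FALSE)

# z-table row builder for direct hit-calling tests
make_ztable <- function(treatment, klass, run_id, z) {
  k <- length(treatment)
  structure(
    data.frame(treatment = treatment, klass = rep_len(klass, k),
               run_id = rep_len(run_id, k),
               plate_id = rep_len("P1", k), row = rep_len(0L, k),
               col = rep_len(0L, k), survival = rep_len(0.5, k), z = z,
               stringsAsFactors = FALSE),
    class = c("z_table", "data.frame"))
}

# Monte-Carlo oracle: P(max_j |T_j| >= t) for the Dunnett statistic,
# simulated from its definition (group means + pooled chi variate)
mc_dunnett_pmax <- function(t, n_treat, n_control, df, nsim, seed) {
  set.seed(seed)
  k <- length(n_treat)
  z0 <- rnorm(nsim, 0, 1 / sqrt(n_control))
  s <- sqrt(rchisq(nsim, df) / df)
  mx <- rep(0, nsim)
  for (j in seq_len(k)) {
    zj <- rnorm(nsim, 0, 1 / sqrt(n_treat[j]))
    tj <- abs(zj - z0) / (s * sqrt(1 / n_treat[j] + 1 / n_control))
    mx <- pmax(mx, tj)
  }
  vapply(t, function(tt) mean(mx >= tt), 1.0)
}

# Monte-Carlo oracle for the studentized range tail P(Q_{k,df} >= q)
mc_tukey_tail <- function(q, k, df, nsim, seed) {
  set.seed(seed)
  z <- matrix(rnorm(nsim * k), nsim, k)
  rng <- apply(z, 1, max) - apply(z, 1, min)
  qq <- rng / sqrt(rchisq(nsim, df) / df)
  vapply(q, function(x) mean(qq >= x), 1.0)
}

# deterministic tertiary fixture: `strong` candidates far separated,
# `weak` nominally significant only, `null` unprotected
make_tertiary_fixture <- function(n_strong = 4, n_weak = 8, n_null = 16) {
  syms <- sprintf("C%02d", seq_len(n_strong + n_weak + n_null))
  mk <- function(vals) vals
  asyn <- list(); gfp <- list()
  for (i in seq_along(syms)) {
    if (i <= n_strong) {
      asyn[[i]] <- c(139, 140, 141)     # tight, strongly protected
      gfp[[i]] <- c(99, 100, 101)
    } else if (i <= n_strong + n_weak) {
      asyn[[i]] <- c(114, 120, 126)     # moderate protection, nominal only
      gfp[[i]] <- c(96, 100, 104)
    } else {
      asyn[[i]] <- c(96, 100, 104)      # no specific protection
      gfp[[i]] <- c(97, 101, 105)
    }
  }
  names(asyn) <- names(gfp) <- syms
  list(symbols = syms, asyn = asyn, gfp = gfp)
}
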