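# Independent oracles used across the suite. These deliberately avoid the
# closed forms and code paths they are checking: quadrature is plain
# composite-Simpson on a dense grid, and simulation oracles are written
# directly against the definitions.

# Simpson's rule on [lo, hi] with n+1 points (n even)
simpson <- function(f, lo, hi, n = 2000L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(lo, hi, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * (hi - lo) / (3 * n)
}

# Dirichlet-multinomial evidence of a single (y, f) row by quadrature:
# int p^(y+a-1) (1-p)^(f+a-1) dp / B(a, a)
dm_evidence_quad <- function(y, f, a = 1, n = 4000L) {
  # substitute p = sin^2(u) to tame endpoint singularities when a < 1 is
  # not used here, but the substitution is harmless for a = 1
  g <- function(u) {
    p <- sin(u)^2
    p^(y + a - 1) * (1 - p)^(f + a - 1) * 2 * sin(u) * cos(u)
  }
  simpson(g, 0, pi / 2, n) / beta(a, a)
}

# Two-sided contingency BF by genuine 2-D grid integration of both
# evidences (alternative: independent p1, p2; null: shared p)
contingency_bf_quad <- function(y1, n1, y2, n2, a = 1, n = 3000L) {
  ev_alt <- dm_evidence_quad(y1, n1 - y1, a, n) *
    dm_evidence_quad(y2, n2 - y2, a, n)
  ev_null <- dm_evidence_quad(y1 + y2, n1 + n2 - y1 - y2, a, n)
  ev_alt / ev_null
}

# Posterior of the log odds ratio by a fine 2-D grid over (p1, p2):
# returns the posterior median
grid_logodds_median <- function(y1, n1, y2, n2, a = 1, m = 1200L) {
  p <- (seq_len(m) - 0.5) / m
  w1 <- dbeta(p, a + y1, a + n1 - y1)
  w2 <- dbeta(p, a + y2, a + n2 - y2)
  lo <- qlogis(p)
  delta <- outer(lo, lo, "-")
  w <- outer(w1, w2)
  ord <- order(delta)
  cs <- cumsum(w[ord]) / sum(w)
  delta[ord][which.max(cs >= 0.5)]
}

# JZS Bayes factor via the g-mixture representation on a dense log grid
jzs_bf_g_oracle <- function(t, n1, n2, rscale = sqrt(2) / 2) {
  neff <- n1 * n2 / (n1 + n2)
  df <- n1 + n2 - 2
  u <- seq(-14, 14, length.out = 20001L)
  g <- exp(u)
  du <- u[2L] - u[1L]
  pig <- sqrt(rscale^2 / 2) / gamma(0.5) * g^(-1.5) *
    exp(-rscale^2 / (2 * g))
  integrand <- (1 + neff * g)^(-0.5) *
    (1 + t^2 / ((1 + neff * g) * df))^(-(df + 1) / 2) * pig * g
  (sum(integrand) * du) / (1 + t^2 / df)^(-(df + 1) / 2)
}

# Brute-force two-look optional stopping (written independently of the
# package's sequential machinery): test at n and, if not significant, at
# 2n; two-sample, unit-normal nulls
two_look_rate_oracle <- function(n, n_sims, alpha = 0.05) {
  hits <- 0L
  for (i in seq_len(n_sims)) {
    x <- rnorm(2L * n)
    y <- rnorm(2L * n)
    p1 <- t.test(x[seq_len(n)], y[seq_len(n)], var.equal = TRUE)$p.value
    if (p1 < alpha) {
      hits <- hits + 1L
    } else if (t.test(x, y, var.equal = TRUE)$p.value < alpha) {
      hits <- hits + 1L
    }
  }
  hits / n_sims
}

# E[|d|] and E[|d| | significant] for a single-look two-sample null study
selected_d_oracle <- function(n, n_sims, alpha = 0.05) {
  x <- matrix(rnorm(n * n_sims), n)
  y <- matrix(rnorm(n * n_sims), n)
  mx <- colMeans(x)
  my <- colMeans(y)
  vx <- colSums((x - rep(mx, each = n))^2) / (n - 1)
  vy <- colSums((y - rep(my, each = n))^2) / (n - 1)
  sp2 <- (vx + vy) / 2
  d <- (mx - my) / sqrt(sp2)
  tt <- d * sqrt(n / 2)
  p <- 2 * pt(-abs(tt), 2 * n - 2)
  list(mean_abs_all = mean(abs(d)),
       mean_abs_sig = mean(abs(d)[p < alpha]),
       sig_rate = mean(p < alpha))
}

mc_se <- function(p, n) sqrt(p * (1 - p) / n)
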