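# Independent brute-force oracles used to cross-check the implementation.

# Kendall tau-b by exhaustive O(n^2) pair counting with tie correction.
taub_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) {
        tie_x <- tie_x + 1L
        tie_y <- tie_y + 1L
      } else if (dx == 0) {
        tie_x <- tie_x + 1L
      } else if (dy == 0) {
        tie_y <- tie_y + 1L
      } else if (dx == dy) {
        conc <- conc + 1L
      } else {
        disc <- disc + 1L
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# Spearman rho by the classic sum-of-squared-rank-differences formula
# (valid for tie-free samples).
rho_oracle_noties <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Two-tailed Mann-Whitney p by full enumeration of all group assignments.
mw_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n_a * (n_a + 1) / 2
  }
  u_obs <- u_of(seq_len(n_a))
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, u_of)
  mu <- n_a * length(b) / 2
  # two-tailed: double the smaller tail of the exact null distribution
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(p, 1))
}

# Manders coefficients by direct elementwise summation.
manders_oracle <- function(ref, qry) {
  list(
    m1 = sum(qry[ref > 0]) / sum(qry),
    m2 = sum(ref[qry > 0]) / sum(ref)
  )
}
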