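# Independent oracles used across the suite. Each re-derives a quantity by
# brute force (dense grids, exhaustive enumeration, direct substring
# checks), deliberately avoiding the code paths it is used to check.

# --- marginal likelihood -----------------------------------------------

# Conjugate closed form at fixed sigma via the full n x n covariance
# (the implementation goes through the p x p information matrix instead).
oracle_lml_fixed_sigma <- function(y, s, X, tau, sigma) {
  S <- X %*% diag(tau^2, ncol(X)) %*% t(X) + diag(s^2 + sigma^2,
                                                  length(y))
  R <- chol(S)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(R))) +
            sum(backsolve(R, y, transpose = TRUE)^2))
}

# Dense 2-D grid integration over (coefficient, sigma) for 1-column designs.
# Simpson in beta and in log-sigma; the likelihood is evaluated pointwise
# from its quadratic form, never through the package.
oracle_lml_grid_1col <- function(y, s, x, tau, sigma_scale,
                                 beta_lim = 12, n_beta = 801,
                                 sigma_range = c(1e-3, 10), n_sigma = 401) {
  simpson_w <- function(n, h) {
    w <- rep(c(2, 4), length.out = n)
    w[1] <- w[n] <- 1
    w * h / 3
  }
  bg <- seq(-beta_lim, beta_lim, length.out = n_beta)
  u <- seq(log(sigma_range[1]), log(sigma_range[2]), length.out = n_sigma)
  sg <- exp(u)
  wb <- log(simpson_w(n_beta, bg[2] - bg[1]))
  ws <- log(simpson_w(n_sigma, u[2] - u[1]))
  log_prior_b <- dnorm(bg, 0, tau, log = TRUE)
  log_prior_s <- 0.5 * log(2 / pi) - log(sigma_scale) -
    sg^2 / (2 * sigma_scale^2)
  rows <- vapply(seq_along(sg), function(j) {
    d <- s^2 + sg[j]^2
    base <- -0.5 * sum(log(2 * pi * d))
    # quadratic in beta: sum((y - x b)^2 / d)
    q0 <- sum(y^2 / d); q1 <- sum(x * y / d); q2 <- sum(x^2 / d)
    ll <- base - 0.5 * (q0 - 2 * bg * q1 + bg^2 * q2)
    m <- max(ll + log_prior_b + wb)
    m + log(sum(exp(ll + log_prior_b + wb - m))) +
      log_prior_s[j] + u[j] + ws[j]
  }, numeric(1))
  m <- max(rows)
  m + log(sum(exp(rows - m)))
}

# --- Fisher's exact ----------------------------------------------------

# Full hypergeometric enumeration over all tables with the observed
# margins, probabilities from log-binomial coefficients. Conventional
# two-sided rule (tables no more probable than the observed, with the
# usual 1e-7 relative tie tolerance).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p_obs <- logp[xs == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# --- two-sample KS -----------------------------------------------------

# Exact permutation null of D by exhaustive enumeration of group
# assignments (small samples, no ties).
oracle_ks_exact_p <- function(a, b) {
  ks_stat <- function(x, y) {
    grid <- sort(c(x, y))
    max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  }
  pooled <- c(a, b)
  d_obs <- ks_stat(a, b)
  sets <- combn(length(pooled), length(a))
  ds <- apply(sets, 2, function(ix) ks_stat(pooled[ix], pooled[-ix]))
  mean(ds >= d_obs - 1e-12)
}

# --- motif scanners ----------------------------------------------------

all_starts <- function(seq, word) {
  n <- nchar(seq); w <- nchar(word)
  if (n < w) return(integer(0))
  which(substring(seq, 1:(n - w + 1), w:n) == word)
}

# Presence of four G-tracts (length `tract`) chained by loops of 1-7 nt:
# positional reachability search, no regular expressions.
oracle_g4_tract <- function(seq, tract) {
  starts <- all_starts(seq, strrep("G", tract))
  if (length(starts) < 1) return(FALSE)
  reach <- starts  # tract-start positions reachable at level 1
  for (lev in 2:4) {
    nxt <- integer(0)
    for (q in reach) {
      lo <- q + tract + 1; hi <- q + tract + 7
      nxt <- c(nxt, starts[starts >= lo & starts <= hi])
    }
    reach <- unique(nxt)
    if (!length(reach)) return(FALSE)
  }
  TRUE
}

oracle_g4 <- function(seq) {
  oracle_g4_tract(seq, 2L) || oracle_g4_tract(seq, 3L)
}

oracle_paired_ggagg <- function(seq) {
  p <- all_starts(seq, "GGAGG")
  if (length(p) < 2) return(FALSE)
  for (i in seq_along(p)) {
    gap <- p - (p[i] + 5)          # linker length between motif copies
    if (any(gap >= 4 & gap <= 10)) return(TRUE)
  }
  FALSE
}

oracle_ggc_repeat <- function(seq) {
  length(all_starts(seq, "GCGGCGGCGGCG")) > 0
}

# --- folding -----------------------------------------------------------

# Exhaustive enumeration of all non-crossing canonical pairings (WC + GU
# wobble, min hairpin loop), exponential recursion -- tiny sequences only.
oracle_max_pairs <- function(seq, min_loop = 3) {
  chars <- strsplit(seq, "")[[1]]
  pairs_ok <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (!pairs_ok(chars[i], chars[k])) next
      best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  rec(1L, length(chars))
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
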