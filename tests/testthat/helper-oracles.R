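# Independent textbook-formula implementations used as oracles.  These are
# deliberately naive (explicit loops and sums) and share no code with the
# package.

midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, 0)
}

oracle_spearman <- function(x, y) {
  rx <- midranks(x)
  ry <- midranks(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / seq(i, m)))
  }
  q
}

oracle_chi2 <- function(a, b) {
  la <- sort(unique(a))
  lb <- sort(unique(b))
  obs <- matrix(0, length(la), length(lb))
  for (i in seq_along(a)) {
    obs[match(a[i], la), match(b[i], lb)] <- obs[match(a[i], la), match(b[i], lb)] + 1
  }
  e <- outer(rowSums(obs), colSums(obs)) / length(a)
  list(chi2 = sum((obs - e)^2 / e),
       df = (length(la) - 1) * (length(lb) - 1))
}

oracle_kruskal <- function(values, groups) {
  r <- midranks(values)
  N <- length(values)
  H <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    H <- H + sum(idx) * (mean(r[idx]) - (N + 1) / 2)^2
  }
  H <- 12 * H / (N * (N + 1))
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

oracle_bray <- function(u, v) {
  sum(abs(u - v)) / sum(u + v)
}

# a small profile matrix with sample/genus names
random_profile <- function(n, g, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n * g), n, g,
              dimnames = list(sprintf("s%03d", 1:n), sprintf("g%03d", 1:g)))
  1000 * m / rowSums(m)
}

# a compact scenario for fast pipeline-level tests
small_scenario <- function(seed = 1, n_samples = 300, ...) {
  synthetic_scenario(n_samples = n_samples, n_genera = 60, m_S = 6, m_N = 15,
                     seed = seed, ...)
}
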