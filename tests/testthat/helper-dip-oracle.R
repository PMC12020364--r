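# Brute-force reference for the Hartigan dip statistic, independent of the
# compiled implementation.
#
# The dip is min over unimodal CDFs G of sup |F_n - G|.  On the sample grid a
# minimising G can be taken piecewise linear with knots at the observed
# values, convex up to a mode block t, concave after it, and with at most one
# jump, located at the mode.  For each candidate mode block the minimal sup
# deviation is a small linear program; the dip is the minimum over modes.
#
# Variables per mode t (K unique values, cumulative counts c, n points):
#   g_1..g_t   values of G at u_1..u_t (g_t = left limit at the mode)
#   r_t..r_K   values of G at u_t..u_K (r_t = right value at the mode)
#   d          the sup deviation, minimised
# Band constraints use that G is nondecreasing, so on [u_i, u_{i+1}) the
# extremes are the right value at u_i and the left limit at u_{i+1}.

dip_oracle <- function(x) {
  stopifnot(length(x) >= 4, all(is.finite(x)))
  n <- length(x)
  xs <- sort(x)
  u <- unique(xs)
  K <- length(u)
  if (K == 1L) {
    return(1 / (2 * n))
  }
  cc <- cumsum(tabulate(match(xs, u), K)) / n # ECDF right values at u
  cl <- c(0, cc[-K]) # ECDF left limits at u

  best <- Inf
  for (t in seq_len(K)) {
    # variable layout: g_1..g_t, r_t..r_K, d
    ng <- t
    nr <- K - t + 1L
    nv <- ng + nr + 1L
    id <- nv # index of d
    ir <- function(i) ng + (i - t) + 1L # index of r_i, i in t..K

    rows <- list()
    rhs <- c()
    add <- function(a, b) {
      rows[[length(rows) + 1L]] <<- a
      rhs <<- c(rhs, b)
    }
    zero <- numeric(nv)

    for (i in seq_len(t)) {
      if (i < t) { # g_i >= cc[i] - d
        a <- zero; a[i] <- -1; a[id] <- -1; add(a, -cc[i])
      }
      a <- zero; a[i] <- 1; a[id] <- -1; add(a, cl[i]) # g_i <= cl[i] + d
    }
    for (i in t:K) {
      a <- zero; a[ir(i)] <- -1; a[id] <- -1; add(a, -cc[i]) # r_i >= cc[i] - d
      up <- if (i == t) cc[i] else cl[i] # jump top may reach cc[t] + d
      a <- zero; a[ir(i)] <- 1; a[id] <- -1; add(a, up)
    }
    # monotone
    if (t > 1) {
      for (i in 2:t) {
        a <- zero; a[i - 1] <- 1; a[i] <- -1; add(a, 0)
      }
    }
    a <- zero; a[t] <- 1; a[ir(t)] <- -1; add(a, 0) # g_t <= r_t
    if (t < K) {
      for (i in (t + 1):K) {
        a <- zero; a[ir(i - 1)] <- 1; a[ir(i)] <- -1; add(a, 0)
      }
    }
    # convexity of g on u_1..u_t
    if (t >= 3) {
      for (i in 2:(t - 1)) {
        a <- zero
        a[i - 1] <- -(u[i + 1] - u[i])
        a[i] <- (u[i + 1] - u[i]) + (u[i] - u[i - 1])
        a[i + 1] <- -(u[i] - u[i - 1])
        add(a, 0) # (g_i-g_{i-1})dx_r <= (g_{i+1}-g_i)dx_l
      }
    }
    # concavity of r on u_t..u_K
    if (nr >= 3) {
      for (i in (t + 1):(K - 1)) {
        a <- zero
        a[ir(i - 1)] <- (u[i + 1] - u[i])
        a[ir(i)] <- -(u[i + 1] - u[i]) - (u[i] - u[i - 1])
        a[ir(i + 1)] <- (u[i] - u[i - 1])
        add(a, 0)
      }
    }

    # explicit G <= 1 rows (x >= 0 is implicit in the solver)
    for (i in seq_len(nv - 1L)) {
      a <- zero; a[i] <- 1; add(a, 1)
    }

    A <- do.call(rbind, rows)
    obj <- zero; obj[id] <- 1
    # boot::simplex wants non-negative right-hand sides (rows with b < 0 are
    # flipped into >= constraints) and can mis-declare optimality on
    # degenerate systems, so every solution is verified for primal
    # feasibility; on failure the constraint rows are permuted to force a
    # different pivot path.
    for (attempt in 0:3) {
      ord <- if (attempt == 0) {
        seq_along(rhs)
      } else { # deterministic shuffle that leaves the caller's RNG untouched
        order(sin(seq_along(rhs) * (attempt * 97 + 13)))
      }
      Ap <- A[ord, , drop = FALSE]
      bp <- rhs[ord]
      neg <- bp < 0
      sol <- tryCatch(
        boot::simplex(
          a = obj,
          A1 = Ap[!neg, , drop = FALSE], b1 = bp[!neg],
          A2 = -Ap[neg, , drop = FALSE], b2 = -bp[neg],
          maxi = FALSE, n.iter = 2000
        ),
        error = function(e) NULL
      )
      if (!is.null(sol) && sol$solved == 1 &&
          max(A %*% sol$soln - rhs) <= 1e-8) {
        best <- min(best, sol$value)
        break
      }
    }
  }
  best
}
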