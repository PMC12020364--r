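test_that("odds ratio and Altman interval match the closed form", {
  r <- odds_ratio(10, 10, 10, 10)
  expect_equal(r$or, 1)
  expect_equal(r$ci, exp(c(-1, 1) * 1.96 * sqrt(0.4)))
  r16 <- odds_ratio(20, 5, 5, 20)
  expect_equal(r16$or, 16)
  expect_equal(r16$ci, exp(log(16) + c(-1, 1) * 1.96 * sqrt(1 / 20 + 1 / 5 + 1 / 5 + 1 / 20)))
  rc <- odds_ratio(10, 0, 5, 5)
  expect_true(rc$corrected)
  expect_equal(rc$or, (10.5 / 0.5) / (5.5 / 5.5))
  expect_error(odds_ratio(0, 0, 0, 0), "empty")
  expect_error(odds_ratio(-1, 2, 3, 4), "non-negative")
})

test_that("odds ratio is log-symmetric under exposure swap", {
  set.seed(14)
  for (i in 1:100) {
    cells <- rpois(4, 8) + 1
    a <- do.call(odds_ratio, as.list(cells))
    b <- do.call(odds_ratio, as.list(cells[c(3, 4, 1, 2)]))
    expect_equal(a$or, 1 / b$or, tolerance = 1e-12)
    expect_equal(a$ci, rev(1 / b$ci), tolerance = 1e-12)
  }
})

test_that("deterioration risk builds the 2x2 correctly and logs exclusions", {
  st <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    S_present = rep(c(TRUE, FALSE), each = 6),
    N_present = rep(c(FALSE, TRUE), each = 6),
    deteriorated = c(TRUE, TRUE, TRUE, TRUE, FALSE, NA,
                     FALSE, FALSE, FALSE, FALSE, TRUE, NA))
  expect_message(r <- deterioration_risk(st, "S_present"), "2 sample")
  expect_equal(r$cells, c(4, 1, 1, 4))
  expect_equal(r$or, 16)
  expect_equal(r$n_used, 10)
  # complementary exposures (both/neither empty) give reciprocal ORs
  rn <- suppressMessages(deterioration_risk(st, "N_present"))
  expect_equal(rn$or, 1 / r$or)
  st_const <- st
  st_const$S_present <- TRUE
  expect_error(suppressMessages(deterioration_risk(st_const, "S_present")),
               "zero margin.*S_present")
  st_out <- st
  st_out$deteriorated <- c(rep(TRUE, 10), NA, NA)
  expect_error(suppressMessages(deterioration_risk(st_out, "S_present")),
               "zero margin.*outcome")
})

test_that("chi-square and Kruskal-Wallis match textbook formulas", {
  a <- rep(c("x", "x", "y", "y"), c(10, 20, 20, 10))
  b <- rep(c("u", "v", "u", "v"), c(10, 20, 20, 10))
  r <- suppressWarnings(crosstab_chi2(a, b))
  expect_equal(r$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(r$df, 1)
  same <- rep(c("p", "q", "r"), each = 30)
  expect_lt(suppressWarnings(crosstab_chi2(same, same))$p, 1e-10)
  expect_error(crosstab_chi2(rep("a", 10), rep(c("x", "y"), 5)), "2 levels")

  kw <- kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, oracle_kruskal(c(1, 2, 3, 10, 11, 12),
                                    rep(c("a", "b"), each = 3)),
               tolerance = 1e-12)
  same_vals <- kruskal_wallis(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same_vals$H, 0, tolerance = 1e-12)
  expect_gt(same_vals$p, 0.99)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("BH respects edge cases and input order", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0,1\\]")
  set.seed(15)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_equal(q, oracle_bh(p))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_true(all(q >= p))
})

test_that("tolerance profile recovers constructed group-state coupling", {
  set.seed(16)
  n <- 80
  x <- c(rnorm(40, 100, 20), rnorm(40, 600, 50))
  na <- data.frame(sample_id = sprintf("s%02d", 1:n), abund_S = x,
                   abund_N = 1000 - x)
  ab <- cbind(
    g6a = rpois(n, exp(x / 200)),       # opportunists track the S network
    g6b = rpois(n, exp(x / 250)),
    g0a = rpois(n, exp((1000 - x) / 200)), # sensitive taxa oppose it
    g0b = rpois(n, exp((1000 - x) / 250)),
    g3a = rpois(n, 5),                  # indifferent
    g5const = rep(2, n))                # constant: undefined correlation
  rownames(ab) <- na$sample_id
  mf <- suppressMessages(macrofauna_table(
    ab, c(g6a = 6L, g6b = 6L, g0a = 0L, g0b = 0L, g3a = 3L, g5const = 5L)))
  tp <- tolerance_profile(na, mf, "S")
  expect_gt(tp$rho[tp$tolerance_group == 6], 0.5)
  expect_lt(tp$rho[tp$tolerance_group == 0], -0.5)
  expect_true(is.na(tp$rho[tp$tolerance_group == 5]))
  expect_true(all(tp$q >= tp$p, na.rm = TRUE))
  na_small <- na[1:5, ]
  expect_error(tolerance_profile(na_small, mf, "S"), "fewer than 10")
})

test_that("covariate association is exact for self and null covariates", {
  set.seed(17)
  n <- 60
  na <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   abund_S = runif(n, 0, 1000), abund_N = runif(n, 0, 1000))
  meta <- sample_metadata(data.frame(
    sample_id = na$sample_id,
    toc = na$abund_S,           # identical to the S network abundance
    ph = rep(7, n),             # constant: undefined
    distance = rnorm(n)))       # independent
  ca <- covariate_association(na, meta, fields = c("toc", "ph", "distance"),
                              network = "S")
  expect_equal(ca$rho[ca$field == "toc"], 1)
  expect_true(is.na(ca$rho[ca$field == "ph"]))
  expect_lt(abs(ca$rho[ca$field == "distance"]), 0.35)
})
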