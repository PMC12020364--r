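test_that("spearman_rho handles monotone, antitone and tied data", {
  expect_equal(spearman_rho(c(1, 2, 3, 5), c(2, 4, 6, 11))$rho, 1)
  expect_equal(spearman_rho(c(1, 2, 3, 5), c(9, 6, 4, 1))$rho, -1)
  expect_equal(spearman_rho(1:4, c(2, 4, 6, 8))$p, 0)
  s <- spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(s$rho, oracle_spearman(c(1, 2, 2, 4), c(1, 3, 2, 4)))
  d <- spearman_rho(rep(1, 5), 1:5)
  expect_true(is.na(d$rho) && is.na(d$p))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:3, 3:1), "n >= 4")
})

test_that("identical genera are perfectly correlated in the network", {
  set.seed(2)
  base <- runif(50, 1, 10)
  gp <- cbind(g1 = base, g2 = base, g3 = runif(50, 1, 10))
  gp <- 1000 * gp / rowSums(gp)
  rownames(gp) <- sprintf("s%02d", 1:50)
  net <- suppressMessages(build_network(gp, run_config(prevalence_min = 0,
                                                       abundance_min = 0)))
  expect_equal(unname(net$rho["g1", "g2"]), 1)
  expect_gte(net$n_pos[["g1"]], 1)
  expect_equal(unname(diag(net$rho)), rep(1, 3))
  expect_equal(net$rho, t(net$rho))
})

test_that("independent genera produce almost no strong edges", {
  gp <- random_profile(500, 40, seed = 11)
  net <- suppressMessages(build_network(gp, run_config(prevalence_min = 0,
                                                       abundance_min = 0)))
  ut <- upper.tri(net$rho)
  expect_lte(mean(abs(net$rho[ut]) > 0.3), 0.01)
  # q >= p after BH, everywhere defined
  expect_true(all(net$q[ut] >= net$p[ut] - 1e-12))
})

test_that("find_hub_pair locates a forced hub and errors on null data", {
  set.seed(5)
  n <- 300
  u <- runif(n)
  m <- sapply(1:30, function(i) 2 - u + rnorm(n, 0, 0.3)) # all anti-u
  gp <- cbind(A = 3 * u, m, matrix(runif(n * 10), n))
  colnames(gp) <- c("A", sprintf("anti%02d", 1:30), sprintf("bg%02d", 1:10))
  gp <- 1000 * gp / rowSums(gp)
  rownames(gp) <- sprintf("s%03d", 1:n)
  cfg <- run_config(prevalence_min = 0, abundance_min = 0)
  net <- suppressMessages(build_network(gp, cfg))
  hubs <- find_hub_pair(net, cfg)
  expect_equal(hubs$hub_S, "A") # maximal negative degree
  expect_lt(hubs$rho, -0.3)

  null_gp <- random_profile(250, 15, seed = 3)
  null_net <- suppressMessages(build_network(null_gp,
                                             run_config(prevalence_min = 0,
                                                        abundance_min = 0)))
  expect_error(find_hub_pair(null_net, cfg), "no opposing structure")
})

test_that("membership rule follows both inequalities exactly", {
  g <- c("hS", "hN", "g1", "g2", "g3", "g4")
  rho <- diag(6)
  dimnames(rho) <- list(g, g)
  rho["g1", "hN"] <- 0.5;  rho["g1", "hS"] <- -0.4  # N member
  rho["g2", "hN"] <- 0.2;  rho["g2", "hS"] <- -0.4  # fails positive rule
  rho["g3", "hS"] <- 0.31; rho["g3", "hN"] <- -0.31 # S member
  rho["g4", "hN"] <- 0.5;  rho["g4", "hS"] <- -0.2  # fails negative rule
  rho[upper.tri(rho)] <- t(rho)[upper.tri(rho)] # mirror the lower triangle
  net <- structure(list(genera = g, rho = rho, rho_pos = 0.3, rho_neg = -0.3),
                   class = "cooccurrence_network")
  hubs <- list(hub_S = "hS", hub_N = "hN")
  nd <- suppressMessages(assign_memberships(net, hubs, run_config()))
  expect_identical(nd$members_N, "g1")
  expect_identical(nd$members_S, "g3")
  expect_length(intersect(nd$members_S, nd$members_N), 0)
  # idempotent / order-independent: permuting genera gives the same sets
  perm <- c(4, 2, 6, 1, 3, 5)
  net2 <- structure(list(genera = g[perm], rho = rho[perm, perm],
                         rho_pos = 0.3, rho_neg = -0.3),
                    class = "cooccurrence_network")
  nd2 <- suppressMessages(assign_memberships(net2, hubs, run_config()))
  expect_identical(nd2$members_N, nd$members_N)
  expect_identical(nd2$members_S, nd$members_S)
})

test_that("network abundance is an exact block column sum", {
  gp <- random_profile(20, 10, seed = 7)
  nd <- list(hub_S = "g001", members_S = c("g002", "g003"),
             hub_N = "g004", members_N = character())
  na <- network_abundance(gp, nd)
  expect_equal(na$abund_S, unname(rowSums(gp[, c("g001", "g002", "g003")])))
  expect_equal(na$abund_N, unname(gp[, "g004"]))
  nd_all <- list(hub_S = "g001", members_S = sprintf("g%03d", 2:10),
                 hub_N = "g001", members_N = character())
  expect_equal(network_abundance(gp, nd_all)$abund_S, rep(1000, 20),
               tolerance = 1e-9)
  nd_missing <- list(hub_S = "g001", members_S = "nope",
                     hub_N = "g004", members_N = character())
  expect_warning(network_abundance(gp, nd_missing), "absent")
})

test_that("phylum enrichment is symmetric and flags exclusivity", {
  nd <- list(hub_S = "hS", hub_N = "hN",
             members_S = sprintf("s%02d", 1:19),
             members_N = sprintf("n%02d", 1:19))
  # balanced phylum: 10 vs 10 in equal-size networks -> OR = 1
  phylum2 <- c(hS = "PX", hN = "PX",
               setNames(c(rep("PA", 10), rep("PB", 9)), sprintf("s%02d", 1:19)),
               setNames(c(rep("PA", 10), rep("PB", 9)), sprintf("n%02d", 1:19)))
  enr <- phylum_enrichment(nd, phylum2)
  expect_equal(enr$or[enr$phylum == "PA"], 1)
  # exclusive phylum: only in S -> corrected OR above 1
  phylum3 <- c(hS = "PX", hN = "PX",
               setNames(rep("ONLY_S", 19), sprintf("s%02d", 1:19)),
               setNames(rep("PB", 19), sprintf("n%02d", 1:19)))
  enr3 <- phylum_enrichment(nd, phylum3)
  row <- enr3[enr3$phylum == "ONLY_S", ]
  expect_true(row$corrected)
  expect_gt(row$or, 1)
})

test_that("BH adjustment of the network is monotone on sorted p-values", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), oracle_bh(p))
  expect_equal(bh_fdr(p), rep(0.04, 4))
})
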