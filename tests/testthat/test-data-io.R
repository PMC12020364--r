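test_that("count table round-trips losslessly through TSV", {
  m <- matrix(c(0:5, 10:15), nrow = 3,
              dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
  ct <- count_table(m)
  expect_identical(dim(ct), c(3L, 4L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  ct2 <- suppressMessages(read_count_table(path))
  expect_equal(unclass(ct2), unclass(ct))
})

test_that("count table validation rejects bad input by name", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(count_table(m), "duplicate sample id.*a")
  m2 <- matrix(c(1, -2, 3, 4), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(count_table(m2), "negative count.*'b'.*'x'")
  m3 <- matrix(1:2, 2, 1, dimnames = list(c("a", "b"), "x"))
  expect_error(count_table(cbind(m3)), "at least 2")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tt1\tt2", "s1\t1\t2", "s1\t3\t4"), tsv)
  expect_error(suppressMessages(read_count_table(tsv)), "duplicate sample")
})

test_that("genus aggregation sums OTUs and conserves totals", {
  ct <- count_table(matrix(c(3, 1, 4, 2, 5, 9), 2,
                           dimnames = list(c("s1", "s2"),
                                           c("o1", "o2", "o3"))))
  tax <- taxonomy_map(data.frame(taxon_id = c("o1", "o2", "o3"),
                                 genus = c("Ga", "Ga", "Gb"),
                                 phylum = "P1", kingdom = "Bacteria"))
  gt <- suppressMessages(aggregate_to_genus(ct, tax))
  expect_equal(unname(gt["s1", "Ga"]), 3 + 4)
  expect_equal(sum(gt), sum(ct))

  # all-distinct genera: identity up to relabeling
  tax2 <- taxonomy_map(data.frame(taxon_id = c("o1", "o2", "o3"),
                                  genus = c("Gx", "Gy", "Gz"),
                                  phylum = "P1", kingdom = "Bacteria"))
  gt2 <- suppressMessages(aggregate_to_genus(ct, tax2))
  expect_equal(sort(colSums(gt2)), sort(colSums(ct)), ignore_attr = TRUE)

  # random table: per-sample totals unchanged
  set.seed(4)
  big <- count_table(matrix(rpois(20 * 50, 5), 20,
                            dimnames = list(sprintf("s%02d", 1:20),
                                            sprintf("o%02d", 1:50))))
  tax3 <- taxonomy_map(data.frame(taxon_id = colnames(big),
                                  genus = sample(sprintf("G%02d", 1:12), 50, TRUE),
                                  phylum = "P1", kingdom = "Bacteria"))
  gt3 <- suppressMessages(aggregate_to_genus(big, tax3))
  expect_equal(unname(rowSums(gt3)), unname(rowSums(big)))
})

test_that("unclassified genera are bucketed per phylum, not dropped", {
  ct <- count_table(matrix(c(3, 1, 4, 2), 2,
                           dimnames = list(c("s1", "s2"), c("o1", "o2"))))
  tax <- taxonomy_map(data.frame(taxon_id = c("o1", "o2"),
                                 genus = c("Ga", NA),
                                 phylum = c("P1", "P2"),
                                 kingdom = "Bacteria"))
  gt <- suppressMessages(aggregate_to_genus(ct, tax))
  expect_true("unclassified_P2" %in% colnames(gt))
  expect_equal(sum(gt), sum(ct))
  expect_true(attr(gt, "bucket")[["unclassified_P2"]])
  # empty intersection is a hard error
  tax_other <- taxonomy_map(data.frame(taxon_id = "zzz", genus = "G"))
  expect_error(aggregate_to_genus(ct, tax_other), "no taxa")
})

test_that("per-mille normalisation is exact and flags zero-sum samples", {
  ct <- count_table(matrix(c(1, 5, 1, 0, 2, 0), 2,
                           dimnames = list(c("s1", "s2"), c("a", "b", "c"))))
  gp <- to_relative_permille(ct)
  expect_equal(unname(gp["s1", ]), c(250, 250, 500))
  expect_equal(unname(gp["s2", ]), c(1000, 0, 0))
  set.seed(9)
  m <- count_table(matrix(rpois(300, 8) + 1, 15,
                          dimnames = list(sprintf("s%02d", 1:15),
                                          sprintf("g%02d", 1:20))))
  expect_true(all(abs(rowSums(to_relative_permille(m)) - 1000) < 1e-6))
  z <- count_table(matrix(c(1, 0, 2, 0), 2,
                          dimnames = list(c("ok", "empty"), c("a", "b"))))
  expect_error(to_relative_permille(z), "zero-sum sample.*empty")
})

test_that("run configuration validates and round-trips through file", {
  expect_error(run_config(rho_neg = 0.2), "rho_neg")
  expect_error(run_config(dip_replicates = 10))
  expect_error(run_config(gam_folds = 1))
  cfgfile <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("rho_pos = 0.25", "dip_replicates = 500", "seed = 42",
               "use_clr = FALSE", "# comment"), cfgfile)
  cfg <- read_config(cfgfile)
  expect_equal(cfg$rho_pos, 0.25)
  expect_equal(cfg$dip_replicates, 500L)
  expect_equal(cfg$seed, 42L)
  writeLines("nope = 1", cfgfile)
  expect_error(read_config(cfgfile), "unknown config key")
})

test_that("metadata validation enforces the nEQR domain and keeps NAs", {
  df <- data.frame(sample_id = c("a", "b"), neqr = c(0.5, NA))
  md <- sample_metadata(df)
  expect_true(is.na(md$neqr[2]))
  expect_error(sample_metadata(data.frame(sample_id = "a", neqr = 1.2)),
               "outside \\[0,1\\].*a")
})
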