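test_that("excess significance follows the G-squared formula", {
  # k = n * alpha exactly: no excess
  expect_equal(excess_significance(50, 1000, 0.05)$G2, 0)
  # direct evaluation: 2*(100*log(100/50) + 900*log(900/950))
  ex <- excess_significance(100, 1000, 0.05)
  expect_equal(ex$G2, 2 * (100 * log(2) + 900 * log(900 / 950)),
               tolerance = 1e-12)
  expect_equal(ex$df, 1L)
  expect_lt(ex$p, 1e-9)
  # boundaries handled by continuity
  expect_true(is.finite(excess_significance(0, 100)$G2))
  expect_true(is.finite(excess_significance(100, 100)$G2))
  expect_error(excess_significance(5, 0), ">= 1")
})

test_that("normalized and relative coupling obey their algebra", {
  nc <- normalized_coupling(rep(0.3, 10), 0.3)
  expect_equal(nc$normalized, rep(0, 10))
  expect_equal(nc$mean, 0)
  base <- c(0.2, 0.35, 0.4, 0.28, 0.31)
  n1 <- normalized_coupling(base, 0.25)
  n2 <- normalized_coupling(base + 0.2, 0.25)
  expect_equal(n2$mean, n1$mean + 0.2, tolerance = 1e-12)
  expect_equal(n2$normalized - n1$normalized, rep(0.2, 5))
  # one-sided p is at most the two-sided p for an upward shift
  expect_lte(n2$p_one, n2$p_two)

  expect_equal(relative_coupling(0.48, 0.30), 1.6)
  expect_equal(relative_coupling(0.30, 0.30), 1)
  expect_error(relative_coupling(0.3, 0), "positive")
})

test_that("coupling per type centres on the null for independent data", {
  tbl <- null_table(n_plots = 60, n_vars = 8, seed = 71)
  ed <- screen_associations(tbl, n_perm = 99, seed = 73)
  cp <- ecosystem_coupling(ed, n_perm = 49, seed = 79)
  expect_s3_class(cp, "data.frame")
  expect_true(all(c("Bacteria->Bacteria", "Bacteria->Fungi",
                    "Fungi->Bacteria", "Fungi->Fungi") %in%
                    cp$assoc_type))
  # observed mean q of independent data sits near the permutation null
  expect_lt(max(abs(cp$mean_normalized_all)), 0.05)
  # the identity mean(normalized) = observed_mean - null_mean
  expect_equal(cp$mean_normalized_all,
               cp$observed_mean_all - cp$null_mean, tolerance = 1e-12)
  expect_true(all(cp$frac_sig >= 0 & cp$frac_sig <= 1))
})

test_that("the coupling network mirrors the per-type table", {
  cp <- data.frame(
    assoc_type = c("Bacteria->Bacteria", "Bacteria->Fungi",
                   "Fungi->Bacteria", "Fungi->Fungi"),
    relative = c(1.5, 1.2, NA, 0.9),
    p_two_sig = c(0.01, 0.2, 0.5, 0.04),
    p_one_sig = c(0.005, 0.03, 0.5, 0.02),
    p_two_all = 1, p_one_all = 1,
    stringsAsFactors = FALSE)
  g <- coupling_network(cp)
  # NA-weight edge dropped, self-loops kept
  expect_equal(igraph::ecount(g), 3)
  ed <- igraph::as_data_frame(g)
  expect_equal(ed$weight[ed$from == "Bacteria" & ed$to == "Bacteria"],
               1.5)
  expect_equal(ed$tier, c("p<0.025", "p<0.05", "p<0.025"))
  tf <- tempfile(fileext = ".graphml")
  write_coupling_graphml(g, tf)
  expect_true(file.exists(tf) && file.size(tf) > 0)
})

test_that("null coupling is reproducible under a fixed seed", {
  tbl <- null_table(n_plots = 40, n_vars = 4, seed = 83)
  ed <- screen_associations(tbl, n_perm = 0, seed = 1)
  n1 <- null_coupling(ed, n_perm = 19, seed = 89)
  n2 <- null_coupling(ed, n_perm = 19, seed = 89)
  expect_identical(n1, n2)
  expect_true(all(is.finite(n1$null_mean)))
  # a single permutation still gives a finite null mean
  n3 <- null_coupling(ed, n_perm = 1, seed = 89)
  expect_true(all(is.finite(n3$null_mean)))
})
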