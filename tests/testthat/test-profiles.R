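test_that("range-box overlap hits its identities", {
  set.seed(41)
  A <- cbind(q = runif(60), m = runif(60, -1, 1))
  expect_equal(dynrb_port(A, A), 1)
  # disjoint q ranges: no overlap at any level
  B <- cbind(q = runif(60, 2, 3), m = runif(60, -1, 1))
  expect_equal(dynrb_port(A, B), 0)
  # A covering exactly half of B in each dimension at gamma = 0
  Bx <- cbind(q = c(0, 1), m = c(0, 1))
  Ax <- cbind(q = c(0, 0.5), m = c(0, 0.5))
  expect_equal(dynrb_port(Ax, Bx, gamma_grid = 0), 0.25)
  # degenerate B interval contributes 0
  Bd <- cbind(q = c(0.5, 0.5), m = c(0, 1))
  expect_equal(dynrb_port(Ax, Bd, gamma_grid = 0), 0)
  expect_error(dynrb_port(A[0, ], B), "non-empty")
  expect_error(dynrb_port(A, B, gamma_grid = 0.6), "0, 0.5")
})

test_that("enlarging A never decreases port(A, B)", {
  set.seed(43)
  B <- cbind(q = runif(40), m = runif(40, -1, 1))
  A <- cbind(q = runif(10, 0.2, 0.4), m = runif(10, -0.2, 0.2))
  A_big <- rbind(A, cbind(q = runif(30), m = runif(30, -1, 1)))
  expect_gte(dynrb_port(A_big, B), dynrb_port(A, B))
})

test_that("profile dissimilarity is a symmetric zero-diagonal matrix", {
  set.seed(47)
  profs <- list(
    a = cbind(q = runif(30), m = runif(30, -1, 1)),
    b = cbind(q = runif(30), m = runif(30, -1, 1)),
    c = cbind(q = runif(30, 0.8, 1), m = runif(30, 0.8, 1)))
  d <- profile_dissimilarity(profs)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(profile_dissimilarity(list(x = profs$a, y = profs$a))["x", "y"],
               0)
})

test_that("clustering joins the closest pair first with high support", {
  set.seed(53)
  # two tight families far apart in q
  fam1 <- function() cbind(q = runif(40, 0, 0.2), m = runif(40, -1, 1))
  fam2 <- function() cbind(q = runif(40, 0.8, 1), m = runif(40, -1, 1))
  profs <- list(A = fam1(), B = fam1(), C = fam2())
  cl <- cluster_profiles(profs, n_boot = 100, seed = 59)
  # A and B merge before C joins
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  expect_true(all(cl$support >= 0 & cl$support <= 1))
  # the A+B clade is recovered in at least 95% of bootstrap trees
  expect_gte(cl$support[2], 0.95)
  # Newick export parses back with support labels
  tf <- tempfile(fileext = ".nwk")
  write_profile_tree(cl, tf)
  phy <- ape::read.tree(tf)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
})

test_that("per-type tests are Bonferroni-corrected and detect shifts", {
  set.seed(61)
  # planted +0.3 shift in q between two types, n = 200 each
  e1 <- fake_edges(rep("A->B", 200), rep("positive", 200),
                   q = runif(200, 0.2, 0.5), m = runif(200))
  e2 <- fake_edges(rep("B->A", 200), rep("positive", 200),
                   q = runif(200, 0.5, 0.8), m = runif(200))
  res <- per_type_tests(rbind(e1, e2))
  qrow <- res$tests[res$tests$metric == "q", ]
  expect_lt(qrow$p_bonferroni, 0.001)
  expect_true(all(res$tests$p_bonferroni >= res$tests$p))
  # distinguishable types get different letters on q
  expect_false(res$letters$letters_q[1] == res$letters$letters_q[2])
  # identical distributions are indistinguishable: shared letter, p = 1
  e3 <- fake_edges(rep("A->B", 50), rep("positive", 50),
                   q = rep(seq(0, 1, length.out = 25), 2),
                   m = rep(seq(-1, 1, length.out = 25), 2))
  e4 <- e3; e4$assoc_type <- "B->A"
  res2 <- per_type_tests(rbind(e3, e4))
  expect_equal(res2$tests$p_bonferroni, rep(1, 2))
  expect_equal(res2$letters$letters_q[1], res2$letters$letters_q[2])
})
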