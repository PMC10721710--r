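test_that("pruning keeps exactly the variables with enough unique values", {
  set.seed(3)
  vals <- cbind(
    v15 = rep(1:15, length.out = 30),
    v16 = rep(1:16, length.out = 30),
    vconst = rep(2, 30),
    vfull = rnorm(30))
  rownames(vals) <- sprintf("p%02d", 1:30)
  tbl <- abundance_table(vals, groups = rep("Environment", 4),
                         gradient = 1:30, kind = rep("measurement", 4))
  expect_setequal(prune_variables(tbl), c("v16", "vfull"))
  expect_setequal(prune_variables(tbl, min_unique = 15),
                  c("v15", "v16", "vfull"))
})

test_that("co-occurrence requires joint presence on enough plots", {
  n <- 135
  vals <- cbind(
    taxA = c(rep(1, 15), rep(0, n - 15)),
    taxB = rep(1, n),
    taxC = c(rep(1, 20), rep(0, n - 20)),
    env1 = rnorm(n), env2 = rnorm(n))
  rownames(vals) <- sprintf("p%03d", 1:n)
  tbl <- abundance_table(vals,
                         groups = c("Fungi", "Bacteria", "Bacteria",
                                    "Environment", "Environment"),
                         gradient = 1:n,
                         kind = c("count", "count", "count",
                                  "measurement", "measurement"))
  # two taxa jointly present on only 15 plots: rejected
  expect_null(co_occurrence_plots(tbl, "taxA", "taxB"))
  # taxon vs environment: the taxon's 20 presence plots
  expect_length(co_occurrence_plots(tbl, "taxC", "env1"), 20)
  # two environment variables: all plots
  expect_length(co_occurrence_plots(tbl, "env1", "env2"), n)
})

test_that("permutation p-values use the add-one estimator", {
  set.seed(5)
  pt <- permutation_test_q(1:100, 1:100, n_perm = 999)
  expect_equal(pt$p_xy, 0.001)   # smallest attainable p
  expect_equal(pt$p_yx, 0.001)
  expect_length(pt$null_q_xy, 999)
  # with n_perm = 0 the point estimates survive, p is NA
  pt0 <- permutation_test_q(1:100, 1:100, n_perm = 0)
  expect_identical(pt0$q_xy, pt$q_xy)
  expect_true(is.na(pt0$p_xy))
})

test_that("association classification follows the significance rules", {
  expect_identical(
    classify_association(0.01, m = 0.6, rho = 0.8, p_rho = 0.001),
    "positive")
  expect_identical(
    classify_association(0.01, m = 0.05, rho = 0.1, p_rho = 0.4),
    "non-monotonic")
  expect_identical(
    classify_association(0.2, m = 0.6, rho = 0.8, p_rho = 0.001),
    "not-significant")
  expect_identical(
    classify_association(0.01, m = -0.2, rho = -0.5, p_rho = 0.01),
    "negative")
  # vectorized
  expect_identical(
    classify_association(c(0.01, 0.5), c(0.5, 0.5), c(0.9, 0.9),
                         c(0.01, 0.01)),
    c("positive", "not-significant"))
})

test_that("every tested pair yields two directed records, deterministically", {
  tbl <- null_table(n_plots = 40, n_vars = 5, seed = 9)
  ed <- screen_associations(tbl, n_perm = 49, seed = 21)
  expect_equal(nrow(ed), 2 * choose(5, 2))
  expect_equal(attr(ed, "n_pairs_tested"), 10)
  # each unordered pair appears once per orientation with mirrored a
  fwd <- ed[ed$source == "v01" & ed$target == "v02", ]
  rev <- ed[ed$source == "v02" & ed$target == "v01", ]
  expect_equal(fwd$a, -rev$a)
  expect_equal(fwd$q - fwd$a, rev$q)
  ed2 <- screen_associations(tbl, n_perm = 49, seed = 21)
  expect_identical(as.data.frame(ed), as.data.frame(ed2))
})

test_that("G-test matches hand evaluation and degenerate cases", {
  gt <- g_test(rbind(c(20, 5), c(5, 20)))
  expect_equal(gt$G, 19.2745, tolerance = 1e-4)
  expect_equal(gt$df, 1L)
  gt0 <- g_test(rbind(c(10, 10, 10), c(10, 10, 10)))
  expect_equal(gt0$G, 0)
  expect_equal(gt0$p, 1)
})

test_that("per-type proportions partition the significant records", {
  types <- rep(c("Fungi->Bacteria", "Plants->Fungi"), each = 30)
  klass <- c(rep(c("positive", "negative", "non-monotonic"), each = 10),
             rep(c("positive", "not-significant"), c(10, 20)))
  pr <- proportions_by_type(fake_edges(types, klass))
  p <- pr$proportions
  expect_equal(p$n[p$assoc_type == "Fungi->Bacteria"], 30)
  expect_equal(p$n[p$assoc_type == "Plants->Fungi"], 10)
  sums <- rowSums(p[, c("prop_positive", "prop_negative",
                        "prop_non-monotonic")])
  expect_equal(unname(sums), c(1, 1))
  expect_s3_class(pr$tests, "data.frame")
  expect_true(all(pr$tests$p_bonferroni >= pr$tests$p))
})

test_that("strongly different class mixes are detected between types", {
  # one type 60% non-monotonic, another 0%, desk-scale counts
  types <- rep(c("A->B", "B->A"), each = 50)
  klass <- c(rep(c("non-monotonic", "positive"), c(30, 20)),
             rep("positive", 50))
  pr <- proportions_by_type(fake_edges(types, klass))
  expect_lt(pr$tests$p_bonferroni[1], 0.01)
})

test_that("stage comparison detects a planted proportion shift", {
  set.seed(31)
  types <- paste0("T", 1:12)
  mk <- function(extra) {
    do.call(rbind, lapply(seq_along(types), function(i) {
      n_nm <- i + extra
      klass <- rep(c("non-monotonic", "positive"), c(n_nm, 40 - n_nm))
      fake_edges(rep(types[i], 40), klass)
    }))
  }
  res <- compare_stages(mk(0), mk(4))  # late +0.1 in every type
  nm <- res[res$klass == "non-monotonic", ]
  expect_lt(nm$p, 0.01)
  expect_gt(nm$median_late, nm$median_early)
  pos <- res[res$klass == "positive", ]
  expect_lt(pos$median_late, pos$median_early)
  # identical stages: no signed ranks, p = 1
  same <- compare_stages(mk(2), mk(2))
  expect_equal(same$p, rep(1, 3))
})
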