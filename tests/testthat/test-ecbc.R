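test_that("rank transform assigns spans and spreads ties deterministically", {
  rp <- rank_transform(c(10, 20, 30), c(1, 2, 3))
  expect_equal(rp$u_lo, c(0, 1, 2) / 3)
  expect_equal(rp$u_hi, c(1, 2, 3) / 3)
  expect_equal(rp$v_lo, rp$u_lo)

  # two tied observations share the interval (0, 2/3]
  rp2 <- rank_transform(c(5, 5, 9), c(1, 2, 3))
  expect_equal(rp2$u_lo, c(0, 0, 2 / 3))
  expect_equal(rp2$u_hi, c(2 / 3, 2 / 3, 1))

  # strictly monotone transforms leave spans unchanged
  x <- rnorm(25)
  rp_a <- rank_transform(x, x)
  rp_b <- rank_transform(exp(3 * x) - 7, x)
  expect_identical(rp_a$u_lo, rp_b$u_lo)
  expect_identical(rp_a$u_hi, rp_b$u_hi)

  expect_error(rank_transform(1:3, 1:4), "equal length")
  expect_error(rank_transform(1, 1), "at least 2")
  expect_error(rank_transform(c(1, NA, 3), 1:3), "missing")
})

test_that("resolution is floor(sqrt(n)) floored at 2", {
  expect_identical(ecbc_resolution(16), 4L)
  expect_identical(ecbc_resolution(24), 4L)
  expect_identical(ecbc_resolution(25), 5L)
  expect_identical(ecbc_resolution(5), 2L)
  expect_error(ecbc_resolution(1), ">= 2")
})

test_that("checkerboard margins are uniform for arbitrary n, N and ties", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    N <- sample(2:min(12, n), 1)
    tied <- rep %% 2 == 0
    x <- if (tied) sample(0:6, n, TRUE) else rnorm(n)
    y <- if (tied) sample(0:3, n, TRUE) else rnorm(n)
    C <- ecbc(x, y, N = N)
    expect_lt(max(abs(rowSums(C) - 1 / N)), 1e-12)
    expect_lt(max(abs(colSums(C) - 1 / N)), 1e-12)
    expect_lt(abs(sum(C) - 1), 1e-12)
  }
})

test_that("diagonal and grid samples rebuild the reference copulas", {
  # 16 comonotone points -> exactly M_4
  C <- ecbc(1:16, 1:16, N = 4)
  expect_equal(unclass(C), diag(4) / 4, tolerance = 1e-14,
               ignore_attr = TRUE)
  # one point per cell -> exactly the independence checkerboard
  k <- 1:16
  y_rank <- ((k - 1) %% 4) * 4 + (k - 1) %/% 4 + 1
  C2 <- ecbc(k, y_rank, N = 4)
  expect_equal(unclass(C2), matrix(1 / 16, 4, 4), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_error(ecbc(1:10, 1:10, N = 1), "2 <= N")
  expect_error(ecbc(1:10, 1:10, N = 11), "2 <= N")
})

test_that("reference copulas match their closed forms", {
  expect_equal(unclass(reference_ecbc("M", 2)),
               matrix(c(0.5, 0, 0, 0.5), 2), ignore_attr = TRUE)
  W3 <- unclass(reference_ecbc("W", 3))
  expect_equal(W3, diag(3)[, 3:1] / 3, ignore_attr = TRUE)
  expect_equal(unclass(reference_ecbc("Pi", 4)),
               matrix(1 / 16, 4, 4), ignore_attr = TRUE)
  expect_error(reference_ecbc("Z", 3))
})

test_that("D1 is an exact metric with known reference values", {
  M4 <- reference_ecbc("M", 4)
  W4 <- reference_ecbc("W", 4)
  P4 <- reference_ecbc("Pi", 4)
  expect_identical(d1_distance(M4, M4), 0)
  expect_equal(d1_distance(M4, P4), 7 / 24, tolerance = 1e-14)
  for (N in c(2, 4, 6, 8))
    expect_equal(d1_distance(reference_ecbc("M", N),
                             reference_ecbc("W", N)), 0.5,
                 tolerance = 1e-14)
  # symmetry and triangle inequality on random checkerboards
  set.seed(7)
  for (rep in 1:10) {
    N <- sample(2:8, 1)
    A <- ecbc(rnorm(40), rnorm(40), N = N)
    B <- ecbc(rnorm(40), rnorm(40), N = N)
    C <- ecbc(rnorm(40), rnorm(40), N = N)
    expect_equal(d1_distance(A, B), d1_distance(B, A))
    expect_lte(d1_distance(A, C),
               d1_distance(A, B) + d1_distance(B, C) + 1e-12)
  }
  expect_error(d1_distance(M4, reference_ecbc("M", 5)), "mismatch")
})

test_that("exact D1 agrees with brute-force grid integration", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(20:150, 1)
    N <- sample(2:8, 1)
    tied <- rep %% 3 == 0
    x <- if (tied) sample(0:9, n, TRUE) else rnorm(n)
    A <- ecbc(x, rnorm(n), N = N)
    B <- if (rep %% 2) reference_ecbc("Pi", N) else
      ecbc(rnorm(n), rnorm(n), N = N)
    expect_lt(abs(d1_distance(A, B) - grid_d1(A, B)), 1e-3)
  }
})

test_that("q has its closed-form value on diagonal checkerboards", {
  for (N in c(2, 4, 8))
    expect_equal(dependence_q(reference_ecbc("M", N)), 1 - 1 / (2 * N),
                 tolerance = 1e-14)
  expect_identical(dependence_q(reference_ecbc("Pi", 4)), 0)
})

test_that("q respects the transpose contract and m the reflection", {
  set.seed(13)
  for (rep in 1:10) {
    x <- rnorm(60); y <- rnorm(60)
    C <- unclass(ecbc(x, y, N = 6))
    # the estimate's q(Y,X) equals q of the transposed checkerboard
    est <- dependence_estimate(x, y, N = 6)
    expect_identical(est$q_yx, dependence_q(t(C)))
    expect_identical(est$q_xy, dependence_q(C))
    # reversing the y axis negates m and preserves q
    Crev <- C[, ncol(C):1]
    expect_equal(monotonicity_m(Crev), -monotonicity_m(C),
                 tolerance = 1e-12)
    expect_equal(dependence_q(Crev), dependence_q(C), tolerance = 1e-12)
  }
})

test_that("m hits its anchors and stays in [-1, 1]", {
  expect_equal(monotonicity_m(reference_ecbc("M", 4)), 1)
  expect_equal(monotonicity_m(reference_ecbc("W", 4)), -1)
  expect_equal(monotonicity_m(reference_ecbc("Pi", 6)), 0)
  set.seed(17)
  for (rep in 1:50) {
    pr <- random_pair(sample(16:120, 1),
                      sample(c("independent", "monotone_up", "dome",
                               "sinusoid"), 1),
                      ties = rep %% 2 == 0)
    est <- dependence_estimate(pr$x, pr$y)
    expect_lte(abs(est$m_xy), 1)
    expect_lte(abs(est$m_yx), 1)
    expect_gte(est$q_xy, 0); expect_lte(est$q_xy, 1)
    expect_equal(est$a, est$q_xy - est$q_yx)
  }
})

test_that("the composed estimate is exact on monotone data and scale-free", {
  est <- dependence_estimate(1:400, 1:400)
  expect_equal(est$m_xy, 1)
  expect_equal(est$a, 0)
  expect_equal(est$N, 20L)
  est2 <- dependence_estimate(1:400, -(1:400))
  expect_equal(est2$m_xy, -1)
  # invariance under strictly increasing marginal transforms, exactly
  set.seed(19)
  x <- rnorm(80); y <- x^2 + rnorm(80, 0, 0.1)
  e1 <- dependence_estimate(x, y)
  e2 <- dependence_estimate(exp(x), y^3 - 2 * y^2 * (y < 0) + 5 * y)
  expect_identical(e1[c("q_xy", "q_yx", "a", "m_xy", "m_yx")],
                   e2[c("q_xy", "q_yx", "a", "m_xy", "m_yx")])
})
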