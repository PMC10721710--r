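#' Normalized-rank transform of a paired sample
#'
#' Converts paired observations to rank intervals on the unit square, the
#' first step in estimating an empirical checkerboard copula. Each
#' observation occupies an interval of total width `t/n` on each axis,
#' where `t` is the size of its tie group: tied observations share a
#' contiguous rank interval and split its mass equally, so the margins are
#' exactly uniform whatever the tie structure. Because only ranks enter,
#' the result (and everything derived from it) is invariant under strictly
#' increasing transformations of either variable.
#'
#' @param x,y numeric vectors of equal length `n >= 2`, no missing values.
#' @param ties `"spread"` (default) spreads each observation's mass
#'   uniformly over its tie group's rank interval; `"random"` breaks ties
#'   by random ordering (uses the current RNG stream), giving each
#'   observation a width-`1/n` interval.
#' @return an object of class `ranked_pair`: a list with `n` and the
#'   interval bounds `u_lo`, `u_hi`, `v_lo`, `v_hi` on \[0,1\].
#' @examples
#' rp <- rank_transform(c(10, 20, 30), c(1, 2, 3))
#' rp$u_hi - rp$u_lo  # each untied observation spans width 1/3
#' @seealso [ecbc()], [dependence_estimate()]
#' @export
rank_transform <- function(x, y, ties = c("spread", "random")) {
  ties <- match.arg(ties)
  if (!is.numeric(x) || !is.numeric(y))
    stop("`x` and `y` must be numeric vectors")
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length (got ", length(x), " and ",
         length(y), ")")
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed")
  n <- length(x)
  if (n < 2) stop("need at least 2 paired observations")
  span <- function(v) {
    if (ties == "random") {
      r <- rank(v, ties.method = "random")
      list(lo = (r - 1) / n, hi = r / n)
    } else {
      r_hi <- rank(v, ties.method = "max")
      r_lo <- rank(v, ties.method = "min") - 1L
      list(lo = r_lo / n, hi = r_hi / n)
    }
  }
  sx <- span(x)
  sy <- span(y)
  structure(
    list(n = n, u_lo = sx$lo, u_hi = sx$hi, v_lo = sy$lo, v_hi = sy$hi),
    class = "ranked_pair"
  )
}

#' Checkerboard resolution for a sample size
#'
#' The grid resolution used for the empirical checkerboard copula is the
#' integer part of the square root of the sample size, floored at 2.
#'
#' @param n sample size, `n >= 2`.
#' @return integer resolution `N`.
#' @examples
#' ecbc_resolution(16)  # 4
#' ecbc_resolution(135) # 11
#' @export
ecbc_resolution <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 2)
    stop("`n` must be a single number >= 2")
  max(2L, as.integer(floor(sqrt(n))))
}

## n x N matrix of the fraction of each observation's rank interval that
## falls into each of the N strips; rows sum to 1.
.strip_overlap <- function(lo, hi, N) {
  breaks_lo <- (seq_len(N) - 1) / N
  breaks_hi <- seq_len(N) / N
  ov <- pmin(rep(hi, times = N), rep(breaks_hi, each = length(hi))) -
    pmax(rep(lo, times = N), rep(breaks_lo, each = length(lo)))
  ov[ov < 0] <- 0
  matrix(ov, nrow = length(lo), ncol = N) / (hi - lo)
}

.mass_from_overlap <- function(U, V) crossprod(U, V) / nrow(U)

#' Empirical checkerboard copula
#'
#' Aggregates a rank-transformed paired sample into an N x N mass matrix
#' with exactly uniform margins: every row and column sums to `1/N`. Each
#' observation contributes mass `1/n` uniformly over the rectangle spanned
#' by its rank intervals, split exactly across cell boundaries.
#'
#' @param x,y numeric vectors, or `x` a [rank_transform()] result (then
#'   `y` is ignored).
#' @param N resolution; defaults to [ecbc_resolution()] of the sample
#'   size. Must satisfy `2 <= N <= n`.
#' @param ties passed to [rank_transform()] when raw vectors are given.
#' @return an `ecbc` object: the N x N mass matrix with attribute `n`.
#' @examples
#' C <- ecbc(1:16, 1:16)      # comonotone sample, N = 4
#' rowSums(C)                 # uniform margins: all 1/4
#' @export
ecbc <- function(x, y = NULL, N = NULL, ties = "spread") {
  rp <- if (inherits(x, "ranked_pair")) x else rank_transform(x, y, ties)
  if (is.null(N)) N <- ecbc_resolution(rp$n)
  N <- as.integer(N)
  if (N < 2 || N > rp$n)
    stop("resolution N must satisfy 2 <= N <= n (got N=", N,
         ", n=", rp$n, ")")
  U <- .strip_overlap(rp$u_lo, rp$u_hi, N)
  V <- .strip_overlap(rp$v_lo, rp$v_hi, N)
  structure(.mass_from_overlap(U, V), class = "ecbc", n = rp$n)
}

#' Reference checkerboard copulas
#'
#' The three analytic benchmarks of the dependence measures, discretized
#' at resolution `N`: the comonotonicity copula `M` (perfect positive
#' monotone dependence, mass `1/N` on the diagonal), the
#' countermonotonicity copula `W` (perfect negative monotone dependence,
#' anti-diagonal), and the independence copula `Pi` (mass `1/N^2`
#' everywhere).
#'
#' @param kind one of `"M"`, `"W"`, `"Pi"`.
#' @param N resolution, `N >= 2`.
#' @return an `ecbc` object.
#' @examples
#' reference_ecbc("M", 2)
#' @export
reference_ecbc <- function(kind = c("M", "W", "Pi"), N) {
  kind <- match.arg(kind)
  N <- as.integer(N)
  if (N < 2) stop("N must be >= 2")
  mass <- switch(kind,
    M  = diag(N) / N,
    W  = diag(N)[, N:1] / N,
    Pi = matrix(1 / N^2, N, N)
  )
  structure(mass, class = "ecbc", n = NA_integer_)
}

## CDF knot values of the conditional distribution of Y given the i-th
## vertical strip, at y = 1/N, ..., N/N; rows are strips. Piecewise
## linear between knots (and 0 at y = 0).
.kernel_knots <- function(mass) {
  N <- nrow(mass)
  N * mass %*% upper.tri(diag(N), diag = TRUE)
}

## Exact integral of |F_A - F_B| over the unit square where both CDFs are
## piecewise linear per strip with knots at j/N. Segments with a sign
## crossing are integrated in closed form.
.d1_knots <- function(FA, FB) {
  N <- ncol(FA)
  dk <- FA - FB                       # differences at knots 1..N
  d0 <- cbind(0, dk[, -N, drop = FALSE])  # left endpoints (0 at y = 0)
  d1 <- dk
  same <- d0 * d1 >= 0
  seg <- matrix(0, nrow(FA), N)
  seg[same] <- (abs(d0[same]) + abs(d1[same])) / 2
  if (any(!same)) {
    a <- d0[!same]; b <- d1[!same]
    seg[!same] <- (a^2 + b^2) / (2 * abs(b - a))
  }
  sum(seg) / N^2                      # segment width 1/N, strip width 1/N
}

#' D1 distance between two checkerboard copulas
#'
#' The integrated absolute difference of the two copulas' Markov kernels
#' (conditional distribution functions of Y given X) over the unit
#' square. For checkerboards both kernels are piecewise linear in y
#' within each vertical strip, so the integral is evaluated exactly,
#' segment by segment, with sign crossings solved analytically. `d1`
#' is a metric: symmetric, zero iff equal, triangle inequality.
#'
#' @param A,B `ecbc` objects (or plain mass matrices) of equal resolution.
#' @return nonnegative scalar.
#' @examples
#' d1_distance(reference_ecbc("M", 4), reference_ecbc("Pi", 4))  # 7/24
#' @export
d1_distance <- function(A, B) {
  A <- unclass(A); B <- unclass(B)
  if (!identical(dim(A), dim(B)))
    stop("resolution mismatch: ", nrow(A), " vs ", nrow(B))
  .d1_knots(.kernel_knots(A), .kernel_knots(B))
}

#' Directed dependence q of a checkerboard copula
#'
#' `q = 3 * D1(C, Pi)` measures the dependence of Y on X: 0 for
#' independence, approaching 1 when Y is a function of X (for the
#' diagonal checkerboard, `q = 1 - 1/(2N)`). The reverse direction
#' `q(Y, X)` is obtained by calling on the transpose.
#'
#' @param C an `ecbc` object or mass matrix.
#' @return scalar in \[0, 1\].
#' @examples
#' dependence_q(reference_ecbc("Pi", 4))  # 0
#' dependence_q(reference_ecbc("M", 4))   # 0.875
#' @export
dependence_q <- function(C) {
  C <- unclass(C)
  N <- nrow(C)
  FPi <- matrix(seq_len(N) / N, N, N, byrow = TRUE)
  3 * .d1_knots(.kernel_knots(C), FPi)
}

.ref_knots <- function(N) {
  j <- matrix(seq_len(N), N, N, byrow = TRUE)
  i <- matrix(seq_len(N), N, N)
  list(M = (j >= i) + 0, W = (j >= N + 1 - i) + 0)
}

#' Index of monotonicity m of a checkerboard copula
#'
#' Contrasts the copula's D1 distances to the countermonotonicity copula
#' `W` and the comonotonicity copula `M`, both discretized at the same
#' resolution:
#' \deqn{m = \frac{D1(C, W) - D1(C, M)}{D1(M, W)}}
#' so that `m = +1` exactly at `M` (strictly positive monotone), `m = -1`
#' exactly at `W` (strictly negative monotone), and `m = 0` whenever the
#' copula is symmetric under the reflection `x -> 1 - x` (which includes
#' independence and symmetric dome shapes). `|m| <= 1` always, by the
#' triangle inequality.
#'
#' @param C an `ecbc` object or mass matrix.
#' @return scalar in \[-1, 1\].
#' @examples
#' monotonicity_m(reference_ecbc("M", 4))   # +1
#' monotonicity_m(reference_ecbc("W", 4))   # -1
#' monotonicity_m(reference_ecbc("Pi", 6))  # 0
#' @export
monotonicity_m <- function(C) {
  C <- unclass(C)
  N <- nrow(C)
  FC <- .kernel_knots(C)
  rk <- .ref_knots(N)
  dMW <- .d1_knots(rk$M, rk$W)
  stopifnot(dMW > 0)  # holds for every N >= 2
  (.d1_knots(FC, rk$W) - .d1_knots(FC, rk$M)) / dMW
}

## Fast combined computation used by the screening loop: q and m in both
## orientations from one mass matrix.
.qm_from_mass <- function(mass) {
  N <- nrow(mass)
  FPi <- matrix(seq_len(N) / N, N, N, byrow = TRUE)
  rk <- .ref_knots(N)
  dMW <- .d1_knots(rk$M, rk$W)
  F_xy <- .kernel_knots(mass)
  F_yx <- .kernel_knots(t(mass))
  c(
    q_xy = 3 * .d1_knots(F_xy, FPi),
    q_yx = 3 * .d1_knots(F_yx, FPi),
    m_xy = (.d1_knots(F_xy, rk$W) - .d1_knots(F_xy, rk$M)) / dMW,
    m_yx = (.d1_knots(F_yx, rk$W) - .d1_knots(F_yx, rk$M)) / dMW
  )
}

.q_from_mass <- function(mass) {
  N <- nrow(mass)
  FPi <- matrix(seq_len(N) / N, N, N, byrow = TRUE)
  c(3 * .d1_knots(.kernel_knots(mass), FPi),
    3 * .d1_knots(.kernel_knots(t(mass)), FPi))
}

#' Directed dependence estimate for a paired sample
#'
#' The full per-pair estimate: rank transform, checkerboard aggregation
#' at resolution `floor(sqrt(n))`, directed dependence in both
#' orientations, asymmetry `a = q(X,Y) - q(Y,X)`, and the index of
#' monotonicity in both orientations.
#'
#' @inheritParams rank_transform
#' @param N resolution override (default [ecbc_resolution()] of `n`).
#' @return a `qm_estimate` object: list with `q_xy`, `q_yx`, `a`, `m_xy`,
#'   `m_yx`, `n`, `N`.
#' @examples
#' est <- dependence_estimate(1:400, 1:400)
#' est$m_xy  # 1: perfectly positive monotone
#' est$a     # 0: symmetric dependence
#' @export
dependence_estimate <- function(x, y, N = NULL, ties = "spread") {
  rp <- rank_transform(x, y, ties)
  if (rp$n < 4) stop("need n >= 4 so that the resolution is at least 2")
  if (is.null(N)) N <- ecbc_resolution(rp$n)
  C <- ecbc(rp, N = N)
  qm <- .qm_from_mass(unclass(C))
  structure(
    list(q_xy = unname(qm["q_xy"]), q_yx = unname(qm["q_yx"]),
         a = unname(qm["q_xy"] - qm["q_yx"]),
         m_xy = unname(qm["m_xy"]), m_yx = unname(qm["m_yx"]),
         n = rp$n, N = nrow(C)),
    class = "qm_estimate"
  )
}

#' @export
print.qm_estimate <- function(x, ...) {
  cat("Directed dependence estimate (n =", x$n, ", resolution N =",
      x$N, ")\n")
  cat(sprintf("  q(X,Y) = %.4f   q(Y,X) = %.4f   a = %+.4f\n",
              x$q_xy, x$q_yx, x$a))
  cat(sprintf("  m(X,Y) = %+.4f  m(Y,X) = %+.4f\n", x$m_xy, x$m_yx))
  invisible(x)
}

#' @export
print.ecbc <- function(x, digits = 4, ...) {
  cat("Empirical checkerboard copula, resolution", nrow(x), "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Write a checkerboard mass matrix as TSV
#'
#' Debug helper: dumps the N x N cell masses (row = x strip, column = y
#' strip, origin at the lower-left of the unit square) to a tab-separated
#' file.
#'
#' @param C an `ecbc` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ecbc_tsv <- function(C, path) {
  m <- unclass(C)
  dimnames(m) <- list(paste0("x", seq_len(nrow(m))),
                      paste0("y", seq_len(ncol(m))))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
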