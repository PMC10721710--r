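# Shared helpers: independent oracles and small constructed tables.

# Brute-force D1 by midpoint-rule integration of |F_A - F_B| on a fine
# y-grid per vertical strip (the kernels are constant in x within a
# strip). Independent of the package's closed-form path.
grid_d1 <- function(A, B, grid = 2000) {
  A <- unclass(A); B <- unclass(B)
  N <- nrow(A)
  FA <- N * t(apply(A, 1, cumsum))
  FB <- N * t(apply(B, 1, cumsum))
  ys <- (seq_len(grid) - 0.5) / grid
  knots <- c(0, seq_len(N) / N)
  tot <- 0
  for (i in seq_len(N)) {
    fa <- stats::approx(knots, c(0, FA[i, ]), ys)$y
    fb <- stats::approx(knots, c(0, FB[i, ]), ys)$y
    tot <- tot + mean(abs(fa - fb)) / N
  }
  tot
}

# Random paired sample from a mix of association shapes, optionally
# with ties (rounding).
random_pair <- function(n, shape = c("independent", "monotone_up",
                                     "monotone_down", "dome",
                                     "sinusoid"),
                        ties = FALSE, noise = 0.2) {
  shape <- match.arg(shape)
  x <- stats::rnorm(n)
  u <- rank(x) / n
  y <- switch(shape,
    independent = stats::rnorm(n),
    monotone_up = u + stats::rnorm(n, 0, noise),
    monotone_down = -u + stats::rnorm(n, 0, noise),
    dome = 1 - 4 * (u - 0.5)^2 + stats::rnorm(n, 0, noise),
    sinusoid = cos(4 * pi * u) + stats::rnorm(n, 0, noise))
  if (ties) {
    x <- round(x, 1)
    y <- round(y, 1)
  }
  list(x = x, y = y)
}

# Minimal classified edge table for tabulation tests (only the columns
# proportions_by_type()/profiles use).
fake_edges <- function(assoc_type, klass, q = NULL, m = NULL) {
  k <- length(klass)
  data.frame(
    source = paste0("v", seq_len(k)), target = paste0("w", seq_len(k)),
    assoc_type = assoc_type, n_used = 30,
    q = if (is.null(q)) stats::runif(k) else q,
    p_q = ifelse(klass == "not-significant", 0.5, 0.01),
    m = if (is.null(m)) stats::runif(k, -1, 1) else m,
    a = 0, rho = 0, p_rho = 0.5, klass = klass,
    stringsAsFactors = FALSE)
}

# Small abundance table with independent noise variables (null data).
null_table <- function(n_plots = 40, n_vars = 6, seed = 1,
                       kind = "measurement") {
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_plots * n_vars), n_plots, n_vars,
                 dimnames = list(sprintf("plot%02d", seq_len(n_plots)),
                                 sprintf("v%02d", seq_len(n_vars))))
  if (kind == "count") vals <- matrix(stats::rpois(length(vals), 50),
                                      n_plots, n_vars,
                                      dimnames = dimnames(vals))
  abundance_table(
    vals,
    groups = rep(c("Bacteria", "Fungi"), length.out = n_vars),
    gradient = seq_len(n_plots),
    kind = rep(kind, n_vars))
}
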