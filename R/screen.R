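#' Variable pruning by number of unique values
#'
#' Community-wide screening only considers variables with at least
#' `min_unique` distinct observed values across the plots: near-constant
#' variables cannot support a checkerboard estimate at a meaningful
#' resolution and carry little gradient information.
#'
#' @param tbl an [abundance_table()].
#' @param min_unique minimum number of distinct values; default 16.
#' @return character vector of retained variable names.
#' @export
prune_variables <- function(tbl, min_unique = 16) {
  keep <- vapply(colnames(tbl$values),
                 function(v) length(unique(tbl$values[, v])) >= min_unique,
                 logical(1))
  colnames(tbl$values)[keep]
}

#' Co-occurrence plot subset for a variable pair
#'
#' Returns the plots on which both variables are present: taxa
#' (`count`/`cover` kinds) are present where their abundance exceeds
#' zero, environmental `measurement` variables are present on every
#' plot. Pairs present together on fewer than `min_plots` plots are
#' rejected (returned as `NULL`): dependence estimates on sparser joint
#' support would be dominated by structural zeros and spurious
#' co-absences.
#'
#' @param tbl an [abundance_table()].
#' @param x,y variable names.
#' @param min_plots minimum joint support; default 16.
#' @return character vector of plot names, or `NULL` if rejected.
#' @export
co_occurrence_plots <- function(tbl, x, y, min_plots = 16) {
  present <- function(v) {
    if (tbl$kind[[v]] == "measurement") rep(TRUE, nrow(tbl$values))
    else tbl$values[, v] > 0
  }
  plots <- rownames(tbl$values)[present(x) & present(y)]
  if (length(plots) < min_plots) NULL else plots
}

## Spearman rank correlation with the large-sample t approximation
## (pruning guarantees n >= 16, where the approximation is adequate and
## tie-robust).
.spearman <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Permutation significance test for directed dependence
#'
#' Estimates p-values for `q(X,Y)` and `q(Y,X)` by permuting the pairing
#' between `x` and `y` `n_perm` times and recomputing both directed
#' dependences from each permuted checkerboard. Both directions share the
#' same permutation stream. The add-one estimator
#' `p = (1 + #\{q_perm >= q_obs\}) / (n_perm + 1)` is used, so the
#' smallest attainable p with 999 permutations is 0.001.
#'
#' @param x,y paired numeric vectors.
#' @param n_perm number of permutations; default 999.
#' @param N resolution override (default `floor(sqrt(n))`).
#' @return list with `q_xy`, `q_yx`, `m_xy`, `m_yx`, `a`, `p_xy`, `p_yx`,
#'   `n`, `N`, and the permutation samples `null_q_xy`, `null_q_yx`.
#' @export
permutation_test_q <- function(x, y, n_perm = 999, N = NULL) {
  rp <- rank_transform(x, y)
  n <- rp$n
  if (is.null(N)) N <- ecbc_resolution(n)
  U <- .strip_overlap(rp$u_lo, rp$u_hi, N)
  V <- .strip_overlap(rp$v_lo, rp$v_hi, N)
  qm <- .qm_from_mass(.mass_from_overlap(U, V))
  null_xy <- null_yx <- numeric(n_perm)
  if (n_perm > 0) {
    for (b in seq_len(n_perm)) {
      qq <- .q_from_mass(.mass_from_overlap(U, V[sample.int(n), ,
                                                 drop = FALSE]))
      null_xy[b] <- qq[1]
      null_yx[b] <- qq[2]
    }
  }
  p_xy <- if (n_perm > 0)
    (1 + sum(null_xy >= qm["q_xy"])) / (n_perm + 1) else NA_real_
  p_yx <- if (n_perm > 0)
    (1 + sum(null_yx >= qm["q_yx"])) / (n_perm + 1) else NA_real_
  list(q_xy = unname(qm["q_xy"]), q_yx = unname(qm["q_yx"]),
       m_xy = unname(qm["m_xy"]), m_yx = unname(qm["m_yx"]),
       a = unname(qm["q_xy"] - qm["q_yx"]),
       p_xy = p_xy, p_yx = p_yx, n = n, N = N,
       null_q_xy = null_xy, null_q_yx = null_yx)
}

#' Classify a directed association
#'
#' Significant associations (permutation `p_q <= alpha`) are assigned to
#' one of three classes: `positive` (significant positive Spearman
#' trend), `negative` (significant negative trend), or `non-monotonic`
#' (significant dependence without a significant monotone trend, the
#' regime where `m` is near 0). Associations with `p_q > alpha` are
#' `not-significant` and are dropped from downstream tabulations. When
#' the signs of `m` and `rho` disagree the Spearman sign decides the
#' monotone label; such conflicts are counted by the screen.
#'
#' @param p_q permutation p-value of q (vectorized).
#' @param m index of monotonicity.
#' @param rho,p_rho Spearman coefficient and p-value.
#' @param alpha significance level; default 0.05.
#' @return character vector of class labels.
#' @export
classify_association <- function(p_q, m, rho, p_rho, alpha = 0.05) {
  ifelse(is.na(p_q) | p_q > alpha, "not-significant",
    ifelse(p_rho <= alpha,
      ifelse(rho > 0, "positive", "negative"),
      "non-monotonic"))
}

#' Community-wide screen of directed associations
#'
#' Runs the full pairwise screening stage: optional CSS normalization of
#' count variables, variable pruning, co-occurrence filtering, directed
#' dependence estimation for every retained pair on its co-occurrence
#' plots, permutation significance, Spearman trend, and classification.
#' Every tested unordered pair yields two directed records, one per
#' orientation, labelled with the ordered constituent-group pair
#' (association type, e.g. `Fungi->Bacteria`).
#'
#' @param tbl an [abundance_table()].
#' @param min_unique pruning threshold on distinct values; default 16.
#' @param min_co_occurrence minimum joint support in plots; default 16.
#' @param n_perm permutations for the significance test; default 999.
#'   `n_perm = 0` skips the test (q, m are still computed; `p_q` and
#'   `klass` are `NA`).
#' @param alpha significance level; default 0.05.
#' @param seed integer seed for the permutation stream (optional).
#' @param normalize apply [css_normalize()] to `count` variables first;
#'   default TRUE.
#' @param css_quantile CSS quantile level; default 0.5.
#' @param use_all_plots compute dependence on all plots instead of the
#'   co-occurrence subset (the subset remains the pair filter); default
#'   FALSE.
#' @param fdr additionally report Benjamini-Hochberg adjusted p-values in
#'   a `p_q_bh` column (off by default; the permutation test is the
#'   paper-level significance control).
#' @return data.frame with one row per directed association: `source`,
#'   `target`, `assoc_type`, `n_used`, `q`, `p_q`, `m`, `a`, `rho`,
#'   `p_rho`, `klass`. Attributes: `table` (the normalized table),
#'   `config`, `n_pairs_considered`, `n_pairs_tested`,
#'   `sign_conflicts` (count of m/rho sign disagreements among monotone
#'   classifications).
#' @export
screen_associations <- function(tbl, min_unique = 16,
                                min_co_occurrence = 16, n_perm = 999,
                                alpha = 0.05, seed = NULL,
                                normalize = TRUE, css_quantile = 0.5,
                                use_all_plots = FALSE, fdr = FALSE) {
  stopifnot(inherits(tbl, "abundance_table"))
  if (!is.null(seed)) set.seed(seed)
  if (normalize && any(tbl$kind == "count")) {
    idx <- tbl$kind == "count"
    tbl$values[, idx] <- suppressWarnings(
      css_normalize(tbl$values[, idx, drop = FALSE],
                    quantile_level = css_quantile))
  }
  vars <- prune_variables(tbl, min_unique)
  if (length(vars) < 2)
    stop("fewer than 2 variables remain after pruning")
  pairs <- utils::combn(vars, 2)
  rows <- vector("list", 2L * ncol(pairs))
  n_tested <- 0L
  conflicts <- 0L
  for (k in seq_len(ncol(pairs))) {
    vx <- pairs[1, k]; vy <- pairs[2, k]
    plots <- co_occurrence_plots(tbl, vx, vy, min_co_occurrence)
    if (is.null(plots)) next
    if (use_all_plots) plots <- rownames(tbl$values)
    n_tested <- n_tested + 1L
    xv <- tbl$values[plots, vx]
    yv <- tbl$values[plots, vy]
    pt <- permutation_test_q(xv, yv, n_perm = n_perm)
    sp <- .spearman(xv, yv)
    kl_xy <- classify_association(pt$p_xy, pt$m_xy, sp["rho"], sp["p"],
                                  alpha)
    kl_yx <- classify_association(pt$p_yx, pt$m_yx, sp["rho"], sp["p"],
                                  alpha)
    for (kl in c(kl_xy, kl_yx)) {
      if (kl %in% c("positive", "negative")) {
        mm <- if (kl == kl_xy) pt$m_xy else pt$m_yx
        if (sign(mm) != 0 && sign(mm) != sign(sp[["rho"]]))
          conflicts <- conflicts + 1L
      }
    }
    type_xy <- paste0(tbl$groups[[vx]], "->", tbl$groups[[vy]])
    type_yx <- paste0(tbl$groups[[vy]], "->", tbl$groups[[vx]])
    rows[[2 * k - 1]] <- data.frame(
      source = vx, target = vy, assoc_type = type_xy,
      n_used = pt$n, q = pt$q_xy, p_q = pt$p_xy, m = pt$m_xy, a = pt$a,
      rho = sp[["rho"]], p_rho = sp[["p"]], klass = kl_xy,
      stringsAsFactors = FALSE)
    rows[[2 * k]] <- data.frame(
      source = vy, target = vx, assoc_type = type_yx,
      n_used = pt$n, q = pt$q_yx, p_q = pt$p_yx, m = pt$m_yx, a = -pt$a,
      rho = sp[["rho"]], p_rho = sp[["p"]], klass = kl_yx,
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(edges)) stop("no variable pair passed the co-occurrence filter")
  rownames(edges) <- NULL
  if (fdr && n_perm > 0) edges$p_q_bh <- stats::p.adjust(edges$p_q, "BH")
  attr(edges, "table") <- tbl
  attr(edges, "config") <- list(
    min_unique = min_unique, min_co_occurrence = min_co_occurrence,
    n_perm = n_perm, alpha = alpha, seed = seed, normalize = normalize,
    css_quantile = css_quantile, use_all_plots = use_all_plots)
  attr(edges, "n_pairs_considered") <- ncol(pairs)
  attr(edges, "n_pairs_tested") <- n_tested
  attr(edges, "sign_conflicts") <- conflicts
  class(edges) <- c("association_screen", "data.frame")
  edges
}

#' Likelihood-ratio (G) test of independence
#'
#' `G = 2 sum O log(O / E)` over the cells of a contingency table, with
#' expected counts from the margins and a chi-square reference. Zero
#' cells contribute 0 (`0 log 0 = 0`); all-zero rows/columns are dropped
#' before computing the degrees of freedom.
#'
#' @param tab matrix of observed counts.
#' @return list with `G`, `df`, `p`.
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(G = NA_real_, df = NA_integer_, p = NA_real_))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pos <- tab > 0
  G <- 2 * sum(tab[pos] * log(tab[pos] / E[pos]))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Class proportions per association type
#'
#' Tabulates, per association type, the counts and proportions of
#' positive, negative, and non-monotonic classes among the significant
#' directed associations, and tests all pairs of types for differing
#' class composition with pairwise G-tests of independence
#' (Bonferroni-corrected). Types without significant associations are
#' reported with zero counts and excluded from the tests.
#'
#' @param edges a classified screen result ([screen_associations()]).
#' @return list with `proportions` (data.frame: type, counts, and
#'   proportions per class, n) and `tests` (data.frame of pairwise
#'   G-tests with raw and Bonferroni-adjusted p).
#' @export
proportions_by_type <- function(edges) {
  sig <- edges[!is.na(edges$klass) & edges$klass != "not-significant", ,
               drop = FALSE]
  classes <- c("positive", "negative", "non-monotonic")
  types <- sort(unique(edges$assoc_type))
  counts <- t(vapply(types, function(tp) {
    tabulate(factor(sig$klass[sig$assoc_type == tp], levels = classes),
             nbins = 3)
  }, numeric(3)))
  colnames(counts) <- classes
  n <- rowSums(counts)
  props <- counts / ifelse(n > 0, n, NA)
  proportions <- data.frame(
    assoc_type = types, n = n, counts,
    prop = props, check.names = FALSE, row.names = NULL)
  names(proportions) <- c("assoc_type", "n", paste0("n_", classes),
                          paste0("prop_", classes))
  tested <- types[n > 0]
  tests <- NULL
  if (length(tested) >= 2) {
    cmb <- utils::combn(tested, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      t1 <- cmb[1, k]; t2 <- cmb[2, k]
      gt <- g_test(counts[c(t1, t2), , drop = FALSE])
      data.frame(type_a = t1, type_b = t2, G = gt$G, df = gt$df,
                 p = gt$p, stringsAsFactors = FALSE)
    }))
    tests$p_bonferroni <- pmin(1, tests$p * nrow(tests))
    rownames(tests) <- NULL
  }
  list(proportions = proportions, tests = tests)
}

#' Split plots into early and late gradient stages
#'
#' Orders plots by gradient position and assigns the first
#' `ceiling(n/2)` to the early stage and the rest to the late stage
#' (ties in position broken by plot order).
#'
#' @param tbl an [abundance_table()].
#' @return list with `early` and `late` abundance tables.
#' @export
split_stages <- function(tbl) {
  ord <- order(tbl$gradient)
  n <- length(ord)
  early <- rownames(tbl$values)[ord[seq_len(ceiling(n / 2))]]
  late <- setdiff(rownames(tbl$values)[ord], early)
  list(early = subset_table(tbl, plots = early),
       late = subset_table(tbl, plots = late))
}

#' Compare class proportions between successional stages
#'
#' For each association class, performs a paired Wilcoxon signed-rank
#' test of the per-type class proportions between two stage-specific
#' screens (pairing unit = association type; only types with significant
#' associations in both stages enter).
#'
#' @param edges_early,edges_late classified screen results for the two
#'   stages.
#' @return data.frame with one row per class: `klass`, `n_types`,
#'   `median_early`, `median_late`, `p`.
#' @export
compare_stages <- function(edges_early, edges_late) {
  pe <- proportions_by_type(edges_early)$proportions
  pl <- proportions_by_type(edges_late)$proportions
  common <- intersect(pe$assoc_type[pe$n > 0], pl$assoc_type[pl$n > 0])
  if (length(common) < 2)
    stop("need at least 2 association types present in both stages")
  classes <- c("positive", "negative", "non-monotonic")
  out <- lapply(classes, function(cl) {
    col <- paste0("prop_", cl)
    e <- pe[match(common, pe$assoc_type), col]
    l <- pl[match(common, pl$assoc_type), col]
    p <- if (all(e == l)) 1 else
      suppressWarnings(stats::wilcox.test(e, l, paired = TRUE,
                                          exact = FALSE)$p.value)
    data.frame(klass = cl, n_types = length(common),
               median_early = stats::median(e),
               median_late = stats::median(l), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
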