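#' Association profiles in (q, m) space
#'
#' Every significant directed association is a point in the
#' two-dimensional "association space" spanned by its strength `q` and
#' its monotonicity `m`. The cloud of points of one association type is
#' that type's profile — a fingerprint of how two constituent groups
#' relate.
#'
#' @param edges a classified screen result ([screen_associations()]).
#' @param min_points drop types with fewer significant associations than
#'   this; default 1.
#' @return named list of two-column matrices (`q`, `m`), one per
#'   association type, of class `association_profiles`.
#' @export
association_profiles <- function(edges, min_points = 1) {
  sig <- edges[!is.na(edges$klass) & edges$klass != "not-significant", ,
               drop = FALSE]
  out <- lapply(split(sig, sig$assoc_type), function(d)
    cbind(q = d$q, m = d$m))
  out <- out[vapply(out, nrow, integer(1)) >= min_points]
  structure(out, class = "association_profiles")
}

#' Dynamic-range-box overlap of two profiles
#'
#' The portion of profile `B`'s range boxes covered by profile `A`,
#' aggregated over a grid of quantile levels: at each level `gamma` and
#' in each dimension, `B`'s box is the interval between its `gamma` and
#' `1 - gamma` quantiles (linear interpolation), and the per-dimension
#' overlap is the length of the intersection with `A`'s box divided by
#' the length of `B`'s box (0 if `B`'s box is degenerate). Per-level
#' portions are the product over the two dimensions; the final portion is
#' the mean over levels. `port` is asymmetric: `port(A, B) != port(B, A)`
#' in general.
#'
#' @param A,B two-column matrices of (q, m) points (profiles).
#' @param gamma_grid quantile levels in `[0, 0.5)`; default
#'   `seq(0, 0.45, by = 0.05)`.
#' @return scalar in \[0, 1\].
#' @export
dynrb_port <- function(A, B, gamma_grid = seq(0, 0.45, by = 0.05)) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!nrow(A) || !nrow(B)) stop("profiles must be non-empty")
  if (any(gamma_grid < 0 | gamma_grid >= 0.5))
    stop("gamma levels must lie in [0, 0.5)")
  per_gamma <- vapply(gamma_grid, function(g) {
    prod(vapply(seq_len(ncol(B)), function(d) {
      ib <- stats::quantile(B[, d], c(g, 1 - g), names = FALSE)
      ia <- stats::quantile(A[, d], c(g, 1 - g), names = FALSE)
      wb <- ib[2] - ib[1]
      if (wb <= 0) return(0)
      max(0, min(ia[2], ib[2]) - max(ia[1], ib[1])) / wb
    }, numeric(1)))
  }, numeric(1))
  mean(per_gamma)
}

#' Pairwise profile dissimilarity matrix
#'
#' Converts dynamic-range-box overlaps into a symmetric dissimilarity
#' suitable for hierarchical clustering:
#' `d(A, B) = 1 - (port(A, B) + port(B, A)) / 2`, with zero diagonal.
#'
#' @param profiles an [association_profiles()] list (>= 2 profiles).
#' @param gamma_grid passed to [dynrb_port()].
#' @return symmetric matrix with values in \[0, 1\].
#' @export
profile_dissimilarity <- function(profiles,
                                  gamma_grid = seq(0, 0.45, by = 0.05)) {
  k <- length(profiles)
  if (k < 2) stop("need at least 2 profiles")
  nm <- names(profiles)
  d <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pij <- dynrb_port(profiles[[i]], profiles[[j]], gamma_grid)
      pji <- dynrb_port(profiles[[j]], profiles[[i]], gamma_grid)
      d[i, j] <- d[j, i] <- 1 - (pij + pji) / 2
    }
  }
  d
}

#' Cluster association profiles with bootstrap support
#'
#' Average-linkage hierarchical clustering of the profile dissimilarity
#' matrix. Clade support is assessed by an ordinary bootstrap: each
#' profile's points are resampled with replacement, the dissimilarity
#' matrix and tree are recomputed, and a node's support is the fraction
#' of bootstrap trees containing the same leaf set.
#'
#' @param profiles an [association_profiles()] list (>= 3 profiles).
#' @param n_boot number of bootstrap replicates; default 1000.
#' @param gamma_grid passed to [dynrb_port()].
#' @param seed integer seed for the bootstrap (optional).
#' @return list with `hclust` (the tree), `dissimilarity` (the matrix),
#'   `phylo` (an [ape::as.phylo()] tree whose node labels are the
#'   support fractions), `support` (numeric vector per internal node).
#' @export
cluster_profiles <- function(profiles, n_boot = 1000,
                             gamma_grid = seq(0, 0.45, by = 0.05),
                             seed = NULL) {
  if (length(profiles) < 3)
    stop("need at least 3 profiles for a non-trivial tree")
  if (!is.null(seed)) set.seed(seed)
  d <- profile_dissimilarity(profiles, gamma_grid)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  boot_trees <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    res <- lapply(profiles, function(p)
      p[sample.int(nrow(p), replace = TRUE), , drop = FALSE])
    db <- profile_dissimilarity(res, gamma_grid)
    boot_trees[[b]] <- ape::as.phylo(
      stats::hclust(stats::as.dist(db), method = "average"))
  }
  counts <- ape::prop.clades(phy, boot_trees, rooted = TRUE)
  counts[is.na(counts)] <- 0
  support <- counts / n_boot
  phy$node.label <- formatC(support, format = "f", digits = 3)
  list(hclust = hc, dissimilarity = d, phylo = phy, support = support)
}

#' Write a support-labelled dendrogram as Newick
#'
#' @param clust result of [cluster_profiles()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tree <- function(clust, path) {
  ape::write.tree(clust$phylo, file = path)
  invisible(path)
}

## Compact letter display: types sharing a letter are not significantly
## different. Greedy insert-absorb over the non-significant pairs.
.compact_letters <- function(types, pairs_ns) {
  groups <- list()
  for (tp in types) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      ok <- all(vapply(groups[[gi]], function(o)
        paste(sort(c(tp, o)), collapse = "|") %in% pairs_ns, logical(1)))
      if (ok) {
        groups[[gi]] <- c(groups[[gi]], tp)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- tp
  }
  letters_out <- stats::setNames(rep("", length(types)), types)
  for (gi in seq_along(groups))
    for (tp in groups[[gi]])
      letters_out[tp] <- paste0(letters_out[tp], letters[gi])
  letters_out
}

#' Per-type location tests on q and m
#'
#' For each pair of association types, two-sample Wilcoxon rank-sum tests
#' compare the distributions of the strength `q` and of the monotonicity
#' `m`, with a single Bonferroni correction across all pairs and both
#' metrics. A compact letter display summarizes, per metric, which types
#' are mutually indistinguishable after correction.
#'
#' @param edges a classified screen result ([screen_associations()]).
#' @param min_points minimum significant associations per type; types
#'   below it are skipped with a warning. Default 2.
#' @return list with `tests` (data.frame: metric, type pair, medians, W,
#'   raw and Bonferroni p) and `letters` (data.frame: type, letter codes
#'   for q and for m).
#' @export
per_type_tests <- function(edges, min_points = 2) {
  profiles <- association_profiles(edges, min_points = min_points)
  all_types <- unique(edges$assoc_type)
  skipped <- setdiff(all_types, names(profiles))
  if (length(skipped))
    warning("type(s) with < ", min_points, " significant associations ",
            "skipped: ", paste(skipped, collapse = ", "))
  types <- names(profiles)
  if (length(types) < 2) stop("need >= 2 association types with data")
  cmb <- utils::combn(types, 2)
  rows <- list()
  for (metric in c("q", "m")) {
    for (k in seq_len(ncol(cmb))) {
      t1 <- cmb[1, k]; t2 <- cmb[2, k]
      v1 <- profiles[[t1]][, metric]
      v2 <- profiles[[t2]][, metric]
      wt <- suppressWarnings(stats::wilcox.test(v1, v2, exact = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, type_a = t1, type_b = t2,
        median_a = stats::median(v1), median_b = stats::median(v2),
        W = unname(wt$statistic), p = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_bonferroni <- pmin(1, tests$p * nrow(tests))
  letters_df <- data.frame(assoc_type = types, stringsAsFactors = FALSE)
  for (metric in c("q", "m")) {
    sub <- tests[tests$metric == metric, ]
    ns <- sub[sub$p_bonferroni > 0.05, c("type_a", "type_b")]
    keys <- apply(ns, 1, function(r) paste(sort(r), collapse = "|"))
    letters_df[[paste0("letters_", metric)]] <-
      .compact_letters(types, keys)[types]
  }
  list(tests = tests, letters = letters_df)
}
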