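## Reconstruct the unordered tested pairs (with their plot subsets) from
## a screen result; used by the coupling null model.
.screen_pairs <- function(edges) {
  tbl <- attr(edges, "table")
  cfg <- attr(edges, "config")
  if (is.null(tbl) || is.null(cfg))
    stop("`edges` must carry its screen attributes ",
         "(run screen_associations())")
  key <- apply(cbind(edges$source, edges$target), 1,
               function(r) paste(sort(r), collapse = "\r"))
  first <- !duplicated(key)
  pairs <- data.frame(x = edges$source[first], y = edges$target[first],
                      type_xy = edges$assoc_type[first],
                      stringsAsFactors = FALSE)
  pairs$type_yx <- paste0(tbl$groups[pairs$y], "->", tbl$groups[pairs$x])
  pairs$plots <- lapply(seq_len(nrow(pairs)), function(i) {
    pl <- co_occurrence_plots(tbl, pairs$x[i], pairs$y[i],
                              cfg$min_co_occurrence)
    if (isTRUE(cfg$use_all_plots)) rownames(tbl$values) else pl
  })
  pairs
}

#' Permutation null model for ecosystem coupling
#'
#' For every tested pair, the pairing between source and target values is
#' permuted `n_perm` times across plots and the directed dependence `q`
#' recomputed from each permuted checkerboard (one permuted checkerboard
#' serves both orientations). The null coupling of an association type is
#' the grand mean of all null `q` values of its pairs — the association
#' strength expected when the variables vary independently while keeping
#' their margins.
#'
#' @param edges a screen result ([screen_associations()]).
#' @param n_perm permutations per pair; default 199 (use 999 for
#'   full-fidelity runs).
#' @param seed integer seed (optional).
#' @return list with `null_mean` (named vector per association type) and
#'   `null_q` (list of null q samples per type).
#' @export
null_coupling <- function(edges, n_perm = 199, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  pairs <- .screen_pairs(edges)
  tbl <- attr(edges, "table")
  types <- sort(unique(edges$assoc_type))
  null_q <- stats::setNames(
    lapply(types, function(tp) numeric(0)), types)
  acc <- stats::setNames(vector("list", length(types)), types)
  for (i in seq_len(nrow(pairs))) {
    plots <- pairs$plots[[i]]
    if (is.null(plots)) next
    xv <- tbl$values[plots, pairs$x[i]]
    yv <- tbl$values[plots, pairs$y[i]]
    rp <- rank_transform(xv, yv)
    N <- ecbc_resolution(rp$n)
    U <- .strip_overlap(rp$u_lo, rp$u_hi, N)
    V <- .strip_overlap(rp$v_lo, rp$v_hi, N)
    qs <- matrix(0, n_perm, 2)
    for (b in seq_len(n_perm))
      qs[b, ] <- .q_from_mass(
        .mass_from_overlap(U, V[sample.int(rp$n), , drop = FALSE]))
    acc[[pairs$type_xy[i]]] <- c(acc[[pairs$type_xy[i]]], list(qs[, 1]))
    acc[[pairs$type_yx[i]]] <- c(acc[[pairs$type_yx[i]]], list(qs[, 2]))
  }
  for (tp in types) null_q[[tp]] <- unlist(acc[[tp]], use.names = FALSE)
  list(null_mean = vapply(null_q, mean, numeric(1)), null_q = null_q)
}

#' Normalized coupling of observed associations
#'
#' Subtracts the null-model mean association strength from each observed
#' `q`, centring the coupling estimates at 0 where observed coupling
#' equals random expectation; positive values indicate stronger-than-
#' chance association. Deviation from 0 is tested with a one-sample
#' Wilcoxon signed-rank test, two-sided and one-sided (greater); the two
#' tests at level 0.05 give the two significance tiers used in
#' reporting (a two-sided rejection corresponds to 0.025 per tail).
#'
#' @param q numeric vector of observed dependence values.
#' @param null_mean scalar null coupling.
#' @return list with `normalized` (the centred vector), `mean`, `p_two`,
#'   `p_one`.
#' @export
normalized_coupling <- function(q, null_mean) {
  if (!length(q)) stop("`q` must be non-empty")
  normalized <- q - null_mean
  p_two <- p_one <- NA_real_
  if (any(normalized != 0)) {
    p_two <- suppressWarnings(
      stats::wilcox.test(normalized, mu = 0, exact = FALSE)$p.value)
    p_one <- suppressWarnings(
      stats::wilcox.test(normalized, mu = 0, alternative = "greater",
                         exact = FALSE)$p.value)
  } else {
    p_two <- p_one <- 1
  }
  list(normalized = normalized, mean = mean(normalized),
       p_two = p_two, p_one = p_one)
}

#' Relative coupling
#'
#' The ratio of the mean observed association strength of significant
#' associations to the null-model mean strength of all associations:
#' 1 means coupling at chance level, values above 1 indicate stronger
#' coupling than expected by chance.
#'
#' @param observed_mean_sig mean q over significant associations.
#' @param null_mean null-model mean q (> 0).
#' @return scalar ratio.
#' @examples
#' relative_coupling(0.48, 0.30)  # 1.6
#' @export
relative_coupling <- function(observed_mean_sig, null_mean) {
  if (is.na(null_mean) || null_mean <= 0)
    stop("`null_mean` must be positive")
  observed_mean_sig / null_mean
}

#' Excess-significance G-squared test
#'
#' Tests whether the observed number of significant associations exceeds
#' the count expected by chance at level `alpha`:
#' \deqn{G^2 = 2\left[k \ln\frac{k}{n\alpha} +
#'       (n-k) \ln\frac{n-k}{n(1-\alpha)}\right]}
#' with a chi-square(1) reference. Boundary counts (`k = 0` or `k = n`)
#' are handled by continuity (`0 log 0 = 0`).
#'
#' @param k_sig number of significant associations.
#' @param n_tested number of associations tested (>= 1).
#' @param alpha nominal significance level; default 0.05.
#' @return list with `G2`, `df`, `p`, `frac_sig`, `expected_frac`.
#' @export
excess_significance <- function(k_sig, n_tested, alpha = 0.05) {
  if (n_tested < 1) stop("`n_tested` must be >= 1")
  if (k_sig < 0 || k_sig > n_tested) stop("`k_sig` out of range")
  term <- function(o, e) if (o == 0) 0 else o * log(o / e)
  G2 <- 2 * (term(k_sig, n_tested * alpha) +
               term(n_tested - k_sig, n_tested * (1 - alpha)))
  list(G2 = G2, df = 1L,
       p = stats::pchisq(G2, 1, lower.tail = FALSE),
       frac_sig = k_sig / n_tested, expected_frac = alpha)
}

#' Directed ecosystem coupling per association type
#'
#' The coupling stage: per association type, the observed coupling (mean
#' `q` over all associations and over significant ones), the permutation
#' null coupling, normalized coupling with deviation-from-zero tests (on
#' significant associations and on all), the relative coupling, and the
#' excess-significance test on the fraction of significant associations.
#'
#' @param edges a classified screen result ([screen_associations()]) with
#'   permutation p-values.
#' @param n_perm null-model permutations per pair; default 199.
#' @param seed integer seed for the null model (optional).
#' @param alpha significance level used for the significant subset and
#'   the excess-significance test; default 0.05.
#' @return data.frame of class `coupling_result`, one row per association
#'   type: `assoc_type`, `n_all`, `n_sig`, `frac_sig`,
#'   `observed_mean_all`, `observed_mean_sig`, `null_mean`,
#'   `mean_normalized_sig`, `mean_normalized_all`, `p_two_sig`,
#'   `p_one_sig`, `p_two_all`, `p_one_all`, `relative`, `G2`, `g2_p`.
#'   Attributes: `global` (overall excess-significance test), `null`
#'   (the [null_coupling()] result), `normalized` (per-type centred
#'   vectors, significant subset).
#' @export
ecosystem_coupling <- function(edges, n_perm = 199, seed = NULL,
                               alpha = 0.05) {
  nul <- null_coupling(edges, n_perm = n_perm, seed = seed)
  types <- names(nul$null_mean)
  has_p <- !all(is.na(edges$p_q))
  norm_store <- stats::setNames(vector("list", length(types)), types)
  rows <- lapply(types, function(tp) {
    sub <- edges[edges$assoc_type == tp, , drop = FALSE]
    sig <- if (has_p) sub[!is.na(sub$p_q) & sub$p_q <= alpha, ,
                          drop = FALSE] else sub[0, ]
    nm <- nul$null_mean[[tp]]
    nc_all <- normalized_coupling(sub$q, nm)
    nc_sig <- if (nrow(sig)) normalized_coupling(sig$q, nm) else NULL
    norm_store[[tp]] <<- if (is.null(nc_sig)) numeric(0) else
      nc_sig$normalized
    ex <- if (has_p) excess_significance(nrow(sig), nrow(sub), alpha)
      else list(G2 = NA_real_, p = NA_real_)
    data.frame(
      assoc_type = tp, n_all = nrow(sub), n_sig = nrow(sig),
      frac_sig = if (has_p) nrow(sig) / nrow(sub) else NA_real_,
      observed_mean_all = mean(sub$q),
      observed_mean_sig = if (nrow(sig)) mean(sig$q) else NA_real_,
      null_mean = nm,
      mean_normalized_sig = if (is.null(nc_sig)) NA_real_ else nc_sig$mean,
      mean_normalized_all = nc_all$mean,
      p_two_sig = if (is.null(nc_sig)) NA_real_ else nc_sig$p_two,
      p_one_sig = if (is.null(nc_sig)) NA_real_ else nc_sig$p_one,
      p_two_all = nc_all$p_two, p_one_all = nc_all$p_one,
      relative = if (nrow(sig) && nm > 0)
        relative_coupling(mean(sig$q), nm) else NA_real_,
      G2 = ex$G2, g2_p = ex$p,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (has_p) {
    k_tot <- sum(!is.na(edges$p_q) & edges$p_q <= alpha)
    attr(out, "global") <- excess_significance(k_tot, nrow(edges), alpha)
  }
  attr(out, "null") <- nul
  attr(out, "normalized") <- norm_store
  class(out) <- c("coupling_result", "data.frame")
  out
}

#' Directed coupling network
#'
#' Represents per-type relative coupling as a directed weighted graph:
#' nodes are constituent groups, edge weights are the relative coupling
#' of the corresponding association type (self-loops for within-group
#' coupling), and each edge carries a significance tier: `p<0.025` when
#' the two-sided deviation test rejects at 0.05 (0.025 per tail),
#' `p<0.05` when only the one-sided test rejects, `ns` otherwise.
#'
#' @param coupling a [ecosystem_coupling()] result.
#' @param significant_only use the tests on the significant-association
#'   subset (default) or on all associations.
#' @return an [igraph::graph] with edge attributes `weight` (relative
#'   coupling) and `tier`.
#' @export
coupling_network <- function(coupling, significant_only = TRUE) {
  parts <- strsplit(coupling$assoc_type, "->", fixed = TRUE)
  ed <- data.frame(
    from = vapply(parts, `[`, "", 1),
    to = vapply(parts, `[`, "", 2),
    weight = coupling$relative,
    stringsAsFactors = FALSE)
  p_two <- if (significant_only) coupling$p_two_sig else coupling$p_two_all
  p_one <- if (significant_only) coupling$p_one_sig else coupling$p_one_all
  ed$tier <- ifelse(!is.na(p_two) & p_two <= 0.05, "p<0.025",
             ifelse(!is.na(p_one) & p_one <= 0.05, "p<0.05", "ns"))
  keep <- !is.na(ed$weight)
  igraph::graph_from_data_frame(
    ed[keep, , drop = FALSE], directed = TRUE,
    vertices = sort(unique(c(ed$from, ed$to))))
}

#' Write a coupling network as GraphML
#'
#' @param graph an [igraph::graph] from [coupling_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coupling_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
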