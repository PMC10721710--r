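#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Defaults follow the
#' emulated study protocol where it states them: pruning at 16 unique
#' values, co-occurrence on at least 16 plots, 999 permutation steps,
#' significance level 0.05. The configuration round-trips losslessly
#' through YAML ([yaml::write_yaml()] / [yaml::read_yaml()]).
#'
#' @param min_unique,min_co_occurrence,n_perm,alpha,css_quantile see
#'   [screen_associations()].
#' @param gamma_grid,n_boot see [dynrb_port()], [cluster_profiles()].
#' @param n_perm_null null-model permutations per pair for the coupling
#'   stage; default 199 (999 for full-fidelity runs).
#' @param seed integer master seed for all stage randomness.
#' @param stage_split also screen the early/late gradient halves and
#'   compare class proportions; default FALSE.
#' @param significant_only base the coupling network tiers on the
#'   significant-association tests; default TRUE.
#' @param use_all_plots,normalize see [screen_associations()].
#' @return a `run_config` list.
#' @export
run_config <- function(min_unique = 16, min_co_occurrence = 16,
                       n_perm = 999, alpha = 0.05, css_quantile = 0.5,
                       gamma_grid = seq(0, 0.45, by = 0.05),
                       n_boot = 1000, n_perm_null = 199, seed = 1,
                       stage_split = FALSE, significant_only = TRUE,
                       use_all_plots = FALSE, normalize = TRUE) {
  structure(list(
    min_unique = min_unique, min_co_occurrence = min_co_occurrence,
    n_perm = n_perm, alpha = alpha, css_quantile = css_quantile,
    gamma_grid = gamma_grid, n_boot = n_boot,
    n_perm_null = n_perm_null, seed = seed, stage_split = stage_split,
    significant_only = significant_only,
    use_all_plots = use_all_plots, normalize = normalize),
    class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

## Deterministic checksum of the YAML-serialized configuration.
.config_hash <- function(config) {
  s <- utf8ToInt(yaml::as.yaml(unclass(config)))
  sprintf("%08x",
          sum(s * (seq_along(s) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full association-screening workflow
#'
#' Executes screening, classification, class-proportion tabulation,
#' association profiles (overlap, clustering, per-type tests), and
#' directed ecosystem coupling on one abundance table, writing every
#' stage's artifacts to a directory. The run is deterministic: the same
#' table and configuration produce byte-identical artifacts.
#'
#' Artifacts: `edges.tsv` (directed association table),
#' `proportions.tsv` + `proportion_tests.tsv`, `profile_overlap.tsv`
#' (pairwise port and dissimilarity), `profile_tree.nwk`
#' (support-labelled dendrogram, when >= 3 profiles),
#' `per_type_tests.tsv` + `per_type_letters.tsv`, `coupling.tsv`,
#' `coupling_edges.tsv`, `coupling.graphml`, `stage_comparison.tsv`
#' (when `stage_split`), `config.yaml`, and `run_log.txt`.
#'
#' @param tbl an [abundance_table()].
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()]; individual parameters may be
#'   overridden via `...`.
#' @param ... overrides for [run_config()] fields.
#' @return invisibly, a list with the stage results (`edges`,
#'   `proportions`, `profiles`, `clustering`, `type_tests`, `coupling`,
#'   `stages`, `paths`).
#' @export
run_pipeline <- function(tbl, out_dir, config = run_config(), ...) {
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(config))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    config[names(dots)] <- dots
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log_lines <- c(
    paste0("ecopula pipeline, package version ",
           as.character(utils::packageVersion("ecopula"))),
    paste0("seed: ", config$seed),
    paste0("config hash: ", .config_hash(config)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  edges <- stage("screen", screen_associations(
    tbl, min_unique = config$min_unique,
    min_co_occurrence = config$min_co_occurrence,
    n_perm = config$n_perm, alpha = config$alpha, seed = config$seed,
    normalize = config$normalize, css_quantile = config$css_quantile,
    use_all_plots = config$use_all_plots))
  n_sig <- sum(!is.na(edges$klass) & edges$klass != "not-significant")
  log_lines <- c(log_lines,
    paste0("pairs considered: ", attr(edges, "n_pairs_considered")),
    paste0("pairs tested (co-occurrence passed): ",
           attr(edges, "n_pairs_tested")),
    paste0("directed records: ", nrow(edges)),
    paste0("significant directed records: ", n_sig),
    paste0("m/rho sign conflicts: ", attr(edges, "sign_conflicts")))
  paths$edges <- .write_tsv(as.data.frame(edges),
                            file.path(out_dir, "edges.tsv"))

  props <- stage("proportions", proportions_by_type(edges))
  paths$proportions <- .write_tsv(props$proportions,
                                  file.path(out_dir, "proportions.tsv"))
  if (!is.null(props$tests))
    paths$proportion_tests <- .write_tsv(
      props$tests, file.path(out_dir, "proportion_tests.tsv"))

  profiles <- stage("profiles", association_profiles(edges))
  clustering <- NULL
  type_tests <- NULL
  if (length(profiles) >= 2) {
    ov <- utils::combn(names(profiles), 2)
    port_df <- do.call(rbind, lapply(seq_len(ncol(ov)), function(k) {
      a <- ov[1, k]; b <- ov[2, k]
      pab <- dynrb_port(profiles[[a]], profiles[[b]], config$gamma_grid)
      pba <- dynrb_port(profiles[[b]], profiles[[a]], config$gamma_grid)
      data.frame(type_a = a, type_b = b, port_ab = pab, port_ba = pba,
                 dissimilarity = 1 - (pab + pba) / 2,
                 stringsAsFactors = FALSE)
    }))
    paths$profile_overlap <- .write_tsv(
      port_df, file.path(out_dir, "profile_overlap.tsv"))
    if (length(profiles) >= 3) {
      clustering <- stage("profiles", cluster_profiles(
        profiles, n_boot = config$n_boot,
        gamma_grid = config$gamma_grid, seed = config$seed))
      paths$profile_tree <- write_profile_tree(
        clustering, file.path(out_dir, "profile_tree.nwk"))
    } else {
      log_lines <- c(log_lines,
                     "profile clustering skipped (< 3 profiles)")
    }
    enough <- sum(vapply(profiles, nrow, integer(1)) >= 2) >= 2
    if (enough) {
      type_tests <- stage("profiles",
                          suppressWarnings(per_type_tests(edges)))
      paths$per_type_tests <- .write_tsv(
        type_tests$tests, file.path(out_dir, "per_type_tests.tsv"))
      paths$per_type_letters <- .write_tsv(
        type_tests$letters, file.path(out_dir, "per_type_letters.tsv"))
    }
  } else {
    log_lines <- c(log_lines, "profile stage skipped (< 2 profiles)")
  }

  coupling <- stage("coupling", ecosystem_coupling(
    edges, n_perm = config$n_perm_null, seed = config$seed,
    alpha = config$alpha))
  paths$coupling <- .write_tsv(as.data.frame(coupling),
                               file.path(out_dir, "coupling.tsv"))
  net <- coupling_network(coupling,
                          significant_only = config$significant_only)
  edge_df <- igraph::as_data_frame(net, what = "edges")
  paths$coupling_edges <- .write_tsv(
    edge_df, file.path(out_dir, "coupling_edges.tsv"))
  paths$coupling_graphml <- write_coupling_graphml(
    net, file.path(out_dir, "coupling.graphml"))
  glob <- attr(coupling, "global")
  if (!is.null(glob))
    log_lines <- c(log_lines,
      sprintf("global excess significance: G2 = %.4f, p = %.4g",
              glob$G2, glob$p))

  stages <- NULL
  if (isTRUE(config$stage_split)) {
    halves <- split_stages(tbl)
    stages <- stage("stages", {
      e_early <- screen_associations(
        halves$early, min_unique = config$min_unique,
        min_co_occurrence = config$min_co_occurrence,
        n_perm = config$n_perm, alpha = config$alpha,
        seed = config$seed, normalize = config$normalize,
        css_quantile = config$css_quantile,
        use_all_plots = config$use_all_plots)
      e_late <- screen_associations(
        halves$late, min_unique = config$min_unique,
        min_co_occurrence = config$min_co_occurrence,
        n_perm = config$n_perm, alpha = config$alpha,
        seed = config$seed, normalize = config$normalize,
        css_quantile = config$css_quantile,
        use_all_plots = config$use_all_plots)
      compare_stages(e_early, e_late)
    })
    paths$stage_comparison <- .write_tsv(
      stages, file.path(out_dir, "stage_comparison.tsv"))
  }

  cfg_out <- unclass(config)
  cfg_out$gamma_grid <- as.numeric(cfg_out$gamma_grid)
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  paths$config <- file.path(out_dir, "config.yaml")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths$log <- file.path(out_dir, "run_log.txt")

  invisible(list(edges = edges, proportions = props,
                 profiles = profiles, clustering = clustering,
                 type_tests = type_tests, coupling = coupling,
                 stages = stages, paths = paths))
}
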