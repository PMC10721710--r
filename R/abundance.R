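#' Plot-by-variable abundance table
#'
#' The pipeline's input container: a numeric matrix of measurements with
#' rows = sampling plots and columns = variables, plus per-variable
#' metadata (constituent group and data kind) and per-plot gradient
#' positions (for example distance along a successional gradient, or
#' stage rank).
#'
#' @param values numeric matrix, plots in rows, variables in columns;
#'   both dimensions named.
#' @param groups character vector (named by variable, or in column
#'   order) assigning each variable to a constituent group, conventionally
#'   `"Bacteria"`, `"Fungi"`, `"Plants"`, `"Environment"`.
#' @param gradient numeric vector (named by plot, or in row order) of
#'   gradient positions; must be defined for every plot.
#' @param kind character vector per variable: `"count"` (nonnegative
#'   integer abundances, eligible for CSS normalization), `"cover"`
#'   (percent cover), or `"measurement"` (environmental measurements,
#'   considered present on every plot).
#' @return an `abundance_table` object (list with `values`, `groups`,
#'   `gradient`, `kind`).
#' @export
abundance_table <- function(values, groups, gradient, kind) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || is.null(rownames(values)))
    stop("`values` must have row (plot) and column (variable) names")
  if (anyDuplicated(colnames(values)))
    stop("duplicated variable names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicated plot names")
  if (!is.numeric(values)) stop("`values` must be numeric")
  vars <- colnames(values)
  plots <- rownames(values)

  align <- function(v, ids, what) {
    if (!is.null(names(v))) {
      missing <- setdiff(ids, names(v))
      if (length(missing))
        stop(what, " missing for: ", paste(missing, collapse = ", "))
      v <- v[ids]
    } else if (length(v) != length(ids)) {
      stop(what, " must have one entry per ", if (what == "gradient")
        "plot" else "variable")
    } else names(v) <- ids
    v
  }
  groups <- align(as.character(groups), vars, "group")
  kind <- align(as.character(kind), vars, "kind")
  gradient <- align(gradient, plots, "gradient")
  if (anyNA(gradient)) stop("gradient must be defined for every plot")
  bad_kind <- setdiff(unique(kind), c("count", "cover", "measurement"))
  if (length(bad_kind))
    stop("unknown kind: ", paste(bad_kind, collapse = ", "))
  cnt <- values[, kind == "count", drop = FALSE]
  if (length(cnt) && (any(cnt < 0) || any(cnt != floor(cnt))))
    stop("count variables must be nonnegative integers")
  structure(list(values = values, groups = groups, gradient = gradient,
                 kind = kind),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", nrow(x$values), "plots x", ncol(x$values),
      "variables\n")
  print(table(group = x$groups, kind = x$kind))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Subset an abundance table
#'
#' @param x an [abundance_table()].
#' @param plots,variables plot / variable names or indices to keep
#'   (default: all).
#' @return an `abundance_table`.
#' @export
subset_table <- function(x, plots = NULL, variables = NULL) {
  v <- x$values
  if (!is.null(plots)) v <- v[plots, , drop = FALSE]
  if (!is.null(variables)) v <- v[, variables, drop = FALSE]
  abundance_table(v, x$groups[colnames(v)], x$gradient[rownames(v)],
                  x$kind[colnames(v)])
}

.read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read an abundance table from delimited files
#'
#' Assembles an [abundance_table()] from three files: the plot x variable
#' value matrix (TSV or CSV; first column = plot id), a variable metadata
#' table with columns `variable`, `group`, `kind`, and a plot metadata
#' table with columns `plot`, `gradient_position`. A BIOM v1 (JSON) count
#' table may be given instead of the matrix file (requires the
#' `biomformat` package); BIOM tables are observation x sample and are
#' transposed on input.
#'
#' @param values_path path to the value matrix (`.tsv`/`.csv`) or a BIOM
#'   v1 file (`.biom`).
#' @param variables_path path to the variable metadata TSV/CSV.
#' @param plots_path path to the plot metadata TSV/CSV.
#' @return an `abundance_table`.
#' @export
read_abundance <- function(values_path, variables_path, plots_path) {
  if (grepl("\\.biom$", values_path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the `biomformat` package")
    b <- biomformat::read_biom(values_path)
    values <- t(as.matrix(biomformat::biom_data(b)))
  } else {
    raw <- .read_table_auto(values_path)
    values <- as.matrix(raw[, -1, drop = FALSE])
    rownames(values) <- as.character(raw[[1]])
    if (!is.numeric(values)) {
      bad <- colnames(values)[!apply(values, 2, is.numeric)]
      stop("non-numeric cells in column(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  vmeta <- .read_table_auto(variables_path)
  need <- c("variable", "group", "kind")
  if (!all(need %in% names(vmeta)))
    stop("variable metadata needs columns: ", paste(need, collapse = ", "))
  pmeta <- .read_table_auto(plots_path)
  if (!all(c("plot", "gradient_position") %in% names(pmeta)))
    stop("plot metadata needs columns: plot, gradient_position")
  missing_v <- setdiff(colnames(values), vmeta$variable)
  if (length(missing_v))
    stop("variable(s) absent from metadata: ",
         paste(utils::head(missing_v, 5), collapse = ", "))
  missing_p <- setdiff(rownames(values), as.character(pmeta$plot))
  if (length(missing_p))
    stop("plot(s) absent from metadata: ",
         paste(utils::head(missing_p, 5), collapse = ", "))
  abundance_table(
    values,
    groups = stats::setNames(vmeta$group, vmeta$variable)[colnames(values)],
    gradient = stats::setNames(pmeta$gradient_position,
                               as.character(pmeta$plot))[rownames(values)],
    kind = stats::setNames(vmeta$kind, vmeta$variable)[colnames(values)]
  )
}

#' Write an abundance table to delimited files
#'
#' Inverse of [read_abundance()]: writes the value matrix and both
#' metadata tables as TSV.
#'
#' @param tbl an [abundance_table()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
write_abundance <- function(tbl, dir, prefix = "community") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    values = file.path(dir, paste0(prefix, "_values.tsv")),
    variables = file.path(dir, paste0(prefix, "_variables.tsv")),
    plots = file.path(dir, paste0(prefix, "_plots.tsv"))
  )
  df <- data.frame(plot = rownames(tbl$values), tbl$values,
                   check.names = FALSE)
  utils::write.table(df, paths["values"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(variable = colnames(tbl$values),
               group = unname(tbl$groups), kind = unname(tbl$kind)),
    paths["variables"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(plot = rownames(tbl$values),
               gradient_position = unname(tbl$gradient)),
    paths["plots"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
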