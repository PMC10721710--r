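#' Cumulative sum scaling (CSS) normalization
#'
#' Normalizes a plot x variable count matrix for unequal sequencing depth.
#' For each sample (row) the scaling factor is the sum of its counts up to
#' a fixed quantile of its positive counts, and counts are divided by
#' that factor and rescaled:
#' \deqn{\tilde{c}_{jv} = c_{jv} / s_j \times 1000, \qquad
#'       s_j = \sum_{v: c_{jv} \le Q_j} c_{jv}}
#' where `Q_j` is the `quantile_level` quantile (linear interpolation) of
#' sample `j`'s positive counts. This is the fixed-quantile variant of
#' CSS; the quantile is not chosen adaptively per dataset. All-zero
#' samples cannot be scaled: they are left unchanged and flagged.
#'
#' @param counts nonnegative matrix, plots in rows, variables in columns.
#' @param quantile_level quantile of the positive counts defining the
#'   scaling sum; default 0.5 (the median).
#' @param scale rescaling constant; default 1000.
#' @return normalized numeric matrix with attribute `unscaled`, the
#'   row names (or indices) of all-zero samples left untouched.
#' @examples
#' css_normalize(matrix(1:4, nrow = 1))  # scaling sum 3 = 1 + 2
#' @export
css_normalize <- function(counts, quantile_level = 0.5, scale = 1000) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (quantile_level <= 0 || quantile_level >= 1)
    stop("`quantile_level` must be strictly between 0 and 1")
  out <- counts
  unscaled <- character(0)
  for (j in seq_len(nrow(counts))) {
    row <- counts[j, ]
    pos <- row[row > 0]
    s <- if (length(pos))
      sum(row[row <= stats::quantile(pos, quantile_level, names = FALSE)])
    else 0
    if (s <= 0) {
      unscaled <- c(unscaled,
                    if (is.null(rownames(counts))) as.character(j)
                    else rownames(counts)[j])
    } else {
      out[j, ] <- row / s * scale
    }
  }
  if (length(unscaled))
    warning("all-zero sample(s) left unscaled: ",
            paste(unscaled, collapse = ", "))
  attr(out, "unscaled") <- unscaled
  out
}
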