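align_compositions <- function(predicted, expected) {
  groups <- sort(union(names(predicted), names(expected)))
  if (is.null(names(predicted)) || is.null(names(expected))) {
    if (length(predicted) != length(expected))
      stop("unnamed composition vectors must have equal length")
    return(list(predicted = as.numeric(predicted),
                expected = as.numeric(expected)))
  }
  p <- stats::setNames(rep(0, length(groups)), groups)
  e <- p
  p[names(predicted)] <- predicted
  e[names(expected)] <- expected
  list(predicted = p, expected = e)
}

#' Pearson correlation between predicted and expected compositions
#'
#' Standard product-moment correlation over the full reporting-group
#' vector (groups absent from one vector count as 0). An exactly constant
#' vector makes the correlation undefined; `NA` is returned with a
#' warning in that case.
#'
#' @param predicted,expected Group-fraction vectors; when named they are
#'   aligned on the union of group names, otherwise compared positionally.
#' @return The correlation coefficient (length-1 numeric, possibly `NA`).
#' @export
pearson_composition <- function(predicted, expected) {
  al <- align_compositions(predicted, expected)
  if (length(al$predicted) < 2L)
    stop("need at least two groups to correlate")
  if (stats::sd(al$predicted) == 0 || stats::sd(al$expected) == 0) {
    warning("constant composition vector: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(al$predicted, al$expected)
}

#' Compare predicted vs expected compositions across samples
#'
#' @param predicted Samples x groups matrix (e.g. `q_merged` from
#'   [run_mgmlst()]).
#' @param expected Named list of expected fraction vectors, one per
#'   sample (matched by name when available, else by order).
#' @return data.frame `sample`, `pearson_r`.
#' @export
compare_compositions <- function(predicted, expected) {
  stopifnot(is.matrix(predicted))
  snames <- rownames(predicted) %||% as.character(seq_len(nrow(predicted)))
  if (!is.null(names(expected)) && all(snames %in% names(expected)))
    expected <- expected[snames]
  stopifnot(length(expected) == nrow(predicted))
  data.frame(sample = snames,
             pearson_r = vapply(seq_len(nrow(predicted)), function(i)
               pearson_composition(predicted[i, ], expected[[i]]),
               numeric(1)),
             stringsAsFactors = FALSE)
}

#' Compare group abundances between two cohorts
#'
#' Per reporting group, tests whether the relative abundance differs
#' between the two cohorts: two-sided Mann-Whitney U by default
#' (`stats::wilcox.test`), Welch t-test by flag. P-values are reported per
#' group without multiplicity correction. Groups with identical values in
#' both cohorts are degenerate: flagged with `p_value = 1` and a warning.
#'
#' @param abundances Samples x groups matrix of fractions.
#' @param labels Cohort label per sample (exactly two levels).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return data.frame `group`, `statistic`, `p_value`, `median_a`,
#'   `median_b`, `degenerate` (cohort a is the first label level).
#' @export
cohort_compare <- function(abundances, labels, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(is.matrix(abundances), nrow(abundances) == length(labels))
  lv <- unique(as.character(labels))
  if (length(lv) != 2L) stop("exactly two cohorts are required")
  ia <- labels == lv[1L]
  ib <- labels == lv[2L]
  rows <- lapply(colnames(abundances) %||%
                   as.character(seq_len(ncol(abundances))), function(g) {
    gi <- if (is.null(colnames(abundances))) as.integer(g) else g
    xa <- abundances[ia, gi]
    xb <- abundances[ib, gi]
    degenerate <- length(unique(c(xa, xb))) == 1L
    if (degenerate) {
      warning("group '", g, "' has identical values in both cohorts")
      stat <- NA_real_
      p <- 1
    } else {
      ht <- if (test == "wilcoxon")
        suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)) else
        stats::t.test(xa, xb)
      stat <- unname(ht$statistic)
      p <- ht$p.value
    }
    data.frame(group = g, statistic = stat, p_value = p,
               median_a = stats::median(xa), median_b = stats::median(xb),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
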