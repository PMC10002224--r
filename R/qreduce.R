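#' Two-sided Mann-Whitney U-test p-value
#'
#' Exact-distribution evaluation when the pooled sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. Identical constant samples give p = 1.
#'
#' @param x,y numeric samples of the two groups (each of length >= 2).
#' @return Two-sided p-value in (0, 1].
#' @export
mann_whitney_p <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (length(unique(c(x, y))) == 1) return(1)
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' The Q index of a coefficient block
#'
#' Ratio of the number of statistically significant statistics in the block to
#' the block's average p-value:
#' \deqn{Q = \frac{\#\{p_i < \alpha\}}{\bar p}.}
#' Larger Q means more of the block's statistics separate the two groups, and
#' they do so with smaller p-values. Q = 0 when no statistic is significant.
#'
#' @param p_values vector of per-statistic p-values (finite, in (0, 1]).
#' @param alpha significance level.
#' @return Q (non-negative; `Inf` when every p underflows to the minimum).
#' @export
q_index <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) stop("q_index: empty p-value vector")
  stopifnot(all(is.finite(p_values)), all(p_values > 0), all(p_values <= 1))
  sum(p_values < alpha) / mean(p_values)
}

#' Rank wavelet coefficient blocks by the Q index and select the best per series
#'
#' For each of the eight series and each block (level j = 1..J, coefficient
#' type CA or CD), the five per-statistic Mann-Whitney p-values between the two
#' groups are computed from the Dataset2 columns and combined into the block's
#' Q index; the arg-max block per series is selected (ties: lower level first,
#' then CD before CA). The five statistics of the eight selected blocks form
#' the comparison's reduced feature set (40 columns).
#'
#' @param ds2 Dataset2 data.frame from [dataset2()] (with `group` column).
#' @param comparison character vector of the two group labels to compare.
#' @param alpha significance level for the Q numerator.
#' @param levels decomposition depth used to build `ds2`.
#' @return List of class `q_index_table`: `table` (one row per series x level x
#'   type with the 5 p-values, significant count, mean p, Q, and a `selected`
#'   flag), `selected_features` (the 40 reduced column names), `comparison`,
#'   `alpha`, `n1`, `n2`.
#' @export
select_blocks <- function(ds2, comparison, alpha = 0.05, levels = 8) {
  stopifnot(length(comparison) == 2)
  g1 <- ds2$group == comparison[1]
  g2 <- ds2$group == comparison[2]
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("select_blocks: both groups need at least 2 subjects")
  stats <- c("Xbar", "S", "SK", "K", "IQR")
  sn <- series_names()
  rows <- list()
  for (s in sn) {
    for (j in seq_len(levels)) {
      for (ct in c("CA", "CD")) {
        pcols <- sprintf("%s(%s%d-%s)", stats, ct, j, s)
        p <- vapply(pcols, function(cn)
          mann_whitney_p(ds2[g1, cn], ds2[g2, cn]), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          series = s, level = j, type = ct,
          p_Xbar = p[1], p_S = p[2], p_SK = p[3], p_K = p[4], p_IQR = p[5],
          k_sig = sum(p < alpha), mean_p = mean(p),
          Q = q_index(p, alpha))
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$selected <- FALSE
  for (s in sn) {
    i <- which(tab$series == s)
    sub <- tab[i, ]
    ## arg-max Q; ties: lower level first, then detail (CD) before approximation
    ord <- order(-sub$Q, sub$level, match(sub$type, c("CD", "CA")))
    tab$selected[i[ord[1]]] <- TRUE
  }
  sel <- tab[tab$selected, ]
  feats <- unlist(lapply(seq_len(nrow(sel)), function(i)
    sprintf("%s(%s%d-%s)", stats, sel$type[i], sel$level[i], sel$series[i])))
  structure(list(table = tab, selected_features = feats,
                 comparison = comparison, alpha = alpha,
                 n1 = sum(g1), n2 = sum(g2)),
            class = "q_index_table")
}

#' @export
print.q_index_table <- function(x, ...) {
  cat(sprintf("Q-index block selection: %s vs %s (n = %d/%d, alpha = %g)\n",
              x$comparison[1], x$comparison[2], x$n1, x$n2, x$alpha))
  sel <- x$table[x$table$selected, c("series", "level", "type", "k_sig", "Q")]
  rownames(sel) <- NULL
  print(sel, ...)
  invisible(x)
}

#' Reduced per-comparison feature table
#'
#' Subset of a Dataset2 table holding only the two compared groups and the 40
#' features of the Q-selected blocks.
#'
#' @param ds2 Dataset2 data.frame.
#' @param qtab a `q_index_table` from [select_blocks()].
#' @return data.frame with `subject_id`, `group` and 40 feature columns.
#' @export
reduce_dataset2 <- function(ds2, qtab) {
  keep <- ds2$group %in% qtab$comparison
  ds2[keep, c("subject_id", "group", qtab$selected_features)]
}
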