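#' Grade-by-response contingency table for one binary item
#'
#' @param counts Numeric matrix (or object coercible to one) with one row
#'   per grade and two columns (\code{yes}, \code{no}), all counts
#'   non-negative with a positive grand total.
#' @param item Item label carried through to results.
#' @param grades Row labels; default \code{1..nrow}.
#' @return Object of class \code{contingency_table}.
#' @examples
#' ct <- contingency_table(rbind(c(65, 58), c(51, 59), c(33, 88), c(14, 86)),
#'                         item = "dropout")
#' @export
contingency_table <- function(counts, item = "item",
                              grades = seq_len(nrow(counts))) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2, nrow(counts) >= 1,
            all(counts >= 0), all(counts == round(counts)),
            sum(counts) > 0, length(grades) == nrow(counts))
  dimnames(counts) <- list(grade = as.character(grades),
                           response = c("yes", "no"))
  structure(list(item = item, counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>", x$item, "\n")
  print(x$counts)
  invisible(x)
}

new_comparison_result <- function(item, test, statistic, df, p_value,
                                  posthoc = NULL, alpha_main = 0.017) {
  structure(list(item = item, test = test, statistic = statistic, df = df,
                 p_value = p_value,
                 significant_main = !is.na(p_value) & p_value < alpha_main,
                 alpha_main = alpha_main, posthoc = posthoc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s [%s]\n", x$item, x$test))
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g%s\n", x$statistic,
              paste(x$df, collapse = ", "), x$p_value,
              if (isTRUE(x$significant_main)) {
                sprintf("  (significant at %.3f)", x$alpha_main)
              } else ""))
  if (!is.null(x$posthoc)) {
    sig <- x$posthoc[x$posthoc$significant, , drop = FALSE]
    cat("  post hoc significant pairs:",
        if (nrow(sig)) paste(sig$group1, ">" , sig$group2, collapse = "; ")
        else "none", "\n")
  }
  invisible(x)
}

#' Chi-square test of homogeneity across grades
#'
#' Pearson chi-square on the grade x yes/no table, without continuity
#' correction, with df = (rows - 1). The main-analysis significance
#' threshold is Bonferroni-adjusted to 0.05/3 = 0.017 (three outcome
#' domains); pairwise post-hoc comparisons between grades use 0.05/6 =
#' 0.008 (six grade pairs).
#'
#' @param table A [contingency_table()].
#' @param posthoc Run the six pairwise grade comparisons (same test on each
#'   2 x 2 subtable) at the post-hoc threshold.
#' @param alpha_main,alpha_posthoc Significance thresholds.
#' @return A \code{comparison_result} with fields \code{statistic},
#'   \code{df}, \code{p_value}, \code{significant_main} and (optionally) a
#'   \code{posthoc} data frame.
#' @export
chi_square_homogeneity <- function(table, posthoc = FALSE,
                                   alpha_main = 0.05 / 3,
                                   alpha_posthoc = 0.05 / 6) {
  stopifnot(inherits(table, "contingency_table"))
  if (any(table$row_totals == 0) || any(table$col_totals == 0)) {
    stop("degenerate table for item '", table$item,
         "': a row or column marginal is zero")
  }
  ht <- stats::chisq.test(table$counts, correct = FALSE)
  ph <- NULL
  if (posthoc) {
    grades <- rownames(table$counts)
    pairs <- utils::combn(seq_along(grades), 2)
    ph <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      idx <- pairs[, k]
      sub <- table$counts[idx, , drop = FALSE]
      res <- suppressWarnings(stats::chisq.test(sub, correct = FALSE))
      data.frame(group1 = grades[idx[1]], group2 = grades[idx[2]],
                 statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 significant = unname(res$p.value) < alpha_posthoc,
                 stringsAsFactors = FALSE)
    }))
  }
  new_comparison_result(table$item, "chi-square homogeneity",
                        unname(ht$statistic), unname(ht$parameter),
                        unname(ht$p.value), ph, alpha_main)
}

#' Kruskal-Wallis rank test across grades
#'
#' Tie-corrected H statistic on df = groups - 1. Identical values in every
#' group yield H = 0 with p = 1 rather than an error. Post-hoc pairwise
#' contrasts apply the same test to each grade pair at the 0.008 threshold.
#'
#' @param values Numeric vector of item responses.
#' @param groups Grouping vector (grade), same length as \code{values}.
#' @param item Label carried into the result.
#' @inheritParams chi_square_homogeneity
#' @return A \code{comparison_result}.
#' @export
kruskal_wallis <- function(values, groups, item = "item", posthoc = FALSE,
                           alpha_main = 0.05 / 3, alpha_posthoc = 0.05 / 6) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(droplevels(groups)) >= 2)
  if (length(unique(values)) == 1) {
    return(new_comparison_result(item, "Kruskal-Wallis", 0,
                                 nlevels(droplevels(groups)) - 1L, 1,
                                 NULL, alpha_main))
  }
  ht <- stats::kruskal.test(values, groups)
  ph <- NULL
  if (posthoc) {
    lev <- levels(droplevels(groups))
    pairs <- utils::combn(seq_along(lev), 2)
    ph <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      sel <- groups %in% lev[pairs[, k]]
      res <- if (length(unique(values[sel])) == 1) {
        list(statistic = 0, p.value = 1)
      } else {
        stats::kruskal.test(values[sel], droplevels(groups[sel]))
      }
      data.frame(group1 = lev[pairs[1, k]], group2 = lev[pairs[2, k]],
                 statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 significant = unname(res$p.value) < alpha_posthoc,
                 stringsAsFactors = FALSE)
    }))
  }
  new_comparison_result(item, "Kruskal-Wallis", unname(ht$statistic),
                        unname(ht$parameter), unname(ht$p.value), ph,
                        alpha_main)
}

#' One-way ANOVA across grades
#'
#' Classic equal-variance F test, df = (groups - 1, N - groups). The
#' summary form [anova_from_summary()] computes the identical F from
#' per-group means, SDs and sizes, which lets printed summary rows be
#' checked without raw data.
#'
#' @inheritParams kruskal_wallis
#' @return A \code{comparison_result}.
#' @export
one_way_anova <- function(values, groups, item = "item", posthoc = FALSE,
                          alpha_main = 0.05 / 3, alpha_posthoc = 0.05 / 6) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  groups <- droplevels(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  ns <- as.integer(table(groups))
  if (all(sds == 0)) {
    if (length(unique(means)) == 1) {
      stop("F undefined: zero within-group variance with equal means")
    }
  }
  res <- anova_from_summary(means, sds, ns)
  ph <- NULL
  if (posthoc) {
    lev <- levels(groups)
    pairs <- utils::combn(seq_along(lev), 2)
    ph <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      sel <- groups %in% lev[pairs[, k]]
      sub <- anova_from_summary(means[pairs[, k]], sds[pairs[, k]],
                                ns[pairs[, k]])
      data.frame(group1 = lev[pairs[1, k]], group2 = lev[pairs[2, k]],
                 statistic = sub$F, p_value = sub$p_value,
                 significant = sub$p_value < alpha_posthoc,
                 stringsAsFactors = FALSE)
    }))
  }
  new_comparison_result(item, "one-way ANOVA", res$F,
                        c(res$df1, res$df2), res$p_value, ph, alpha_main)
}

#' @rdname one_way_anova
#' @param means,sds,ns Per-group sample means, standard deviations
#'   (denominator n - 1) and sizes.
#' @return `anova_from_summary()` returns a list with `F`, `df1`, `df2`,
#'   `p_value`.
#' @examples
#' anova_from_summary(c(21.0, 19.6, 17.9, 16.6), c(7.6, 6.2, 6.5, 7.0),
#'                    c(123, 110, 121, 100))$F  # about 8.8
#' @export
anova_from_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(sds) == length(ns),
            length(ns) >= 2, all(ns >= 2), all(sds >= 0))
  k <- length(ns)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ss_within == 0) {
    if (ss_between == 0) {
      stop("F undefined: zero within-group variance with equal means")
    }
    return(list(F = Inf, df1 = df1, df2 = as.integer(df2), p_value = 0))
  }
  F <- (ss_between / df1) / (ss_within / df2)
  list(F = F, df1 = df1, df2 = as.integer(df2),
       p_value = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Row percentage of yes-responses over a subset of grades
#'
#' @param table A [contingency_table()].
#' @param grades Character or numeric subset of the table's grade labels;
#'   default all.
#' @param digits Decimal places of the reported percentage (default 1, the
#'   convention of the printed tables).
#' @return Percentage in \[0, 100\], rounded to \code{digits}.
#' @examples
#' ct <- contingency_table(rbind(c(65, 58), c(51, 59), c(33, 88), c(14, 86)),
#'                         "dropout")
#' row_percentage(ct, grades = c(1, 2))  # 49.8
#' @export
row_percentage <- function(table, grades = rownames(table$counts),
                           digits = 1) {
  stopifnot(inherits(table, "contingency_table"))
  grades <- as.character(grades)
  stopifnot(length(grades) >= 1, all(grades %in% rownames(table$counts)))
  sub <- table$counts[grades, , drop = FALSE]
  round(100 * sum(sub[, "yes"]) / sum(sub), digits)
}

#' Printed grade-wise contingency rows shipped with the package
#'
#' Per-grade yes/no counts for the binary survey items (sex recoded as
#' men/women), as published in the study's descriptive table. One row of
#' this table (sleep) is internally inconsistent in the source (its
#' grade-3 cells sum to 131 rather than the stratum's 121 respondents) and
#' is flagged by the \code{consistent} column.
#'
#' @return Data frame with columns \code{item}, \code{grade}, \code{yes},
#'   \code{no}, \code{consistent}.
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.csv", package = "surveynet")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  n_grade <- c(123L, 110L, 121L, 100L)
  totals <- tapply(out$yes + out$no, out$item, function(x) all(x == n_grade))
  out$consistent <- as.logical(totals[out$item])
  out
}

#' @rdname table1_counts
#' @param item One item label from [table1_counts()].
#' @return `table1_contingency()` returns the [contingency_table()] for one
#'   item.
#' @export
table1_contingency <- function(item) {
  tab <- table1_counts()
  rows <- tab[tab$item == item, ]
  if (!nrow(rows)) {
    stop("unknown table item '", item, "'; available: ",
         paste(unique(tab$item), collapse = ", "))
  }
  rows <- rows[order(rows$grade), ]
  contingency_table(cbind(rows$yes, rows$no), item = item,
                    grades = rows$grade)
}

#' @rdname table1_counts
#' @return `table1_scale_summaries()` returns the printed per-grade
#'   mean/SD/n rows for the PSS, GAD-7 and PHQ-9 totals together with the
#'   published F statistic (column \code{printed_f}).
#' @export
table1_scale_summaries <- function() {
  path <- system.file("extdata", "table1_scale_summaries.csv",
                      package = "surveynet")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run every printed contingency row through the homogeneity test
#'
#' @param posthoc Include pairwise grade contrasts.
#' @return Data frame: one row per item with statistic, df, p-value and the
#'   main-threshold significance flag.
#' @export
compare_table1 <- function(posthoc = FALSE) {
  items <- unique(table1_counts()$item)
  do.call(rbind, lapply(items, function(it) {
    res <- chi_square_homogeneity(table1_contingency(it), posthoc = posthoc)
    data.frame(item = it, statistic = res$statistic, df = res$df,
               p_value = res$p_value, significant_main = res$significant_main,
               stringsAsFactors = FALSE)
  }))
}
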