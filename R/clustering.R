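#' Chi-square difference between two genotype cells
#'
#' Pearson chi-square statistic (df = 1, no continuity correction) of the
#' 2 x 2 table formed by the case/control counts of two genotype cells (or
#' merged blocks). This is the merge criterion of the dynamic clustering:
#' the pair of cells with the smallest statistic is the least significantly
#' different and is merged first. When any marginal of the 2 x 2 table is
#' zero the statistic is defined as 0 (the cells are indistinguishable).
#'
#' @param cell_a,cell_b numeric pairs `(case_count, ctrl_count)`.
#' @return The chi-square statistic.
#' @examples
#' pairwise_difference(c(10, 10), c(20, 20))  # identical proportions: 0
#' @export
pairwise_difference <- function(cell_a, cell_b) {
  a <- as.numeric(cell_a); b <- as.numeric(cell_b)
  stopifnot(length(a) == 2L, length(b) == 2L, all(a >= 0), all(b >= 0))
  r1 <- sum(a); r2 <- sum(b); c1 <- a[1L] + b[1L]; c2 <- a[2L] + b[2L]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)
  n <- r1 + r2
  n * (a[1L] * b[2L] - a[2L] * b[1L])^2 / (r1 * r2 * c1 * c2)
}

as_dche_table <- function(table) {
  if (inherits(table, "dche_table")) return(table)
  if (is.matrix(table) && nrow(table) == 2L) {
    return(structure(list(snps = NA_integer_, case_counts = table[1L, ],
                          ctrl_counts = table[2L, ],
                          t = round(log(ncol(table), 3))),
                     class = "dche_table"))
  }
  stop("expected a dche_table or a 2-row count matrix")
}

#' Greedily merge genotype cells into a fixed number of groups
#'
#' Starting from one block per non-empty cell, repeatedly merges the pair of
#' blocks whose case/control profiles are least significantly different
#' ([pairwise_difference()] on the block totals) until `target_d` blocks
#' remain. Ties are broken deterministically towards the pair with the
#' lexicographically smallest block labels, a block's label being the
#' smallest cell index it contains. Cells empty in both phenotype rows are
#' dropped before clustering.
#'
#' @param table a [count_contingency()] table (or a 2-row count matrix,
#'   cases on top).
#' @param target_d number of groups to merge down to.
#' @return An object of class `dche_grouping`: list with `blocks` (list of
#'   0-based cell-index vectors), `case_totals`, `ctrl_totals`, `d`,
#'   `merge_trace` (matrix with columns `label_a`, `label_b`, `chi2`) and
#'   `warn_too_few_cells` (TRUE when `target_d` exceeds the number of
#'   non-empty cells, in which case the initial partition is returned).
#' @export
greedy_merge <- function(table, target_d) {
  table <- as_dche_table(table)
  stopifnot(target_d >= 1L)
  res <- cpp_greedy_merge(as.integer(table$case_counts),
                          as.integer(table$ctrl_counts),
                          as.integer(target_d))
  if (res$warn_too_few_cells)
    warning("target_d exceeds the number of non-empty cells; ",
            "returning the initial partition")
  trace <- res$trace
  colnames(trace) <- c("label_a", "label_b", "chi2")
  structure(list(blocks = res$blocks, case_totals = res$case_totals,
                 ctrl_totals = res$ctrl_totals, d = length(res$blocks),
                 merge_trace = trace,
                 warn_too_few_cells = res$warn_too_few_cells),
            class = "dche_grouping")
}

#' @export
print.dche_grouping <- function(x, ...) {
  cat("Genotype grouping, d =", x$d, "\n")
  cat("blocks:", format_blocks(x$blocks), "\n")
  cat("case totals:", paste(x$case_totals, collapse = ", "), "\n")
  cat("ctrl totals:", paste(x$ctrl_totals, collapse = ", "), "\n")
  invisible(x)
}

# "0,1,2,3,6;5,7,8;4" serialization of a block list (0-based cell labels)
format_blocks <- function(blocks) {
  paste(vapply(blocks, function(b) paste(b, collapse = ","), character(1)),
        collapse = ";")
}

#' Chi-square evaluation of a genotype grouping
#'
#' Pearson chi-square test on the 2 x d table of merged group totals, with
#' d - 1 degrees of freedom.
#'
#' @param grouping a [greedy_merge()] result.
#' @return list with `grouping`, `chi2`, `df`, `p_unadjusted`.
#' @export
evaluate_grouping <- function(grouping) {
  stopifnot(inherits(grouping, "dche_grouping"))
  if (grouping$d < 2L) stop("grouping must have at least 2 groups")
  if (sum(grouping$case_totals) <= 0 || sum(grouping$ctrl_totals) <= 0)
    stop("both phenotype rows must have positive totals")
  ct <- chi_square_pvalue(rbind(grouping$case_totals, grouping$ctrl_totals))
  list(grouping = grouping, chi2 = ct$statistic, df = ct$df,
       p_unadjusted = ct$p)
}

#' Dynamic clustering of a contingency table
#'
#' The core scoring procedure: the genotype cells of a SNP tuple are greedily
#' merged ([greedy_merge()]) and the resulting 2 x d table is evaluated at
#' every group count d from `min(6, #non-empty cells)` down to 3; the most
#' significant evaluation is returned (ties towards smaller d). Tables with
#' only 2 non-empty cells are evaluated at d = 2 and flagged `degenerate`.
#'
#' @param table a [count_contingency()] table (or 2-row count matrix).
#' @return An object of class `dche_cluster`: list with `d`, `chi2`, `df`,
#'   `p_unadjusted`, `grouping` (the selected [greedy_merge()] partition),
#'   `evaluations` (data frame of all d evaluated), `merge_trace` and
#'   `degenerate`.
#' @examples
#' tab <- rbind(c(40, 49, 13, 43, 110, 49, 16, 50, 30),
#'              c(55, 76, 21, 62, 103, 22, 24, 27, 10))
#' dynamic_cluster(tab)
#' @export
dynamic_cluster <- function(table) {
  table <- as_dche_table(table)
  res <- cpp_dynamic_cluster(as.integer(table$case_counts),
                             as.integer(table$ctrl_counts))
  trace <- res$trace
  colnames(trace) <- c("label_a", "label_b", "chi2")
  grouping <- structure(list(blocks = res$blocks,
                             case_totals = res$case_totals,
                             ctrl_totals = res$ctrl_totals,
                             d = res$d, merge_trace = trace,
                             warn_too_few_cells = FALSE),
                        class = "dche_grouping")
  structure(list(d = res$d, chi2 = res$chi2, df = res$df,
                 p_unadjusted = res$p, grouping = grouping,
                 evaluations = res$evaluations, merge_trace = trace,
                 degenerate = res$degenerate, snps = table$snps),
            class = "dche_cluster")
}

#' @export
print.dche_cluster <- function(x, ...) {
  cat("Dynamic clustering: best d =", x$d, " chi2 =",
      format(x$chi2, digits = 6), " df =", x$df, " p =",
      format(x$p_unadjusted, digits = 4), "\n")
  cat("blocks:", format_blocks(x$grouping$blocks), "\n")
  invisible(x)
}
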