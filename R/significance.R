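#' Pearson chi-square test of a 2 x k count table
#'
#' @param table 2-row matrix of non-negative counts (cases on top); columns
#'   with zero totals are not allowed.
#' @return list with `statistic`, `df` (= k - 1), `p` (upper tail).
#' @examples
#' chi_square_pvalue(rbind(c(71, 97, 44, 89, 184, 93, 29, 113, 80),
#'                         c(108, 151, 47, 138, 184, 55, 43, 57, 17)))
#' @export
chi_square_pvalue <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, all(table >= 0))
  if (any(rowSums(table) <= 0) || any(colSums(table) <= 0))
    stop("degenerate table: a marginal total is zero")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  stat <- sum((table - expected)^2 / expected)
  df <- ncol(table) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Significance policy: per-order budgets for the two-level correction
#'
#' Family-wise error is controlled at two levels: a Bonferroni correction
#' over the `choose(M, t)` SNP tuples of order `t`, and a clustering-level
#' budget `alpha0[t]` calibrated by permutation on null simulations (see
#' [calibrate_alpha0()]). A module is significant when its unadjusted
#' p-value is at most `alpha0[t] / choose(M, t)`. The default budgets
#' 1.5e-3, 1.2e-8 and 1e-21 for t = 2, 3, 4 hold the family-wise false
#' positive rate near the critical level 0.1.
#'
#' @param alpha0 named numeric vector of clustering-level budgets for orders
#'   `"2"`, `"3"`, `"4"`.
#' @param critical target family-wise false positive rate (default 0.1).
#' @return An object of class `dche_policy`.
#' @export
dche_policy <- function(alpha0 = c(`2` = 1.5e-3, `3` = 1.2e-8, `4` = 1e-21),
                        critical = 0.1) {
  alpha0 <- unlist(alpha0)
  if (is.null(names(alpha0)) || any(!nzchar(names(alpha0))))
    names(alpha0) <- as.character(seq_along(alpha0) + 1L)
  stopifnot(all(alpha0 > 0), critical > 0, critical <= 1)
  structure(list(alpha0 = alpha0, critical = critical),
            class = "dche_policy")
}

#' Per-module significance threshold
#'
#' `alpha0[t] / choose(M, t)`: the clustering-level budget divided by the
#' number of order-`t` SNP tuples among `M` SNPs.
#'
#' @param policy a [dche_policy()].
#' @param t interaction order (2 to 4).
#' @param M number of SNPs.
#' @return The per-module threshold on the unadjusted p-value.
#' @examples
#' interaction_threshold(dche_policy(), t = 2, M = 1000)  # 3.0e-9
#' @export
interaction_threshold <- function(policy, t, M) {
  stopifnot(inherits(policy, "dche_policy"), t >= 2, t <= 4, M >= t)
  key <- as.character(t)
  if (!key %in% names(policy$alpha0))
    stop("no alpha0 configured for order ", t)
  policy$alpha0[[key]] / choose(M, t)
}

#' Bonferroni-adjusted p-value over order-t tuples
#'
#' @param p unadjusted p-value.
#' @param M number of SNPs.
#' @param t interaction order.
#' @return `min(1, p * choose(M, t))`.
#' @export
adjust_pvalue <- function(p, M, t) {
  stopifnot(all(p >= 0), all(p <= 1))
  pmin(1, p * choose(M, t))
}

#' Fraction of datasets reporting at least one interaction module
#'
#' The empirical family-wise false positive rate over a collection of null
#' datasets: the fraction on which the search reported one or more modules.
#'
#' @param results_per_dataset list with one element per dataset; each element
#'   is the (possibly empty) collection of reported modules.
#' @return The fraction of datasets with a non-empty report.
#' @export
false_positive_rate <- function(results_per_dataset) {
  stopifnot(length(results_per_dataset) > 0)
  mean(vapply(results_per_dataset, function(r) {
    n <- if (is.data.frame(r)) nrow(r) else length(r)
    n > 0L
  }, logical(1)))
}

# deterministic per-replicate stream seed below 2^31
derive_seed <- function(master, r) {
  (as.double(master) * 48271 + as.double(r) * 9973) %% 2147483563 + 1
}

#' Calibrate the clustering-level budget alpha0 on null simulations
#'
#' Generates `reps` null datasets (no embedded interaction; genotypes drawn
#' under Hardy-Weinberg equilibrium with per-SNP MAF uniform on
#' `[0.05, 0.5]`), runs the exhaustive order-t scan on each, and records the
#' per-dataset minimum of `p_unadjusted * choose(M, t)` over all modules.
#' The `critical` quantile of that distribution is returned as `alpha0`, so
#' that a fraction `critical` of null datasets would report at least one
#' module at the threshold `alpha0 / choose(M, t)`.
#'
#' @param t interaction order (2 or 3 supported; calibration at order 3
#'   seeds the extension with the full pair list).
#' @param M,N number of SNPs and individuals per null dataset (balanced).
#' @param reps number of null replicates (at least 50; 1000 matches the
#'   published calibration, smaller values are desk-scale).
#' @param critical target family-wise false positive rate.
#' @param seed master seed; replicate r uses an independently derived
#'   stream seed, so individual datasets are reproducible.
#' @param permute_labels if TRUE, generate one genotype matrix and permute
#'   phenotype labels across replicates instead of simulating fresh
#'   genotypes.
#' @return list with `alpha0` (the calibrated budget), `minima` (the
#'   recorded per-dataset minima), `t`, `M`, `N`, `reps`, `critical`.
#' @export
calibrate_alpha0 <- function(t, M, N, reps, critical = 0.1, seed = 1L,
                             permute_labels = FALSE) {
  stopifnot(t %in% c(2L, 3L), M >= t, N >= 4, critical > 0, critical <= 1)
  if (reps < 50) stop("reps must be at least 50 to resolve the quantile")
  if (reps * critical < 5)
    warning("few expected exceedances at this critical level; ",
            "the alpha0 estimate has a wide interval")
  base <- if (permute_labels) {
    generate_dataset(simulation_spec(M = M, N = N, seed = derive_seed(seed, 0)))$data
  } else NULL
  minima <- vapply(seq_len(reps), function(r) {
    if (permute_labels) {
      dat <- base
      set.seed(derive_seed(seed, r))
      dat$phenotypes <- sample(dat$phenotypes)
    } else {
      dat <- generate_dataset(simulation_spec(M = M, N = N,
                                              seed = derive_seed(seed, r)))$data
    }
    planes <- encode_bitplanes(dat)
    pairs <- cpp_pair_scan(planes$case_raw, planes$ctrl_raw, planes$wc,
                           planes$wt, planes$M, seq_len(M) - 1L, 1L)
    if (t == 2L) {
      min(pairs$p * choose(M, 2))
    } else {
      all_pairs <- cpp_pair_scan(planes$case_raw, planes$ctrl_raw, planes$wc,
                                 planes$wt, planes$M, seq_len(M) - 1L,
                                 choose(M, 2))
      trip <- cpp_extend_scan(planes$case_raw, planes$ctrl_raw, planes$wc,
                              planes$wt, planes$M, all_pairs$idx, 1L)
      min(trip$p * choose(M, 3))
    }
  }, numeric(1))
  alpha0 <- unname(stats::quantile(minima, probs = critical, type = 1))
  list(alpha0 = alpha0, minima = minima, t = t, M = M, N = N,
       reps = reps, critical = critical)
}
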