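#' Interleaved SNP partitioning for parallel execution
#'
#' Splits SNP indices into `d_parts` interleaved stripes: part i holds
#' indices i, i + d_parts, i + 2 d_parts, ... Striping balances the pair
#' scan because the work of pairs (i, j > i) shrinks with i; each pair is
#' owned by the stripe of its smaller index. Results merged across parts
#' are identical to a single-part run.
#'
#' @param M number of SNPs.
#' @param d_parts number of parts (1 to M).
#' @return list of `d_parts` integer vectors (1-based), jointly covering
#'   `1:M`, sizes differing by at most 1.
#' @examples
#' partition_snps(7, 3)
#' @export
partition_snps <- function(M, d_parts) {
  if (d_parts <= 0) stop("d_parts must be positive")
  if (d_parts > M) stop("d_parts must not exceed the number of SNPs")
  lapply(seq_len(d_parts), function(i) seq.int(i, M, by = d_parts))
}

# best dynamic-clustering p of one tuple; order-1 tuples are scored by a
# plain 2 x k chi-square on the genotype table (empty columns dropped).
# Untestable tables score 1 (no evidence).
eval_tuple_p <- function(planes, snps) {
  tab <- count_contingency(planes, snps)
  m <- rbind(tab$case_counts, tab$ctrl_counts)
  if (length(snps) == 1L) {
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) < 2L || any(rowSums(m) <= 0)) return(1)
    return(chi_square_pvalue(m)$p)
  }
  if (sum(colSums(m) > 0) < 2L || any(rowSums(m) <= 0)) return(1)
  dynamic_cluster(tab)$p_unadjusted
}

subset_key <- function(snps) paste(sort(as.integer(snps)), collapse = ",")

# all proper non-empty subsets of a tuple, as a list of integer vectors
proper_subsets <- function(snps) {
  t <- length(snps)
  out <- list()
  for (k in seq_len(t - 1L)) {
    cmb <- utils::combn(snps, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  out
}

#' Redundancy filter: is a module least-possible-significant?
#'
#' A t-SNP module is a least possible significant epistatic interaction iff
#' (1) its unadjusted p-value is at most the per-module threshold and
#' (2) it is strictly more significant than every proper subset of its SNPs
#' (subsets of all sizes down to single SNPs). Condition (2) rejects
#' modules in which one or more SNPs merely ride on a stronger sub-signal.
#'
#' @param snps the module's SNP indices.
#' @param p_unadjusted the module's unadjusted p-value.
#' @param threshold per-module significance threshold
#'   ([interaction_threshold()]).
#' @param subset_pvalues named numeric vector/list of p-values for every
#'   proper non-empty subset, keyed by the comma-joined sorted indices
#'   (e.g. `"3,7"`).
#' @return TRUE/FALSE.
#' @export
is_least_possible_significant <- function(snps, p_unadjusted, threshold,
                                          subset_pvalues) {
  subs <- proper_subsets(snps)
  keys <- vapply(subs, subset_key, character(1))
  missing_keys <- setdiff(keys, names(subset_pvalues))
  if (length(missing_keys) > 0)
    stop("missing subset evaluation(s): ", paste(missing_keys, collapse = "; "))
  if (p_unadjusted > threshold) return(FALSE)
  all(p_unadjusted < unlist(subset_pvalues[keys]))
}

scan_to_df <- function(scan, t) {
  idx <- scan$idx + 1L
  df <- as.data.frame(idx)
  names(df) <- paste0("snp", seq_len(t))
  df$p <- scan$p
  df$chi2 <- scan$chi2
  df$df <- scan$df
  df$d <- scan$d
  attr(df, "n_untestable") <- scan$n_untestable
  df
}

#' Exhaustive two-locus scan
#'
#' Evaluates every unordered SNP pair by [dynamic_cluster()] on its 2 x 9
#' contingency table (bitwise counting) and returns the `l` most significant
#' pairs, ascending by unadjusted p-value (ties broken by SNP indices).
#'
#' @param planes an [encode_bitplanes()] object.
#' @param l candidate-list size (default 10000).
#' @param snp_subset optional vector of first-index SNPs to restrict the
#'   scan to one partition stripe (pairs are (i in subset, j > i global)).
#' @return data frame with columns `snp1`, `snp2`, `p`, `chi2`, `df`, `d`;
#'   attribute `n_untestable` counts skipped pairs.
#' @export
exhaustive_pair_scan <- function(planes, l = 10000L, snp_subset = NULL) {
  stopifnot(inherits(planes, "dche_bitplanes"), planes$M >= 2L, l >= 1L)
  iset <- if (is.null(snp_subset)) seq_len(planes$M) else as.integer(snp_subset)
  scan <- cpp_pair_scan(planes$case_raw, planes$ctrl_raw, planes$wc,
                        planes$wt, planes$M, iset - 1L, as.integer(l))
  scan_to_df(scan, 2L)
}

#' Extend candidate tuples by one SNP
#'
#' For each order-(t-1) seed tuple and each SNP outside it, evaluates the
#' order-t tuple by [dynamic_cluster()]; duplicate formations (the same SNP
#' set reached from different seeds) are evaluated once. Returns the top
#' `l` unique tuples ascending by p-value.
#'
#' @param planes an [encode_bitplanes()] object.
#' @param seeds matrix or data frame of seed tuples (one row each, 1-based
#'   indices), e.g. the `snp1`/`snp2` columns of [exhaustive_pair_scan()].
#' @param l candidate-list size.
#' @return data frame like [exhaustive_pair_scan()] with t index columns.
#' @export
extend_candidates <- function(planes, seeds, l = 4000L) {
  stopifnot(inherits(planes, "dche_bitplanes"))
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) {
    warning("empty seed list; nothing to extend")
    return(data.frame())
  }
  storage.mode(seeds) <- "integer"
  t <- ncol(seeds) + 1L
  scan <- cpp_extend_scan(planes$case_raw, planes$ctrl_raw, planes$wc,
                          planes$wt, planes$M, seeds - 1L, as.integer(l))
  scan_to_df(scan, t)
}

#' Search configuration
#'
#' @param t_max maximum interaction order (2 to 4).
#' @param top per-order candidate-list sizes for t = 2, 3, 4.
#' @param policy a [dche_policy()].
#' @param partitions number of interleaved stripes for the pair scan.
#' @return An object of class `dche_config`.
#' @export
dche_config <- function(t_max = 2L, top = c(10000L, 4000L, 2000L),
                        policy = dche_policy(), partitions = 1L) {
  if (!t_max %in% 2:4)
    stop("supported interaction orders are 2 to 4 (t_max = ", t_max, ")")
  top <- as.integer(top)
  if (length(top) < t_max - 1L) stop("top must give a list size per order")
  stopifnot(all(top >= 1L), partitions >= 1L)
  structure(list(t_max = as.integer(t_max), top = top, policy = policy,
                 partitions = as.integer(partitions)),
            class = "dche_config")
}

#' Detect high-order epistatic interactions by dynamic clustering
#'
#' The main entry point. Runs the stepwise search on a case-control
#' genotype matrix: (optional) per-SNP quality control, bit-plane encoding,
#' an exhaustive two-locus scan scored by [dynamic_cluster()], and stepwise
#' extension of the best candidates to orders 3 and 4. Each reported module
#' carries its merged grouping, unadjusted and Bonferroni-adjusted
#' p-values, the two-level significance threshold
#' `alpha0[t] / choose(M, t)`, and the redundancy flag of
#' [is_least_possible_significant()]. The search is deterministic.
#'
#' @param data a [genotype_matrix()] object.
#' @param t_max maximum interaction order (2 to 4).
#' @param top per-order candidate-list sizes for t = 2, 3, 4.
#' @param policy a [dche_policy()] (per-order alpha0 budgets and the
#'   critical level).
#' @param partitions number of interleaved stripes for the pair scan; the
#'   output is identical for any value.
#' @param qc apply [quality_control()] first (default FALSE; supply
#'   `maf_min`, `missing_max`, `hwe_min` to tune).
#' @param maf_min,missing_max,hwe_min QC thresholds, see
#'   [quality_control()].
#' @return An object of class `dche`: list with `results` (one data frame
#'   per order, columns `rank`, `snps`, `snp_names`, `d`, `grouping`,
#'   `chi2`, `df`, `p_unadjusted`, `p_adjusted`, `threshold`,
#'   `significant`, `least_possible_significant`), `M`, `n_case`,
#'   `n_ctrl`, `config`, `qc_report`, `counters`.
#' @examples
#' sim <- generate_dataset(simulation_spec(M = 20, N = 400, seed = 7))
#' fit <- dche(sim$data, t_max = 2, top = 5)
#' fit
#' @export
dche <- function(data, t_max = 2L, top = c(10000L, 4000L, 2000L),
                 policy = dche_policy(), partitions = 1L, qc = FALSE,
                 maf_min = 0.05, missing_max = 0.10, hwe_min = 0.001) {
  stopifnot(inherits(data, "dche_genotypes"))
  config <- dche_config(t_max, top, policy, partitions)
  qc_report <- NULL
  if (qc) {
    qcres <- quality_control(data, maf_min, missing_max, hwe_min)
    data <- qcres$data
    qc_report <- qcres$report
  }
  M <- ncol(data$genotypes)
  if (M < 2L) stop("need at least 2 SNPs after quality control")
  planes <- encode_bitplanes(data)

  counters <- list()
  lists <- list()
  # exhaustive pair scan over interleaved stripes, merged and re-truncated
  l2 <- config$top[1L]
  parts <- partition_snps(M, min(config$partitions, M))
  pieces <- lapply(parts, function(iset)
    exhaustive_pair_scan(planes, l = l2, snp_subset = iset))
  pairs <- do.call(rbind, pieces)
  pairs <- pairs[order(pairs$p, pairs$snp1, pairs$snp2), , drop = FALSE]
  pairs <- utils::head(pairs, l2)
  rownames(pairs) <- NULL
  counters[["2"]] <- sum(vapply(pieces, function(p)
    attr(p, "n_untestable"), numeric(1)))
  lists[["2"]] <- pairs

  if (config$t_max >= 3L) {
    for (t in 3:config$t_max) {
      seeds <- lists[[as.character(t - 1L)]][, seq_len(t - 1L), drop = FALSE]
      ext <- extend_candidates(planes, seeds, l = config$top[t - 1L])
      counters[[as.character(t)]] <- attr(ext, "n_untestable")
      lists[[as.character(t)]] <- ext
    }
  }

  results <- lapply(names(lists), function(tt) {
    build_results(lists[[tt]], as.integer(tt), planes, data$snp_names, M,
                  config$policy)
  })
  names(results) <- names(lists)

  structure(list(results = results, M = M,
                 n_case = planes$n_case, n_ctrl = planes$n_ctrl,
                 config = config, qc_report = qc_report,
                 counters = counters, call = match.call()),
            class = "dche")
}

# assemble the reported module table for one order, including groupings and
# the redundancy flag (needs p-values of every proper subset)
build_results <- function(cand, t, planes, snp_names, M, policy) {
  n <- nrow(cand)
  threshold <- interaction_threshold(policy, t, M)
  empty <- data.frame(rank = integer(0), snps = character(0),
                      snp_names = character(0), d = integer(0),
                      grouping = character(0), chi2 = numeric(0),
                      df = integer(0), p_unadjusted = numeric(0),
                      p_adjusted = numeric(0), threshold = numeric(0),
                      significant = logical(0),
                      least_possible_significant = logical(0))
  if (n == 0L) return(empty)
  idx <- as.matrix(cand[, seq_len(t), drop = FALSE])
  # subset p-value cache shared across modules of this order
  cache <- new.env(parent = emptyenv())
  subset_p <- function(snps) {
    key <- subset_key(snps)
    if (is.null(cache[[key]])) cache[[key]] <- eval_tuple_p(planes, snps)
    cache[[key]]
  }
  rows <- lapply(seq_len(n), function(r) {
    snps <- idx[r, ]
    cl <- dynamic_cluster(count_contingency(planes, snps))
    subs <- proper_subsets(snps)
    sp <- vapply(subs, subset_p, numeric(1))
    names(sp) <- vapply(subs, subset_key, character(1))
    lps <- is_least_possible_significant(snps, cl$p_unadjusted, threshold, sp)
    data.frame(rank = r, snps = paste(snps, collapse = ","),
               snp_names = paste(snp_names[snps], collapse = ","),
               d = cl$d, grouping = format_blocks(cl$grouping$blocks),
               chi2 = cl$chi2, df = cl$df, p_unadjusted = cl$p_unadjusted,
               p_adjusted = adjust_pvalue(cl$p_unadjusted, M, t),
               threshold = threshold,
               significant = cl$p_unadjusted <= threshold,
               least_possible_significant = lps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.dche <- function(x, ...) {
  cat("Dynamic-clustering epistasis search:", x$M, "SNPs,",
      x$n_case, "cases /", x$n_ctrl, "controls\n")
  for (tt in names(x$results)) {
    res <- x$results[[tt]]
    cat("order", tt, ":", nrow(res), "candidate modules,",
        sum(res$significant), "significant,",
        sum(res$least_possible_significant), "least-possible-significant\n")
    if (nrow(res) > 0) {
      top <- res[1L, ]
      cat("  top: SNPs (", top$snps, ")  d =", top$d,
          " p =", format(top$p_unadjusted, digits = 4),
          " adjusted =", format(top$p_adjusted, digits = 4), "\n")
    }
  }
  invisible(x)
}

#' @export
summary.dche <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$results), function(tt) {
    res <- object$results[[tt]]
    data.frame(order = as.integer(tt), candidates = nrow(res),
               significant = sum(res$significant),
               least_possible = sum(res$least_possible_significant),
               best_p = if (nrow(res)) min(res$p_unadjusted) else NA_real_,
               threshold = if (nrow(res)) res$threshold[1L] else NA_real_)
  }))
  class(out) <- c("summary.dche", "data.frame")
  out
}

#' @export
print.summary.dche <- function(x, ...) {
  cat("Reported interaction modules per order:\n")
  print.data.frame(x)
  invisible(x)
}

#' @export
as.data.frame.dche <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- do.call(rbind, lapply(names(x$results), function(tt) {
    res <- x$results[[tt]]
    if (nrow(res) == 0L) return(NULL)
    cbind(order = as.integer(tt), res)
  }))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- row.names
  out
}

#' @export
plot.dche <- function(x, order = names(x$results)[1L], ...) {
  res <- x$results[[as.character(order)]]
  if (is.null(res) || nrow(res) == 0L) {
    warning("no modules to plot at order ", order)
    return(invisible(x))
  }
  plot(res$rank, -log10(res$p_unadjusted), type = "h", lwd = 2,
       xlab = "candidate rank", ylab = expression(-log[10](p)),
       main = paste0("Order-", order, " interaction candidates"), ...)
  abline(h = -log10(res$threshold[1L]), lty = 2, col = "red")
  legend("topright", legend = "significance threshold", lty = 2,
         col = "red", bty = "n")
  invisible(x)
}

#' Write the result tables of a search to TSV files
#'
#' One file per order (`dche_t2.tsv`, ...), columns as in the `results`
#' element of [dche()].
#'
#' @param x a [dche()] object.
#' @param dir output directory (created if absent).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "dche"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(names(x$results), function(tt) {
    f <- file.path(dir, paste0("dche_t", tt, ".tsv"))
    utils::write.table(x$results[[tt]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }, character(1))
  invisible(files)
}
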