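#' Detection power over simulated replicates
#'
#' A replicate counts as detected iff the top-ranked module's SNP set equals
#' the embedded ground truth and its Bonferroni-adjusted p-value is at most
#' the critical level. Power is the detected fraction; the overall quality
#' `q` pools correct detections across all replicates supplied.
#'
#' @param results list with one element per replicate: the order-t result
#'   data frame of [dche()] (or any data frame with `snps` and
#'   `p_adjusted` columns, best module first).
#' @param truths list of ground-truth SNP index vectors, aligned with
#'   `results`.
#' @param critical significance level on the adjusted p-value (default 0.1).
#' @return list with `power`, `q`, `n_correct`, `n_datasets`, `detected`
#'   (per-replicate logical).
#' @export
detection_power <- function(results, truths, critical = 0.1) {
  if (length(results) != length(truths))
    stop("results and truths must have the same length")
  detected <- mapply(function(res, truth) {
    if (is.null(res) || nrow(res) == 0L) return(FALSE)
    top <- res[1L, ]
    top_set <- sort(as.integer(strsplit(top$snps, ",")[[1L]]))
    setequal(top_set, as.integer(truth)) && top$p_adjusted <= critical
  }, results, truths)
  n_correct <- sum(detected)
  list(power = n_correct / length(results), q = n_correct / length(results),
       n_correct = n_correct, n_datasets = length(results),
       detected = as.logical(detected))
}

#' Centre elements of a top-k interaction list
#'
#' Ranks SNPs (or any elements) by how often they occur among the top-k
#' reported tuples; the `s` most frequent are the "centre" elements. Ties
#' are broken by first appearance in the ranked list.
#'
#' @param tuples list of tuples (vectors of SNP indices or names), best
#'   first.
#' @param s number of centre elements to return.
#' @return data frame with columns `element` and `frequency`, at most `s`
#'   rows.
#' @export
centre_elements <- function(tuples, s) {
  stopifnot(s >= 1)
  if (length(tuples) == 0L)
    return(data.frame(element = character(0), frequency = integer(0)))
  flat <- unlist(lapply(tuples, as.character))
  first_seen <- !duplicated(flat)
  order_of_appearance <- stats::setNames(seq_along(flat)[first_seen],
                                         flat[first_seen])
  counts <- table(flat)
  elements <- names(counts)
  ord <- order(-as.integer(counts), order_of_appearance[elements])
  out <- data.frame(element = elements[ord],
                    frequency = as.integer(counts)[ord],
                    row.names = NULL)
  utils::head(out, s)
}
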