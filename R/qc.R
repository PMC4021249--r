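#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Pearson chi-square test with 1 degree of freedom of observed genotype
#' counts against the Hardy-Weinberg expectation at the estimated allele
#' frequency. Monomorphic SNPs (allele frequency 0 or 1) return p = 1 by
#' convention.
#'
#' @param counts integer triple `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @return Upper-tail p-value.
#' @examples
#' hwe_test(c(81, 18, 1))  # exact HWE proportions at allele frequency 0.1
#' @export
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0)) {
    stop("counts must be three non-negative genotype counts")
  }
  n <- sum(counts)
  if (n <= 0) stop("total count must be positive")
  q <- (counts[2L] + 2 * counts[3L]) / (2 * n)
  if (q <= 0 || q >= 1) return(1)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((counts - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Minor allele frequency per SNP from non-missing genotypes (all samples).
snp_maf <- function(geno) {
  apply(geno, 2L, function(col) {
    ok <- col != 3L
    n <- sum(ok)
    if (n == 0L) return(NA_real_)
    q <- sum(col[ok]) / (2 * n)  # frequency of the coded (minor-labelled) allele
    min(q, 1 - q)
  })
}

#' Per-SNP quality control
#'
#' Removes SNPs with high missingness, low minor allele frequency, or strong
#' departure from Hardy-Weinberg equilibrium. With the default thresholds a
#' SNP is kept iff its missing rate is at most 10%, its MAF at least 0.05 and
#' its HWE p-value (computed on controls) at least 0.001. MAF is estimated
#' from non-missing genotypes over all samples.
#'
#' @param data a [genotype_matrix()] object.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param missing_max maximum fraction of missing genotypes (default 0.10).
#' @param hwe_min minimum HWE p-value on controls (default 0.001).
#' @return list with `data` (the filtered [genotype_matrix()]) and `report`,
#'   a data frame with one row per input SNP: `snp`, `maf`, `missing_rate`,
#'   `hwe_p`, `kept`.
#' @export
quality_control <- function(data, maf_min = 0.05, missing_max = 0.10,
                            hwe_min = 0.001) {
  stopifnot(inherits(data, "dche_genotypes"))
  stopifnot(maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1,
            hwe_min >= 0, hwe_min <= 1)
  geno <- data$genotypes
  miss <- colMeans(geno == 3L)
  maf <- snp_maf(geno)
  ctrl <- geno[data$phenotypes == 0L, , drop = FALSE]
  hwe <- apply(ctrl, 2L, function(col) {
    ok <- col != 3L
    if (!any(ok)) return(1)
    hwe_test(tabulate(col[ok] + 1L, nbins = 3L))
  })
  kept <- miss <= missing_max & !is.na(maf) & maf >= maf_min & hwe >= hwe_min
  report <- data.frame(snp = data$snp_names, maf = maf, missing_rate = miss,
                       hwe_p = hwe, kept = kept, row.names = NULL)
  if (!any(kept)) {
    warning("quality control removed all SNPs")
    filtered <- data
    filtered$genotypes <- geno[, kept, drop = FALSE]
    filtered$snp_names <- character(0)
  } else {
    filtered <- genotype_matrix(geno[, kept, drop = FALSE], data$phenotypes,
                                data$snp_names[kept])
  }
  list(data = filtered, report = report)
}
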