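#' Construct a case-control genotype matrix
#'
#' The basic data container: an `N x M` integer matrix of genotype codes with
#' a binary phenotype per row. Codes follow the minor-allele-count convention
#' used by the BOOST text format: 0 = homozygous major (AA), 1 = heterozygous
#' (Aa), 2 = homozygous minor (aa), 3 = missing.
#'
#' @param genotypes integer matrix (individuals in rows, SNPs in columns)
#'   with entries in `{0,1,2,3}`.
#' @param phenotypes integer vector of length `nrow(genotypes)`; 1 = case,
#'   0 = control.
#' @param snp_names optional character vector of unique SNP identifiers;
#'   defaults to `snp1..snpM`.
#' @return An object of class `dche_genotypes`: a list with elements
#'   `genotypes`, `phenotypes`, `snp_names`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0), 2, 2), c(1, 0))
#' g
#' @export
genotype_matrix <- function(genotypes, phenotypes, snp_names = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  phenotypes <- as.integer(phenotypes)
  if (nrow(genotypes) == 0L) stop("empty dataset: no individuals")
  if (length(phenotypes) != nrow(genotypes))
    stop("phenotypes must have one entry per row of genotypes")
  if (anyNA(genotypes) || any(genotypes < 0L | genotypes > 3L))
    stop("genotype codes must be in {0,1,2,3} (3 = missing)")
  if (anyNA(phenotypes) || any(phenotypes != 0L & phenotypes != 1L))
    stop("phenotypes must be 0 (control) or 1 (case)")
  if (is.null(snp_names)) snp_names <- paste0("snp", seq_len(ncol(genotypes)))
  snp_names <- as.character(snp_names)
  if (length(snp_names) != ncol(genotypes))
    stop("snp_names must have one entry per SNP")
  if (anyDuplicated(snp_names)) stop("snp_names must be unique")
  dimnames(genotypes) <- NULL
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 snp_names = snp_names),
            class = "dche_genotypes")
}

#' @export
print.dche_genotypes <- function(x, ...) {
  cat("Case-control genotype data:", nrow(x$genotypes), "individuals (",
      sum(x$phenotypes == 1L), "cases /", sum(x$phenotypes == 0L),
      "controls ),", ncol(x$genotypes), "SNPs\n")
  nmiss <- sum(x$genotypes == 3L)
  if (nmiss > 0) cat("Missing genotypes:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.dche_genotypes <- function(x) dim(x$genotypes)

n_cases <- function(x) sum(x$phenotypes == 1L)
n_controls <- function(x) sum(x$phenotypes == 0L)

#' Read a BOOST-format case-control genotype file
#'
#' One row per individual; the first whitespace-delimited field is the
#' phenotype (1 = case, 0 = control), the remaining `M` fields are genotype
#' codes in `{0,1,2,3}` (3 = missing).
#'
#' @param path path to the text file.
#' @param snp_names optional character vector of SNP names, or the path of a
#'   companion file holding one name per line.
#' @return A [genotype_matrix()] object.
#' @export
read_genotypes <- function(path, snp_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf != nf[1L]))
    stop("ragged rows: line ", which(nf != nf[1L])[1L], " has ",
         nf[which(nf != nf[1L])[1L]], " fields, expected ", nf[1L])
  if (nf[1L] < 2L) stop("each row needs a phenotype and at least one genotype")
  vals <- suppressWarnings(as.integer(unlist(toks)))
  if (anyNA(vals)) {
    bad <- which(is.na(matrix(vals, ncol = nf[1L], byrow = TRUE)),
                 arr.ind = TRUE)[1L, 1L]
    stop("malformed token on line ", bad)
  }
  mat <- matrix(vals, ncol = nf[1L], byrow = TRUE)
  pheno <- mat[, 1L]
  if (any(pheno != 0L & pheno != 1L))
    stop("phenotype outside {0,1} on line ", which(pheno != 0L & pheno != 1L)[1L])
  geno <- mat[, -1L, drop = FALSE]
  if (any(geno < 0L | geno > 3L)) {
    bad <- which(apply(geno < 0L | geno > 3L, 1L, any))[1L]
    stop("genotype outside {0,1,2,3} on line ", bad)
  }
  if (is.character(snp_names) && length(snp_names) == 1L &&
      file.exists(snp_names))
    snp_names <- readLines(snp_names)
  genotype_matrix(geno, pheno, snp_names)
}

#' Write a genotype matrix in BOOST text format
#'
#' @param data a [genotype_matrix()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(data, path) {
  stopifnot(inherits(data, "dche_genotypes"))
  if (nrow(data$genotypes) == 0L) stop("empty dataset")
  body <- cbind(data$phenotypes, data$genotypes)
  lines <- apply(body, 1L, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Encode genotypes as per-genotype bit planes
#'
#' Each SNP column is expanded into three bit vectors per phenotype group,
#' one per genotype code; bit `b` of the plane for genotype `g` is set iff
#' the `b`-th case (respectively control) carries `g` at that SNP. Missing
#' genotypes set no bit. Contingency tables of SNP tuples are then collected
#' by bitwise AND + popcount, the key trick that makes the exhaustive pair
#' scan affordable.
#'
#' @param data a [genotype_matrix()] object.
#' @return An object of class `dche_bitplanes` (opaque; consumed by
#'   [count_contingency()] and the search functions).
#' @export
encode_bitplanes <- function(data) {
  stopifnot(inherits(data, "dche_genotypes"))
  enc <- cpp_encode_bitplanes(data$genotypes, data$phenotypes)
  enc$snp_names <- data$snp_names
  class(enc) <- "dche_bitplanes"
  enc
}

#' @export
print.dche_bitplanes <- function(x, ...) {
  cat("Bit-plane encoded genotypes:", x$M, "SNPs,", x$n_case, "cases,",
      x$n_ctrl, "controls\n")
  invisible(x)
}

#' Contingency table of a SNP tuple
#'
#' Cross-tabulates phenotype against the `3^t` genotype combinations of a
#' tuple of `t` SNPs. Cells are labelled `0 .. 3^t - 1` in mixed-radix base
#' 3 with the first SNP as the most significant digit (for `t = 2` this is
#' the usual left-to-right, top-to-bottom reading of the 3 x 3 layout).
#' Individuals missing at any SNP of the tuple contribute to no cell.
#'
#' @param planes an [encode_bitplanes()] object.
#' @param snps integer vector of 1 to 4 distinct SNP indices (1-based).
#' @return An object of class `dche_table`: list with `snps`, `case_counts`,
#'   `ctrl_counts` (length `3^t`, cell order as above) and `t`.
#' @export
count_contingency <- function(planes, snps) {
  stopifnot(inherits(planes, "dche_bitplanes"))
  snps <- as.integer(snps)
  counts <- cpp_count_contingency(planes$case_raw, planes$ctrl_raw,
                                  planes$wc, planes$wt, planes$M, snps - 1L)
  structure(list(snps = snps, case_counts = counts[1L, ],
                 ctrl_counts = counts[2L, ], t = length(snps)),
            class = "dche_table")
}

#' @export
print.dche_table <- function(x, ...) {
  cat("2 x", 3L^x$t, "contingency table for SNPs",
      paste(x$snps, collapse = ","), "\n")
  m <- rbind(case = x$case_counts, control = x$ctrl_counts)
  colnames(m) <- paste0("c", seq_len(ncol(m)) - 1L)
  print(m)
  invisible(x)
}

#' Pairwise overlap of the genotype bit planes of one SNP
#'
#' Diagnostic used to verify the planes are well-formed: entry `(a, b)` is
#' the popcount of the AND of the planes for genotypes `a-1` and `b-1`.
#' Off-diagonal entries are always 0 (an individual has one genotype).
#'
#' @param planes an [encode_bitplanes()] object.
#' @param snp SNP index (1-based).
#' @return list with 3 x 3 integer matrices `case` and `ctrl`.
#' @export
plane_overlap <- function(planes, snp) {
  stopifnot(inherits(planes, "dche_bitplanes"))
  list(case = cpp_plane_overlap(planes$case_raw, planes$wc, planes$M,
                                as.integer(snp) - 1L),
       ctrl = cpp_plane_overlap(planes$ctrl_raw, planes$wt, planes$M,
                                as.integer(snp) - 1L))
}
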