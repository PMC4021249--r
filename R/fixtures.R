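#' Generate named toy datasets
#'
#' Writes small BOOST-format genotype files used in examples and tests:
#' \describe{
#'   \item{`table4a`}{two SNPs, 800 cases / 800 controls, whose 2 x 9
#'     contingency table equals the first worked example table
#'     (71(108), 97(151), 44(47), 89(138), 184(184), 93(55), 29(43),
#'     113(57), 80(17)).}
#'   \item{`table4b`}{two SNPs, 400 cases / 400 controls, reproducing the
#'     second worked example table (40(55) ... 30(10)), the one whose
#'     dynamic clustering yields the 161/129/110 vs 238/59/103 pattern.}
#'   \item{`null_small`}{50 null SNPs, 200 balanced samples.}
#'   \item{`strong_pair`}{100 SNPs, 1600 balanced samples, one embedded
#'     two-locus multiplicative interaction (prevalence 0.1, heritability
#'     0.03, MAF 0.4) at SNPs 3 and 7.}
#' }
#' The contingency-table fixtures assign individuals to genotype cells
#' deterministically (any assignment with the right cell counts yields the
#' same table); the simulated fixtures depend on `seed`.
#'
#' @param name one of `"table4a"`, `"table4b"`, `"null_small"`,
#'   `"strong_pair"`.
#' @param seed integer seed for the simulated fixtures.
#' @param path output file path (default: a temporary file).
#' @return The path of the written file.
#' @export
make_fixture <- function(name, seed = 1L, path = tempfile(fileext = ".txt")) {
  data <- switch(name,
    table4a = table_fixture(
      case = c(71, 97, 44, 89, 184, 93, 29, 113, 80),
      ctrl = c(108, 151, 47, 138, 184, 55, 43, 57, 17)),
    table4b = table_fixture(
      case = c(40, 49, 13, 43, 110, 49, 16, 50, 30),
      ctrl = c(55, 76, 21, 62, 103, 22, 24, 27, 10)),
    null_small = generate_dataset(
      simulation_spec(M = 50, N = 200, seed = seed))$data,
    strong_pair = {
      solved <- solve_effect_params("multiplicative",
                                    target_prevalence = 0.1,
                                    target_h2 = 0.03, maf = c(0.4, 0.4))
      generate_dataset(simulation_spec(M = 100, N = 1600,
                                       model = solved$model,
                                       disease_loci = c(3L, 7L),
                                       seed = seed))$data
    },
    stop("unknown fixture name: ", name)
  )
  write_genotypes(data, path)
  path
}

# two-SNP genotype data realising exact 2 x 9 cell counts
table_fixture <- function(case, ctrl) {
  cell_rows <- function(counts) {
    cells <- rep(0:8, counts)
    cbind(cells %/% 3L, cells %% 3L)
  }
  geno <- rbind(cell_rows(case), cell_rows(ctrl))
  pheno <- rep(c(1L, 0L), c(sum(case), sum(ctrl)))
  genotype_matrix(geno, pheno)
}
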