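test_that("BOOST text parsing maps fields to phenotype and genotypes", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0 1 2", "1 1 1 0", "0 2 0 1", "0 0 0 0"), f)
  d <- read_genotypes(f)
  expect_equal(dim(d), c(4L, 3L))
  expect_equal(sum(d$phenotypes == 1L), 2L)
  expect_equal(sum(d$phenotypes == 0L), 2L)
  expect_equal(d$genotypes[1L, ], c(0L, 1L, 2L))

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_genotypes(empty), "no records")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0 1", "0 x 1"), bad)
  expect_error(read_genotypes(bad), "line 2")

  ragged <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0 1", "0 1"), ragged)
  expect_error(read_genotypes(ragged), "ragged")

  pheno2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 0 1"), pheno2)
  expect_error(read_genotypes(pheno2), "phenotype")

  gen9 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0 9"), gen9)
  expect_error(read_genotypes(gen9), "genotype")
})

test_that("write/read round-trips, including missing codes", {
  one <- genotype_matrix(matrix(2L, 1, 1), 1L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_genotypes(one, f)
  expect_equal(readLines(f), "1 2")

  set.seed(31)
  for (rep in 1:5) {
    N <- sample(5:40, 1)
    M <- sample(2:15, 1)
    geno <- matrix(sample(0:3, N * M, TRUE, prob = c(.4, .3, .2, .1)), N, M)
    d <- genotype_matrix(geno, rbinom(N, 1, 0.5))
    f <- tempfile(fileext = ".txt")
    write_genotypes(d, f)
    d2 <- read_genotypes(f)
    expect_identical(d2$genotypes, d$genotypes)
    expect_identical(d2$phenotypes, d$phenotypes)
    unlink(f)
  }

  expect_error(genotype_matrix(matrix(integer(0), 0, 2), integer(0)),
               "empty dataset")
  expect_error(genotype_matrix(matrix(0L, 2, 2), c(1L, 0L),
                               snp_names = c("a", "a")), "unique")
})

test_that("bit planes are complete, disjoint, and ignore missing genotypes", {
  d <- genotype_matrix(matrix(c(0L, 1L, 1L, 2L), 4, 1), rep(1L, 4))
  pl <- encode_bitplanes(d)
  tab <- count_contingency(pl, 1)
  expect_equal(tab$case_counts, c(1L, 2L, 1L))
  expect_equal(tab$ctrl_counts, c(0L, 0L, 0L))

  allmiss <- genotype_matrix(matrix(3L, 5, 1), c(1L, 1L, 0L, 0L, 0L))
  tab <- count_contingency(encode_bitplanes(allmiss), 1)
  expect_equal(tab$case_counts, c(0L, 0L, 0L))
  expect_equal(tab$ctrl_counts, c(0L, 0L, 0L))

  set.seed(7)
  N <- 200; M <- 50
  geno <- matrix(sample(0:3, N * M, TRUE, prob = c(.45, .3, .2, .05)), N, M)
  pheno <- rbinom(N, 1, 0.5)
  d <- genotype_matrix(geno, pheno)
  pl <- encode_bitplanes(d)
  for (i in c(1L, 17L, 50L)) {
    tab <- count_contingency(pl, i)
    for (g in 0:2) {
      expect_equal(tab$case_counts[g + 1L], sum(geno[pheno == 1, i] == g))
      expect_equal(tab$ctrl_counts[g + 1L], sum(geno[pheno == 0, i] == g))
    }
    # completeness: plane popcounts account for every non-missing individual
    expect_equal(sum(tab$case_counts),
                 sum(pheno == 1) - sum(geno[pheno == 1, i] == 3L))
    # disjointness: the same individual is never in two genotype planes
    ov <- plane_overlap(pl, i)
    expect_true(all(ov$case[upper.tri(ov$case)] == 0L))
    expect_true(all(ov$ctrl[upper.tri(ov$ctrl)] == 0L))
    expect_equal(diag(ov$case), tab$case_counts)
  }
})

test_that("bitwise contingency counting equals the nested-loop oracle", {
  set.seed(12)
  for (rep in 1:3) {
    N <- sample(50:500, 1)
    M <- sample(6:20, 1)
    miss <- if (rep == 1) 0 else 0.05
    geno <- matrix(sample(0:3, N * M, TRUE,
                          prob = c(.4 * (1 - miss) / .9, .3 * (1 - miss) / .9,
                                   .2 * (1 - miss) / .9, miss)), N, M)
    pheno <- rbinom(N, 1, 0.5)
    d <- genotype_matrix(geno, pheno)
    pl <- encode_bitplanes(d)
    for (t in 1:3) {
      snps <- sample(M, t)
      tab <- count_contingency(pl, snps)
      orc <- oracle_count(geno, pheno, snps)
      expect_equal(tab$case_counts, unname(orc[1L, ]))
      expect_equal(tab$ctrl_counts, unname(orc[2L, ]))
    }
    if (miss == 0) {
      tab <- count_contingency(pl, sample(M, 2))
      expect_equal(sum(tab$case_counts), sum(pheno == 1))
      expect_equal(sum(tab$ctrl_counts), sum(pheno == 0))
    }
  }
  d <- genotype_matrix(matrix(0:3, 4, 4), c(1L, 1L, 0L, 0L))
  pl <- encode_bitplanes(d)
  expect_error(count_contingency(pl, c(2, 2)), "degenerate tuple")
})

test_that("quality control applies the missingness/MAF/HWE filter", {
  set.seed(5)
  n_ctrl <- 100; n_case <- 100; N <- n_case + n_ctrl
  pheno <- rep(c(1L, 0L), c(n_case, n_ctrl))
  # SNP 1: healthy (MAF ~0.3, HWE)
  s1 <- rbinom(N, 2, 0.3)
  # SNP 2: 15% missing
  s2 <- rbinom(N, 2, 0.3); s2[sample(N, 30)] <- 3L
  # SNP 3: rare (MAF 0.04 exactly among non-missing: 16 hets in 200)
  s3 <- rep(0L, N); s3[sample(N, 16)] <- 1L
  # SNP 4: gross HWE violation in controls (all het)
  s4 <- c(rbinom(n_case, 2, 0.5), rep(1L, n_ctrl))
  d <- genotype_matrix(cbind(s1, s2, s3, s4), pheno,
                       snp_names = c("ok", "miss", "rare", "hwe"))
  qc <- quality_control(d)
  expect_equal(qc$report$kept, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(qc$report$maf[3L], 16 / (2 * 200))
  expect_gt(qc$report$missing_rate[2L], 0.10)
  expect_lt(qc$report$hwe_p[4L], 0.001)
  expect_equal(qc$data$snp_names, "ok")

  # idempotence: filtering the filtered data keeps the same SNP set
  qc2 <- quality_control(qc$data)
  expect_equal(qc2$data$snp_names, qc$data$snp_names)

  # control-only HWE: exact HWE proportions in controls are kept even if
  # cases deviate
  s5 <- c(rep(2L, n_case), rep(c(0L, 1L, 2L), c(81L, 18L, 1L)))
  d5 <- genotype_matrix(cbind(s1, s5), pheno)
  qc5 <- quality_control(d5)
  expect_true(qc5$report$kept[2L])
  expect_gt(qc5$report$hwe_p[2L], 0.9)
})

test_that("HWE chi-square test matches the df=1 closed form", {
  expect_gt(hwe_test(c(81, 18, 1)), 0.99)  # exact HWE proportions
  # (25,0,25): allele freq 0.5, expected (12.5,25,12.5), chi2 = 50
  expect_equal(hwe_test(c(25, 0, 25)),
               pchisq(50, df = 1, lower.tail = FALSE))
  expect_lt(hwe_test(c(25, 0, 25)), 1e-10)
  expect_equal(hwe_test(c(100, 0, 0)), 1)  # monomorphic convention
  expect_error(hwe_test(c(0, 0, 0)), "positive")
})
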