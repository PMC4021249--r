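# build a dataset embedding the printed Table-4b pair among null SNPs
embed_4b_dataset <- function(n_null = 8, seed = 77) {
  d <- read_genotypes(make_fixture("table4b"))
  set.seed(seed)
  N <- nrow(d$genotypes)
  null_cols <- matrix(rbinom(N * n_null, 2, runif(n_null, 0.1, 0.4)[
    rep(seq_len(n_null), each = N)]), N, n_null)
  genotype_matrix(cbind(d$genotypes, null_cols), d$phenotypes)
}

test_that("exhaustive pair scan ranks the embedded pair first", {
  d <- embed_4b_dataset()
  pl <- encode_bitplanes(d)
  top <- exhaustive_pair_scan(pl, l = 5)
  expect_equal(c(top$snp1[1], top$snp2[1]), c(1L, 2L))
  expect_equal(top$p[1], 1.1578e-9, tolerance = 1e-4)
  expect_true(all(diff(top$p) >= 0))  # ascending by p

  two <- genotype_matrix(matrix(rbinom(100, 2, 0.3), 50, 2),
                         rep(c(1L, 0L), 25))
  expect_equal(nrow(exhaustive_pair_scan(encode_bitplanes(two), l = 10)), 1L)

  # two monomorphic SNPs: single non-empty cell, pair is untestable
  mono <- genotype_matrix(matrix(0L, 20, 2), rep(c(1L, 0L), 10))
  scan <- exhaustive_pair_scan(encode_bitplanes(mono), l = 10)
  expect_equal(nrow(scan), 0L)
  expect_equal(attr(scan, "n_untestable"), 1)
})

test_that("pair scan results are invariant to SNP column order", {
  set.seed(19)
  N <- 120; M <- 8
  geno <- matrix(rbinom(N * M, 2, 0.3), N, M)
  pheno <- rep(c(1L, 0L), N / 2)
  d <- genotype_matrix(geno, pheno)
  full <- exhaustive_pair_scan(encode_bitplanes(d), l = choose(M, 2))
  key <- function(df, map = seq_len(M)) {
    i <- map[df$snp1]; j <- map[df$snp2]
    paste(pmin(i, j), pmax(i, j))
  }
  perm <- sample(M)
  dp <- genotype_matrix(geno[, perm], pheno)
  fullp <- exhaustive_pair_scan(encode_bitplanes(dp), l = choose(M, 2))
  p1 <- setNames(full$p, key(full))
  p2 <- setNames(fullp$p, key(fullp, perm))
  expect_equal(p2[names(p1)], p1)
})

test_that("candidate extension enumerates, dedupes and truncates", {
  set.seed(41)
  d <- genotype_matrix(matrix(rbinom(100 * 5, 2, 0.3), 100, 5),
                       rep(c(1L, 0L), 50))
  pl <- encode_bitplanes(d)
  ext <- extend_candidates(pl, matrix(c(1L, 2L), 1), l = 100)
  expect_equal(nrow(ext), 3L)  # M - 2 extensions of one seed
  sets <- apply(ext[, 1:3], 1, function(x) paste(sort(x), collapse = ","))
  expect_false(anyDuplicated(sets) > 0)

  # (1,2)+3 and (1,3)+2 form the same set: one entry
  ext2 <- extend_candidates(pl, rbind(c(1L, 2L), c(1L, 3L)), l = 100)
  sets2 <- apply(ext2[, 1:3], 1, function(x) paste(sort(x), collapse = ","))
  expect_equal(anyDuplicated(sets2), 0L)
  expect_true("1,2,3" %in% sets2)

  expect_equal(nrow(extend_candidates(pl, rbind(c(1L, 2L)), l = 2)), 2L)
  expect_warning(out <- extend_candidates(pl, matrix(integer(0), 0, 2)),
                 "empty seed")
  expect_equal(nrow(out), 0L)
})

test_that("least-possible-significant flag follows its definition", {
  subs <- c(`3` = 1e-6, `7` = 1e-6)
  expect_true(is_least_possible_significant(c(3, 7), 1e-12, 3e-9, subs))
  # a subset more significant than the module: redundant
  expect_false(is_least_possible_significant(
    c(3, 7), 1e-12, 3e-9, c(`3` = 1e-13, `7` = 1e-6)))
  # not significant at the threshold
  expect_false(is_least_possible_significant(c(3, 7), 1e-6, 3e-9, subs))
  # strictness: equality with a subset p does not pass
  expect_false(is_least_possible_significant(
    c(3, 7), 1e-6, 1e-3, c(`3` = 1e-6, `7` = 1)))
  expect_error(
    is_least_possible_significant(c(3, 7, 9), 1e-12, 3e-9, subs),
    "3,7")
})

test_that("the top pair always survives list management", {
  set.seed(55)
  M <- 30
  d <- genotype_matrix(matrix(rbinom(200 * M, 2, 0.25), 200, M),
                       rep(c(1L, 0L), 100))
  pl <- encode_bitplanes(d)
  top1 <- exhaustive_pair_scan(pl, l = 1)
  # full enumeration through the module-level API
  all_p <- vapply(combn(M, 2, simplify = FALSE), function(pr) {
    dynamic_cluster(count_contingency(pl, pr))$p_unadjusted
  }, numeric(1))
  expect_equal(top1$p[1], min(all_p))
})

test_that("interleaved partitioning covers all SNPs evenly", {
  expect_equal(partition_snps(7, 3),
               list(c(1L, 4L, 7L), c(2L, 5L), c(3L, 6L)))
  expect_equal(partition_snps(5, 1), list(1:5))
  parts <- partition_snps(100, 7)
  expect_equal(sort(unlist(parts)), 1:100)
  expect_lte(diff(range(lengths(parts))), 1L)
  expect_error(partition_snps(10, 0), "positive")
  expect_error(partition_snps(3, 4), "exceed")
})

test_that("serial and partitioned searches return identical results", {
  d <- embed_4b_dataset(n_null = 20, seed = 3)
  fit1 <- dche(d, t_max = 3, top = c(30, 10))
  fit4 <- dche(d, t_max = 3, top = c(30, 10), partitions = 4)
  expect_identical(fit1$results, fit4$results)
})

test_that("search wiring: thresholds, flags and configuration errors", {
  d <- embed_4b_dataset()
  fit <- dche(d, t_max = 2, top = 5,
              policy = dche_policy(alpha0 = c(`2` = 1.5e-3)))
  r2 <- fit$results[["2"]]
  expect_equal(r2$snps[1], "1,2")
  expect_equal(r2$threshold[1], 1.5e-3 / choose(10, 2))
  expect_equal(r2$p_adjusted, pmin(1, r2$p_unadjusted * choose(10, 2)))
  expect_equal(r2$significant, r2$p_unadjusted <= r2$threshold)
  expect_true(r2$significant[1])
  expect_equal(r2$d[1], 3L)
  expect_equal(r2$grouping[1], "0,1,2,3,6;4;5,7,8")

  expect_error(dche(d, t_max = 5), "2 to 4")
  expect_error(dche_config(t_max = 5), "2 to 4")

  s <- summary(fit)
  expect_equal(s$candidates, 5L)
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 5L)
  expect_equal(df$order[1], 2L)
})
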