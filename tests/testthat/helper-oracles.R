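# Shared fixtures and independent oracles for the test suite.

# The two worked-example 2 x 9 contingency tables (cases on top).
tab4a <- rbind(c(71, 97, 44, 89, 184, 93, 29, 113, 80),
               c(108, 151, 47, 138, 184, 55, 43, 57, 17))
tab4b <- rbind(c(40, 49, 13, 43, 110, 49, 16, 50, 30),
               c(55, 76, 21, 62, 103, 22, 24, 27, 10))

# Nested-loop contingency counting oracle, independent of the bitwise path.
oracle_count <- function(geno, pheno, snps) {
  t <- length(snps)
  cc <- integer(3L^t)
  tc <- integer(3L^t)
  for (r in seq_len(nrow(geno))) {
    g <- geno[r, snps]
    if (any(g == 3L)) next
    cell <- sum(g * 3L^((t - 1L):0L)) + 1L
    if (pheno[r] == 1L) cc[cell] <- cc[cell] + 1L else tc[cell] <- tc[cell] + 1L
  }
  rbind(cc, tc)
}

# Exhaustive minimum p over all partitions of the non-empty cells of a 2 x 9
# table into 3 groups (every cell-to-label assignment; label permutations are
# harmless duplicates). Brute force, used only as a test oracle.
oracle_assignments <- as.matrix(expand.grid(rep(list(0:2), 9)))

oracle_partition_min_p <- function(cc, tc) {
  ne <- which(cc + tc > 0)
  A <- oracle_assignments[, ne, drop = FALSE]
  BC <- matrix(0, nrow(A), 3)
  BT <- matrix(0, nrow(A), 3)
  for (k in 1:3) {
    Ik <- (A == (k - 1L))
    BC[, k] <- Ik %*% cc[ne]
    BT[, k] <- Ik %*% tc[ne]
  }
  ok <- (BC[, 1] + BT[, 1] > 0) & (BC[, 2] + BT[, 2] > 0) &
    (BC[, 3] + BT[, 3] > 0)
  BC <- BC[ok, , drop = FALSE]
  BT <- BT[ok, , drop = FALSE]
  R1 <- rowSums(BC)
  R2 <- rowSums(BT)
  n <- R1 + R2
  stat <- numeric(nrow(BC))
  for (k in 1:3) {
    col <- BC[, k] + BT[, k]
    e1 <- R1 * col / n
    e2 <- R2 * col / n
    stat <- stat + (BC[, k] - e1)^2 / e1 + (BT[, k] - e2)^2 / e2
  }
  min(stats::pchisq(stat, 2, lower.tail = FALSE))
}

# random 2 x 9 table with >= 3 non-empty cells and both rows positive
random_small_table <- function() {
  repeat {
    cc <- sample(0:30, 9, replace = TRUE)
    tc <- sample(0:30, 9, replace = TRUE)
    if (sum(cc + tc > 0) >= 3 && sum(cc) > 0 && sum(tc) > 0)
      return(rbind(cc, tc))
  }
}

# block list (0-based labels) as a canonical set of sets for comparisons
block_sets <- function(blocks) {
  s <- lapply(blocks, function(b) sort(as.integer(b)))
  s[order(vapply(s, min, integer(1)))]
}
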