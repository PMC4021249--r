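test_that("odds/penetrance conversions are exact inverses", {
  expect_equal(odds_to_penetrance(1), 0.5)
  expect_equal(odds_to_penetrance(0), 0)
  expect_equal(penetrance_to_odds(0.5), 1)
  expect_equal(penetrance_to_odds(0.9), 9)
  expect_equal(penetrance_to_odds(0), 0)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(odds_to_penetrance(penetrance_to_odds(p)), p)
  expect_error(penetrance_to_odds(1), "infinite")
  expect_error(odds_to_penetrance(-0.1), "non-negative")
})

test_that("genotype prior is the Hardy-Weinberg product", {
  expect_equal(genotype_prior(0.5), c(0.25, 0.5, 0.25))
  p2 <- genotype_prior(c(0.5, 0.5))
  expect_equal(sum(p2), 1)
  expect_equal(p2[5L], 0.25)  # centre cell (Aa, Bb)
  # t = 3 against brute-force enumeration of the 27 products
  maf <- c(0.1, 0.3, 0.5)
  per_locus <- lapply(maf, function(m) c((1 - m)^2, 2 * m * (1 - m), m^2))
  brute <- numeric(27)
  for (c1 in 0:2) for (c2 in 0:2) for (c3 in 0:2) {
    brute[c1 * 9 + c2 * 3 + c3 + 1] <-
      per_locus[[1]][c1 + 1] * per_locus[[2]][c2 + 1] * per_locus[[3]][c3 + 1]
  }
  expect_equal(genotype_prior(maf), brute)
  for (t in 1:4) {
    expect_equal(sum(genotype_prior(rep(0.2, t))), 1)
  }
})

test_that("prevalence and heritability match hand substitution", {
  const <- disease_model(c(0.3, 0.3), rep(0.07, 9))
  expect_equal(model_prevalence(const), 0.07)
  expect_equal(model_heritability(const), 0)

  # t = 1, MAF 0.5, penetrances (0, 0, 1): p(D) = 0.25 and
  # h2 = (0.0625*0.25 + 0.0625*0.5 + 0.5625*0.25) / (0.25*0.75) = 1
  toy <- disease_model(0.5, c(0, 0, 1))
  expect_equal(model_prevalence(toy), 0.25)
  expect_equal(model_heritability(toy), 1)
})

test_that("multiplicative and additive odds tables have the stated shape", {
  expect_equal(multiplicative_odds_table(0.3, 0), rep(0.3, 9))
  m <- multiplicative_odds_table(1, 1)
  expect_equal(m[c(5, 6, 8, 9)], c(2, 4, 4, 16))
  expect_equal(m[-c(5, 6, 8, 9)], rep(1, 5))
  expect_equal(length(unique(m)), 4L)  # four penetrance classes

  a <- additive_odds_table(1, 1)
  g <- expand.grid(g2 = 0:2, g1 = 0:2)
  expect_equal(a, 2^(g$g1 + g$g2))
  expect_equal(additive_odds_table(0.2, 0), rep(0.2, 9))
})

test_that("effect-parameter solver recovers prevalence and heritability", {
  # no effect: alpha is the baseline odds of the prevalence
  z <- solve_effect_params("multiplicative", 0.1, 0, c(0.2, 0.2))
  expect_equal(z$effect, 0)
  expect_equal(z$alpha, 0.1 / 0.9)

  for (case in list(list(fam = "multiplicative", maf = 0.1),
                    list(fam = "additive", maf = 0.4))) {
    s <- solve_effect_params(case$fam, target_prevalence = 0.1,
                             target_h2 = 0.03, maf = rep(case$maf, 2))
    expect_lt(abs(model_prevalence(s$model) - 0.1), 1e-8)
    expect_lt(abs(model_heritability(s$model) - 0.03), 1e-8)
    expect_gt(s$effect, 0)
  }

  expect_error(solve_effect_params("multiplicative", 0.1, 50, c(0.05, 0.05)),
               "not attainable")
})

test_that("dataset generation is reproducible and samples the model", {
  spec <- simulation_spec(M = 30, N = 100, seed = 12)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$data$genotypes, b$data$genotypes)
  expect_null(a$ground_truth)
  expect_equal(sum(a$data$phenotypes == 1L), 50L)
  expect_error(simulation_spec(M = 10, N = 101), "even")

  # empirical case-genotype frequencies at the disease loci match the
  # retrospective law P(g|case) within sampling error
  solved <- solve_effect_params("multiplicative", 0.1, 0.03, c(0.4, 0.4))
  model <- solved$model
  prior <- genotype_prior(model$maf)
  pd <- model_prevalence(model)
  p_case <- model$penetrance * prior / pd
  sim <- generate_dataset(simulation_spec(M = 10, N = 8000, model = model,
                                          disease_loci = c(2L, 9L),
                                          seed = 99))
  expect_equal(sim$ground_truth, c(2L, 9L))
  cases <- sim$data$genotypes[sim$data$phenotypes == 1L, ]
  cells <- cases[, 2L] * 3L + cases[, 9L]
  freq <- tabulate(cells + 1L, nbins = 9L) / nrow(cases)
  se <- sqrt(p_case * (1 - p_case) / nrow(cases))
  expect_true(all(abs(freq - p_case) <= 4 * se))

  # goodness-of-fit of disease-locus genotypes across seeds: at level 0.001
  # essentially no rejections are expected over 20 seeds
  p_ctrl <- (1 - model$penetrance) * prior / (1 - pd)
  rejects <- 0L
  for (s in 1:20) {
    sm <- generate_dataset(simulation_spec(M = 4, N = 2000, model = model,
                                           disease_loci = c(1L, 2L),
                                           seed = 1000 + s))
    for (grp in 0:1) {
      rows <- sm$data$genotypes[sm$data$phenotypes == grp, ]
      cells <- rows[, 1L] * 3L + rows[, 2L]
      obs <- tabulate(cells + 1L, nbins = 9L)
      pr <- if (grp == 1L) p_case else p_ctrl
      pv <- suppressWarnings(chisq.test(obs, p = pr)$p.value)
      if (pv < 0.001) rejects <- rejects + 1L
    }
  }
  expect_lte(rejects, 1L)
})
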