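#' Odds / penetrance conversions
#'
#' A disease model can be specified per genotype combination either by its
#' penetrance `p(D|g)` or by its odds `ODD(g) = p(D|g) / (1 - p(D|g))`;
#' the two are related cell-wise by `p = ODD / (1 + ODD)`.
#'
#' @param odds non-negative odds value(s).
#' @return `odds_to_penetrance`: penetrance in `[0, 1)`.
#' @export
odds_to_penetrance <- function(odds) {
  if (any(odds < 0)) stop("odds must be non-negative")
  odds / (1 + odds)
}

#' @rdname odds_to_penetrance
#' @param p penetrance value(s) in `[0, 1)`.
#' @return `penetrance_to_odds`: non-negative odds.
#' @export
penetrance_to_odds <- function(p) {
  if (any(p < 0) || any(p >= 1))
    stop("penetrance must be in [0, 1); p = 1 gives infinite odds")
  p / (1 - p)
}

#' Hardy-Weinberg genotype-combination prior
#'
#' Joint probability of each of the `3^t` genotype combinations of `t`
#' unlinked loci under Hardy-Weinberg equilibrium: the product over loci of
#' `((1-m)^2, 2m(1-m), m^2)`. Cells are ordered mixed-radix base 3 with the
#' first locus as the most significant digit, matching
#' [count_contingency()].
#'
#' @param maf vector of minor allele frequencies, one per locus.
#' @return probability vector of length `3^length(maf)`.
#' @export
genotype_prior <- function(maf) {
  stopifnot(all(maf > 0), all(maf <= 0.5))
  as.numeric(Reduce(kronecker,
                    lapply(maf, function(m) c((1 - m)^2, 2 * m * (1 - m), m^2))))
}

#' Construct a disease model
#'
#' A `t`-locus disease model: a penetrance or odds table over the `3^t`
#' genotype combinations plus the minor allele frequencies of the disease
#' loci. Prevalence and heritability are derived quantities (see
#' [model_prevalence()] and [model_heritability()]).
#'
#' @param maf minor allele frequencies of the `t` disease loci.
#' @param table numeric vector of length `3^t`, mixed-radix cell order.
#' @param table_kind `"penetrance"` or `"odds"`.
#' @return An object of class `dche_model` with elements `maf`, `t`,
#'   `penetrance`, `odds`.
#' @export
disease_model <- function(maf, table, table_kind = c("penetrance", "odds")) {
  table_kind <- match.arg(table_kind)
  t <- length(maf)
  if (length(table) != 3L^t)
    stop("table must have 3^t = ", 3L^t, " cells")
  if (table_kind == "odds") {
    odds <- as.numeric(table)
    pen <- odds_to_penetrance(odds)
  } else {
    pen <- as.numeric(table)
    if (any(pen < 0) || any(pen > 1)) stop("penetrance must be in [0, 1]")
    odds <- ifelse(pen < 1, pen / (1 - pen), Inf)
  }
  structure(list(maf = as.numeric(maf), t = t, penetrance = pen, odds = odds),
            class = "dche_model")
}

#' @export
print.dche_model <- function(x, ...) {
  cat(x$t, "-locus disease model, MAF = ", paste(x$maf, collapse = ", "),
      "\n", sep = "")
  cat("prevalence p(D) =", format(model_prevalence(x), digits = 4),
      " heritability h2 =", format(model_heritability(x), digits = 4), "\n")
  invisible(x)
}

#' Disease prevalence of a model
#'
#' `p(D) = sum_i p(D|g_i) p(g_i)` with `p(g_i)` the Hardy-Weinberg prior of
#' the genotype combination.
#'
#' @param model a [disease_model()].
#' @return Prevalence in `[0, 1]`.
#' @export
model_prevalence <- function(model) {
  stopifnot(inherits(model, "dche_model"))
  sum(model$penetrance * genotype_prior(model$maf))
}

#' Heritability of a model
#'
#' `h2 = sum_i (p(D|g_i) - p(D))^2 p(g_i) / (p(D) (1 - p(D)))`: the variance
#' of the penetrance across genotype combinations relative to the phenotypic
#' variance.
#'
#' @param model a [disease_model()].
#' @return Non-negative heritability.
#' @export
model_heritability <- function(model) {
  stopifnot(inherits(model, "dche_model"))
  prior <- genotype_prior(model$maf)
  pd <- sum(model$penetrance * prior)
  if (pd <= 0 || pd >= 1) stop("prevalence must be strictly inside (0, 1)")
  sum((model$penetrance - pd)^2 * prior) / (pd * (1 - pd))
}

#' Two-locus multiplicative-effect odds table
#'
#' Baseline odds `alpha` everywhere except the four doubly-variant cells:
#' `(Aa,Bb) = alpha(1+theta)`, `(Aa,bb) = (aa,Bb) = alpha(1+theta)^2`,
#' `(aa,bb) = alpha(1+theta)^4`. The table has exactly four distinct odds
#' values when `theta != 0`, i.e. four latent penetrance classes.
#'
#' @param alpha baseline odds (> 0).
#' @param theta multiplicative effect (> -1).
#' @return length-9 odds vector in mixed-radix cell order.
#' @export
multiplicative_odds_table <- function(alpha, theta) {
  stopifnot(alpha > 0, theta > -1)
  w <- rep(1, 9)
  w[5L] <- (1 + theta)      # cell (1,1), index 4
  w[6L] <- (1 + theta)^2    # cell (1,2), index 5
  w[8L] <- (1 + theta)^2    # cell (2,1), index 7
  w[9L] <- (1 + theta)^4    # cell (2,2), index 8
  alpha * w
}

#' Two-locus additive-effect odds table
#'
#' Odds accumulate per copy of a minor allele at either locus:
#' `odds(g1, g2) = alpha (1 + beta)^(g1 + g2)`.
#'
#' @param alpha baseline odds (> 0).
#' @param beta per-allele effect (> -1).
#' @return length-9 odds vector in mixed-radix cell order.
#' @export
additive_odds_table <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > -1)
  g <- expand.grid(g2 = 0:2, g1 = 0:2)  # g1 most significant digit
  alpha * (1 + beta)^(g$g1 + g$g2)
}

#' Solve effect parameters from prevalence and heritability
#'
#' Given a model family, target prevalence and heritability, and the MAFs of
#' the disease loci, finds `(alpha, theta)` (multiplicative) or
#' `(alpha, beta)` (additive) such that the model reproduces both targets.
#' The odds table scales as `alpha * w(theta)`, so `alpha` is solved from
#' the prevalence constraint by inner root-finding at each candidate
#' `theta`, and `theta` by outer root-finding on the heritability; both
#' residuals are driven below `tol`.
#'
#' @param model_family `"multiplicative"` or `"additive"`.
#' @param target_prevalence desired `p(D)` in (0, 1).
#' @param target_h2 desired heritability (>= 0).
#' @param maf minor allele frequencies of the two disease loci.
#' @param tol convergence tolerance on the targets (default 1e-10).
#' @return list with `alpha`, `effect` (theta or beta), and the realised
#'   `model` ([disease_model()]).
#' @export
solve_effect_params <- function(model_family = c("multiplicative", "additive"),
                                target_prevalence, target_h2, maf,
                                tol = 1e-10) {
  model_family <- match.arg(model_family)
  stopifnot(target_prevalence > 0, target_prevalence < 1, target_h2 >= 0,
            length(maf) == 2L)
  make_table <- switch(model_family,
                       multiplicative = multiplicative_odds_table,
                       additive = additive_odds_table)
  prior <- genotype_prior(maf)
  build <- function(alpha, effect) {
    disease_model(maf, make_table(alpha, effect), table_kind = "odds")
  }
  solve_alpha <- function(effect) {
    # prevalence is strictly increasing in alpha; bracket then uniroot
    f <- function(a) sum(odds_to_penetrance(make_table(a, effect)) * prior) -
      target_prevalence
    lo <- 1e-12; hi <- 1
    while (f(hi) < 0) hi <- hi * 2
    stats::uniroot(f, c(lo, hi), tol = tol)$root
  }
  if (target_h2 == 0) {
    alpha <- penetrance_to_odds(target_prevalence)
    return(list(alpha = alpha, effect = 0, model = build(alpha, 0)))
  }
  h2_at <- function(effect) {
    m <- build(solve_alpha(effect), effect)
    model_heritability(m) - target_h2
  }
  lo <- 0; hi <- 0.5
  while (h2_at(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e6) stop("target heritability not attainable at these MAFs; ",
                       "maximum attainable h2 is below the target")
  }
  effect <- stats::uniroot(h2_at, c(lo, hi), tol = tol)$root
  alpha <- solve_alpha(effect)
  list(alpha = alpha, effect = effect, model = build(alpha, effect))
}

#' Simulation specification
#'
#' Describes one simulated case-control dataset: `M` SNPs, `N` individuals
#' split evenly into cases and controls, optionally one embedded
#' ground-truth interaction at `disease_loci` drawn from a
#' [disease_model()]. Unassociated SNPs are sampled under Hardy-Weinberg
#' equilibrium with per-SNP MAF drawn uniformly from `maf_range`.
#'
#' @param M number of SNPs.
#' @param N number of individuals (even; N/2 cases and N/2 controls).
#' @param model a [disease_model()], or NULL for a pure null dataset.
#' @param disease_loci indices (1-based) where the model's loci are placed.
#' @param maf_range range of the uniform MAF distribution for null SNPs.
#' @param seed integer seed; the dataset is reproducible from it.
#' @return An object of class `dche_simspec`.
#' @export
simulation_spec <- function(M, N, model = NULL, disease_loci = NULL,
                            maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(M >= 1, N >= 2)
  if (N %% 2 != 0) stop("N must be even for balanced case/control sampling")
  if (!is.null(model)) {
    stopifnot(inherits(model, "dche_model"))
    if (is.null(disease_loci)) disease_loci <- seq_len(model$t)
    disease_loci <- as.integer(disease_loci)
    stopifnot(length(disease_loci) == model$t,
              !anyDuplicated(disease_loci),
              all(disease_loci >= 1L), all(disease_loci <= M))
  }
  structure(list(M = as.integer(M), N = as.integer(N), model = model,
                 disease_loci = disease_loci,
                 maf_range = as.numeric(maf_range), seed = seed),
            class = "dche_simspec")
}

#' Generate a simulated case-control dataset
#'
#' Null SNPs are drawn i.i.d. per individual as Binomial(2, MAF) minor
#' allele counts (Hardy-Weinberg sampling). When a model is present, the
#' genotype combinations at the disease loci are drawn retrospectively:
#' case rows from `P(g|case) = p(D|g) p(g) / p(D)` and control rows from
#' `P(g|control) = (1 - p(D|g)) p(g) / (1 - p(D))`. Cases occupy the first
#' N/2 rows.
#'
#' @param spec a [simulation_spec()].
#' @return list with `data` (a [genotype_matrix()]) and `ground_truth`
#'   (the disease locus indices, or NULL for a null dataset).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dche_simspec"))
  set.seed(spec$seed)
  M <- spec$M; N <- spec$N
  n_case <- N %/% 2L
  maf <- stats::runif(M, spec$maf_range[1L], spec$maf_range[2L])
  geno <- matrix(stats::rbinom(N * M, 2L, rep(maf, each = N)), N, M)
  pheno <- rep(c(1L, 0L), c(n_case, N - n_case))
  if (!is.null(spec$model)) {
    model <- spec$model
    prior <- genotype_prior(model$maf)
    pd <- sum(model$penetrance * prior)
    if (pd <= 0 || pd >= 1) stop("model prevalence must be inside (0, 1)")
    p_case <- model$penetrance * prior / pd
    p_ctrl <- (1 - model$penetrance) * prior / (1 - pd)
    ncell <- 3L^model$t
    cells_case <- sample.int(ncell, n_case, replace = TRUE, prob = p_case)
    cells_ctrl <- sample.int(ncell, N - n_case, replace = TRUE, prob = p_ctrl)
    cells <- c(cells_case, cells_ctrl) - 1L
    for (k in seq_len(model$t)) {
      digit <- (cells %/% 3L^(model$t - k)) %% 3L
      geno[, spec$disease_loci[k]] <- digit
    }
  }
  list(data = genotype_matrix(geno, pheno),
       ground_truth = spec$disease_loci)
}
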