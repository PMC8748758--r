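make_weights <- function(panel, beta, p = NULL, eaf = NULL,
                         effect = NULL) {
  m <- nrow(panel$map)
  as_sumstats(data.frame(
    variant_id = panel$map$variant_id, chromosome = panel$map$chromosome,
    position = panel$map$position,
    effect_allele = if (is.null(effect)) panel$map$counted_allele else effect,
    other_allele = ifelse((if (is.null(effect)) panel$map$counted_allele
                           else effect) == "A", "G", "A"),
    beta = beta, se = 0.02,
    p_value = if (is.null(p)) rep(0.01, m) else p,
    eaf = if (is.null(eaf)) rep(NA_real_, m) else eaf, n = 10000))
}

test_that("compute_scores reproduces the dosage-weight matrix product", {
  panel <- toy_panel(n_ind = 5, n_var = 3, seed = 2)
  beta <- c(0.5, -0.2, 0.1)
  sc <- compute_scores(panel, make_weights(panel, beta))
  expect_equal(sc$raw, unname(drop(panel$dosage %*% beta)))
  expect_equal(mean(sc$score), 0, tolerance = 1e-12)
  expect_equal(sd(sc$score), 1, tolerance = 1e-12)
  expect_equal(attr(sc, "n_variants_used"), 3L)

  # single variant, beta = 1: raw scores are the dosages
  p1 <- genotype_panel(matrix(c(0, 1, 2), ncol = 1),
                       data.frame(variant_id = "v1", chromosome = "1",
                                  position = 100L, counted_allele = "A"))
  expect_equal(compute_scores(p1, make_weights(p1, 1))$raw, c(0, 1, 2))

  expect_error(compute_scores(panel, make_weights(panel, c(0, 0, 0))),
               "zero-variance")
  expect_error(compute_scores(panel, make_weights(panel, beta),
                              p_threshold = 1e-10), "zero variants")
})

test_that("scoring is invariant to allele coding flips and p-thresholds filter", {
  panel <- toy_panel(n_ind = 50, n_var = 4, seed = 3)
  beta <- c(0.3, -0.1, 0.2, 0.05)
  base <- compute_scores(panel, make_weights(panel, beta))
  # recode variant 2: weights name the panel's other allele
  eff <- panel$map$counted_allele
  eff[2] <- "G"
  beta_flip <- beta; beta_flip[2] <- -beta[2]
  flipped <- compute_scores(panel, make_weights(panel, beta_flip,
                                                effect = eff))
  # raw scores shift by the constant 2*beta of the recoded variant;
  # standardized scores are exactly invariant
  expect_equal(flipped$raw - base$raw,
               rep(-2 * beta[2], nrow(base)), tolerance = 1e-12)
  expect_equal(flipped$score, base$score, tolerance = 1e-12)

  w <- make_weights(panel, beta, p = c(1e-9, 0.5, 1e-9, 0.5))
  sc <- compute_scores(panel, w, p_threshold = 1e-4)
  expect_equal(attr(sc, "n_variants_used"), 2L)
  expect_equal(sc$raw, unname(drop(panel$dosage[, c(1, 3)] %*% beta[c(1, 3)])))
})

test_that("missing dosages impute as 2*eaf (or cohort mean)", {
  dose <- matrix(c(0, 1, 2, NA, 1, 1, 0, 2), ncol = 2)
  panel <- genotype_panel(dose, data.frame(
    variant_id = c("a", "b"), chromosome = "1", position = c(1L, 2L) * 100L,
    counted_allele = "A"))
  w <- make_weights(panel, c(1, 0.5), eaf = c(0.25, NA))
  sc <- compute_scores(panel, w)
  manual <- dose
  manual[4, 1] <- 2 * 0.25
  expect_equal(sc$raw, unname(drop(manual %*% c(1, 0.5))))
})

test_that("nagelkerke_delta_r2 matches a likelihood-based oracle", {
  set.seed(11)
  n <- 200
  x <- rnorm(n)
  cov1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x + 0.4 * cov1))
  res <- nagelkerke_delta_r2(y, x, data.frame(cov1 = cov1))

  ll0 <- oracle_logistic_loglik(y, NULL)
  ll_red <- oracle_logistic_loglik(y, cbind(cov1))
  ll_full <- oracle_logistic_loglik(y, cbind(cov1, x))
  r2 <- function(ll) (1 - exp(2 / n * (ll0 - ll))) / (1 - exp(2 / n * ll0))
  expect_equal(res$delta_r2, r2(ll_full) - r2(ll_red), tolerance = 1e-8)
  expect_gt(res$delta_r2, 0)
  expect_lt(res$p, 0.05)

  # constant or zero score contributes nothing
  expect_equal(nagelkerke_delta_r2(y, rep(1, n))$delta_r2, 0)
  expect_equal(nagelkerke_delta_r2(y, rep(0, n))$delta_r2, 0)
  # affine rescaling leaves delta R2 unchanged
  res2 <- nagelkerke_delta_r2(y, 3 * x - 7, data.frame(cov1 = cov1))
  expect_equal(res2$delta_r2, res$delta_r2, tolerance = 1e-10)
  # separation is flagged, not silently fitted
  expect_error(suppressWarnings(nagelkerke_delta_r2(as.numeric(x > 0), x)),
               "converge|separation")
})

test_that("observed_to_liability obeys its closed-form contracts", {
  expect_equal(observed_to_liability(0, 0.01, 0.5), 0)
  expect_equal(observed_to_liability(0, 0.37, 0.2), 0)
  expect_lt(observed_to_liability(0.01, 0.01, 0.5),
            observed_to_liability(0.02, 0.01, 0.5))
  # P = K reduces to the unascertained scaling K(1-K)/z^2
  K <- 0.08
  z <- dnorm(qnorm(1 - K))
  expect_equal(observed_to_liability(0.1, K, K), 0.1 * K * (1 - K) / z^2,
               tolerance = 1e-12)
  expect_error(observed_to_liability(0.1, 0, 0.5), "K and P")
  expect_error(observed_to_liability(0.1, 0.01, 1), "K and P")
  expect_error(observed_to_liability(1, 0.01, 0.5), "r2_obs")
})

test_that("liability conversion recovers the simulated liability variance", {
  # liability-threshold world with known liability R2 = v; the observed
  # (linear 0/1) R2 in an ascertained 50/50 sample converts back to ~v
  set.seed(202)
  v <- 0.05; K <- 0.1
  N <- 4e5
  g <- rnorm(N, 0, sqrt(v))
  liab <- g + rnorm(N, 0, sqrt(1 - v))
  case <- as.integer(liab > qnorm(1 - K))
  idx <- c(sample(which(case == 1), 3000), sample(which(case == 0), 3000))
  r2_obs <- cor(g[idx], case[idx])^2
  est <- observed_to_liability(r2_obs, K, 0.5)
  expect_equal(est, v, tolerance = 0.2)  # Monte-Carlo + approximation slack
})

test_that("bootstrap_r2_ci is seeded-reproducible and degenerates sanely", {
  set.seed(5)
  n <- 150
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * x))
  a <- bootstrap_r2_ci(y, x, n_boot = 30, seed = 7)
  b <- bootstrap_r2_ci(y, x, n_boot = 30, seed = 7)
  expect_identical(a$ci, b$ci)
  expect_identical(a$boot, b$boot)
  expect_true(a$ci[1] <= a$estimate && a$estimate <= a$ci[2])
  expect_warning(d <- bootstrap_r2_ci(y, x, n_boot = 1, seed = 1), "n_boot")
  expect_equal(d$ci, rep(d$estimate, 2))
})

test_that("null-score bootstrap CIs cover zero at roughly nominal rate", {
  set.seed(31)
  hits <- 0
  n_sim <- 30
  for (s in seq_len(n_sim)) {
    n <- 120
    y <- rbinom(n, 1, 0.5)
    x <- rnorm(n)  # unrelated score
    ci <- bootstrap_r2_ci(y, x, n_boot = 60, seed = s)$ci
    if (ci[1] <= 0 && 0 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.8)
})

test_that("decile ORs: reference is 1, covariate-free ORs equal ad/bc", {
  set.seed(9)
  n <- 400
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * score))
  res <- decile_or_analysis(score, y)
  expect_equal(nrow(res), 10)
  expect_equal(res$or[res$decile == 5], 1)

  ord <- order(score, seq_len(n))
  decile <- integer(n); decile[ord] <- rep(1:10, each = 40)
  for (d in c(1, 10)) {
    a <- sum(y[decile == d] == 1); b <- sum(y[decile == d] == 0)
    c_ <- sum(y[decile == 5] == 1); d_ <- sum(y[decile == 5] == 0)
    expect_equal(res$or[res$decile == d], (a * d_) / (b * c_),
                 tolerance = 1e-6)
  }
  expect_error(decile_or_analysis(rnorm(50), rbinom(50, 1, 0.5)), ">= 10")
})

test_that("null scores yield no FDR-significant decile contrasts in most sims", {
  set.seed(77)
  bad <- 0
  n_sim <- 15
  for (s in seq_len(n_sim)) {
    n <- 300
    y <- rbinom(n, 1, 0.5)
    res <- decile_or_analysis(rnorm(n), y)
    p <- res$p[!is.na(res$p)]
    if (length(p) && any(bh_fdr(p) < 0.05)) bad <- bad + 1
  }
  expect_lte(bad, 2)
})

test_that("sex_bootstrap_compare returns calibrated structure and K-sensitivity", {
  set.seed(13)
  n <- 600
  sex <- rep(c("male", "female"), each = n / 2)
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.6 * score))
  covs <- data.frame(age = rnorm(n, 40, 10))
  res <- sex_bootstrap_compare(list(CONC = score), y, covs, sex,
                               n_boot = 40, n_case = 80, n_control = 80,
                               seed = 42)
  expect_named(res, "CONC")
  expect_equal(dim(res$CONC$boot), c(40, 2))
  expect_true(is.finite(res$CONC$p))

  # bootstrap mean tracks the stratum point estimate (consistency)
  males <- sex == "male"
  full <- nagelkerke_delta_r2(y[males], score[males],
                              covs[males, , drop = FALSE])$delta_r2
  full_liab <- observed_to_liability(full, 0.01, 0.5)
  expect_equal(unname(res$CONC$mean["male"]), full_liab,
               tolerance = 0.5 * full_liab + 0.02)

  # sex-specific prevalences change values, not the direction of the gap
  res2 <- sex_bootstrap_compare(list(CONC = score), y, covs, sex,
                                n_boot = 40, n_case = 80, n_control = 80,
                                K_by_sex = c(male = 0.0079, female = 0.0045),
                                seed = 42)
  gap1 <- res$CONC$mean["male"] - res$CONC$mean["female"]
  gap2 <- res2$CONC$mean["male"] - res2$CONC$mean["female"]
  expect_equal(sign(gap1), sign(gap2))

  expect_error(sex_bootstrap_compare(list(s = score), y, covs,
                                     rep("male", n), n_boot = 5),
               "both sex strata")
})
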