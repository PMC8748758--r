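make_instr <- function(be, bo, se_e = 0.02, se_o = 0.05) {
  structure(data.frame(variant_id = paste0("i", seq_along(be)),
                       beta_exposure = be, se_exposure = se_e,
                       beta_outcome = bo, se_outcome = se_o,
                       wald_ratio = bo / be, wald_se = se_o / abs(be),
                       stringsAsFactors = FALSE),
            class = c("instrument_set", "data.frame"))
}

test_that("IVW: Wald collapse, exact line, weighted-ratio identity", {
  one <- make_instr(0.2, 0.1)
  f1 <- ivw_estimate(one)
  expect_equal(f1$method, "WaldRatio")
  expect_equal(f1$beta, 0.5)

  line <- make_instr(c(0.1, 0.2, 0.3), c(0.2, 0.4, 0.6))
  f2 <- ivw_estimate(line)
  expect_equal(f2$beta, 2, tolerance = 1e-12)
  expect_equal(heterogeneity_diagnostics(line, f2)$Q, 0, tolerance = 1e-20)

  # IVW slope == inverse-variance-weighted mean of Wald ratios, always
  set.seed(3)
  instr <- make_instr(runif(8, 0.05, 0.3), rnorm(8, 0.1, 0.1),
                      se_o = runif(8, 0.02, 0.1))
  f3 <- ivw_estimate(instr)
  wm <- sum(instr$wald_ratio / instr$wald_se^2) / sum(1 / instr$wald_se^2)
  expect_equal(f3$beta, wm, tolerance = 1e-10)

  # equal weights and exposures: estimate is the mean of the two ratios
  two <- make_instr(c(0.2, 0.2), c(0.1, 0.3))
  expect_equal(ivw_estimate(two)$beta, mean(two$wald_ratio),
               tolerance = 1e-12)
})

test_that("Egger matches the weighted normal-equations oracle; shift moves intercept", {
  set.seed(7)
  instr <- make_instr(runif(5, 0.1, 0.4), rnorm(5, 0.2, 0.1),
                      se_o = runif(5, 0.03, 0.08))
  fit <- egger_estimate(instr)
  o <- lm(beta_outcome ~ beta_exposure, data = instr,
          weights = 1 / se_outcome^2)
  expect_equal(fit$beta, unname(coef(o)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(o)[1]), tolerance = 1e-10)
  so <- summary(o)
  floor_fac <- sqrt(max(1, so$sigma^2) / so$sigma^2)
  expect_equal(fit$se, unname(so$coefficients[2, 2]) * floor_fac,
               tolerance = 1e-8)

  shifted <- instr
  shifted$beta_outcome <- instr$beta_outcome + 0.5
  shifted$wald_ratio <- shifted$beta_outcome / shifted$beta_exposure
  fit2 <- egger_estimate(shifted)
  expect_equal(fit2$intercept, fit$intercept + 0.5, tolerance = 1e-10)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-10)

  line <- make_instr(c(0.1, 0.2, 0.3), c(0.2, 0.4, 0.6))
  fl <- egger_estimate(line)
  expect_equal(fl$beta, ivw_estimate(line)$beta, tolerance = 1e-10)
  expect_equal(fl$intercept, 0, tolerance = 1e-12)
  expect_error(egger_estimate(make_instr(c(0.1, 0.2), c(0.1, 0.2))),
               "at least 3")
})

test_that("weighted median: plain median, constants, interpolation oracle", {
  eq <- make_instr(rep(0.2, 5), c(0.02, 0.04, 0.06, 0.08, 0.10))
  f <- weighted_median_estimate(eq, n_boot = 50, seed = 1)
  expect_equal(f$beta, median(eq$wald_ratio), tolerance = 1e-12)

  const <- make_instr(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.3, 0.4) * 1.5,
                      se_o = c(0.02, 0.07, 0.03, 0.05))
  expect_equal(weighted_median_estimate(const, n_boot = 20, seed = 1)$beta,
               1.5, tolerance = 1e-12)

  # brute-force cumulative-weight interpolation oracle
  instr <- make_instr(c(0.2, 0.25, 0.5, 0.4), c(0.1, 0.05, 0.4, 0.08),
                      se_o = c(0.03, 0.06, 0.04, 0.05))
  w <- 1 / instr$wald_se^2
  ord <- order(instr$wald_ratio)
  r <- instr$wald_ratio[ord]; ws <- w[ord] / sum(w)
  s <- cumsum(ws) - ws / 2
  k <- max(which(s < 0.5))
  oracle <- r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
  expect_equal(weighted_median_estimate(instr, n_boot = 20, seed = 1)$beta,
               oracle, tolerance = 1e-12)
})

test_that("mode estimators: constants, outlier robustness, grid oracle", {
  const <- make_instr(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.3, 0.4) * 0.7)
  expect_equal(mode_estimate(const, n_boot = 20, seed = 1)$beta, 0.7,
               tolerance = 1e-6)

  clustered <- make_instr(rep(0.2, 6), c(0.198, 0.200, 0.202, 0.201,
                                         0.199, 2.0))
  f <- mode_estimate(clustered, weighted = FALSE, n_boot = 20, seed = 1)
  expect_lt(abs(f$beta - 1.0), 0.2)

  set.seed(11)
  instr <- make_instr(runif(6, 0.1, 0.4), rnorm(6, 0.15, 0.08),
                      se_o = runif(6, 0.02, 0.08))
  wts <- (1 / instr$wald_se^2); wts <- wts / sum(wts)
  r <- instr$wald_ratio
  disp <- min(sd(r), mad(r))
  s <- 0.9 * disp * 6^(-1 / 5)
  grid <- seq(min(r) - 3 * s, max(r) + 3 * s, length.out = 100001)
  dens <- sapply(grid, function(g) sum(wts * dnorm(g, r, s)))
  oracle <- grid[which.max(dens)]
  f2 <- mode_estimate(instr, n_boot = 20, seed = 1)
  expect_equal(f2$beta, oracle, tolerance = 0.01)
  expect_error(mode_estimate(make_instr(0.1, 0.1)), "at least 3")
})

test_that("heterogeneity: hand Q, df, leave-one-out definition", {
  instr <- make_instr(c(0.1, 0.2, 0.25), c(0.05, 0.2, 0.1),
                      se_o = c(0.03, 0.05, 0.04))
  fit <- ivw_estimate(instr)
  hd <- heterogeneity_diagnostics(instr, fit)
  w <- 1 / instr$wald_se^2
  expect_equal(hd$Q, sum(w * (instr$wald_ratio - fit$beta)^2),
               tolerance = 1e-12)
  expect_equal(hd$df, 2)
  expect_equal(hd$q_p, pchisq(hd$Q, 2, lower.tail = FALSE))

  same <- make_instr(c(0.1, 0.2, 0.4), c(0.1, 0.2, 0.4) * 3)
  hd2 <- heterogeneity_diagnostics(same, ivw_estimate(same))
  expect_equal(hd2$Q, 0, tolerance = 1e-18)
  expect_equal(hd2$q_p, 1)

  expect_equal(nrow(hd$leave_one_out), 3)
  expect_equal(hd$leave_one_out$beta[1],
               ivw_estimate(instr[-1, ])$beta, tolerance = 1e-12)
})

test_that("scale equivariance and orientation invariance hold exactly", {
  set.seed(19)
  instr <- make_instr(runif(6, 0.1, 0.5), rnorm(6, 0.2, 0.1),
                      se_o = runif(6, 0.03, 0.08))
  k <- 2.5
  scaled <- instr
  scaled$beta_exposure <- instr$beta_exposure * k
  scaled$se_exposure <- instr$se_exposure * k
  scaled$wald_ratio <- scaled$beta_outcome / scaled$beta_exposure
  scaled$wald_se <- scaled$se_outcome / abs(scaled$beta_exposure)
  expect_equal(ivw_estimate(scaled)$beta, ivw_estimate(instr)$beta / k,
               tolerance = 1e-12)
  expect_equal(egger_estimate(scaled)$beta, egger_estimate(instr)$beta / k,
               tolerance = 1e-12)
  expect_equal(weighted_median_estimate(scaled, n_boot = 10, seed = 2)$beta,
               weighted_median_estimate(instr, n_boot = 10, seed = 2)$beta / k,
               tolerance = 1e-12)
  expect_equal(mode_estimate(scaled, n_boot = 10, seed = 2)$beta,
               mode_estimate(instr, n_boot = 10, seed = 2)$beta / k,
               tolerance = 1e-9)

  # orientation: recoding a variant's alleles (swap + negate betas) leaves
  # the exposure-positive instrument set unchanged
  n <- 6
  mk <- function(b1, b2, ea, oa) {
    t1 <- as_sumstats(data.frame(variant_id = paste0("i", 1:n),
                                 chromosome = "1", position = 1:n * 1000L,
                                 effect_allele = ea, other_allele = oa,
                                 beta = b1, se = 0.02, p_value = 1e-10,
                                 eaf = 0.3, n = 1e5))
    t2 <- as_sumstats(data.frame(variant_id = paste0("i", 1:n),
                                 chromosome = "1", position = 1:n * 1000L,
                                 effect_allele = ea, other_allele = oa,
                                 beta = b2, se = 0.05, p_value = 1e-4,
                                 eaf = 0.3, n = 1e5))
    make_instrument_set(harmonize_pair(t1, t2), paste0("i", 1:n))
  }
  set.seed(23)
  b1 <- runif(n, 0.1, 0.4); b2 <- rnorm(n, 0.2, 0.1)
  ea <- rep("A", n); oa <- rep("G", n)
  base <- mk(b1, b2, ea, oa)
  ea2 <- replace(ea, 2, "G"); oa2 <- replace(oa, 2, "A")
  flip_coding <- mk(replace(b1, 2, -b1[2]), replace(b2, 2, -b2[2]), ea2, oa2)
  expect_equal(flip_coding$beta_exposure, base$beta_exposure)
  expect_equal(flip_coding$beta_outcome, base$beta_outcome)
  expect_equal(ivw_estimate(flip_coding)$beta, ivw_estimate(base)$beta)
  expect_true(all(base$beta_exposure > 0))
})

test_that("MR-PRESSO: clean no-op, determinism, outlier flagging", {
  set.seed(29)
  J <- 12
  be <- runif(J, 0.1, 0.4)
  bo <- 0.5 * be + rnorm(J, 0, 0.02)
  clean <- make_instr(be, bo, se_o = 0.02)
  res <- mr_presso(clean, n_sim = 300, seed = 5)
  expect_length(res$outlier_ids, 0)
  expect_equal(res$corrected$beta, res$uncorrected$beta)
  expect_gt(res$global_p, 0.05)

  res2 <- mr_presso(clean, n_sim = 300, seed = 5)
  expect_identical(res$global_p, res2$global_p)

  dirty <- clean
  dirty$beta_outcome[3] <- dirty$beta_outcome[3] + 1  # gross pleiotropy
  dirty$wald_ratio <- dirty$beta_outcome / dirty$beta_exposure
  res3 <- mr_presso(dirty, n_sim = 300, seed = 5)
  expect_true("i3" %in% res3$outlier_ids)
  expect_lt(res3$global_p, 0.05)
  expect_lt(abs(res3$corrected$beta - 0.5),
            abs(res3$uncorrected$beta - 0.5))
  expect_error(mr_presso(make_instr(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))),
               "at least 4")
})

test_that("instrument selection thresholds, clumps, and errors with fallback hint", {
  panel <- toy_panel(n_ind = 200, n_var = 6, seed = 5,
                     duplicate = list(c(3, 4)))
  ss <- as_sumstats(data.frame(
    variant_id = panel$map$variant_id, chromosome = "1",
    position = panel$map$position, effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.02,
    p_value = c(1e-9, 1e-10, 1e-12, 1e-9, 0.5, 0.2), eaf = 0.3, n = 1e5))
  ids <- select_instruments(ss, clump_r2 = 0.05, panel = panel)
  expect_setequal(ids, c("rs1", "rs2", "rs3"))  # rs4 clumped into rs3
  expect_error(select_instruments(ss, p_threshold = 1e-20, panel = panel),
               "5e-6")
})

test_that("run_bidirectional refuses self-runs and emits an FDR grid", {
  cfg <- sim_config(m_variants = 600, n_gwas1 = 50000, n_gwas2 = 50000,
                    h2_trait1 = 0.3, h2_trait2 = 0.3, prop_causal = 0.2,
                    n_ref = 300, seed = 61)
  truth <- simulate_true_effects(cfg)
  panel <- simulate_genotype_panel(cfg)
  gwas <- simulate_gwas_sumstats(cfg, truth, panel)
  expect_error(run_bidirectional(gwas$trait1, gwas$trait1, panel),
               "self-run")
  res <- run_bidirectional(gwas$trait2, gwas$trait1, panel,
                           config = list(n_boot = 50, n_presso_sim = 100))
  expect_true(all(c("forward", "reverse", "grid") %in% names(res)))
  expect_true(all(res$grid$p_fdr >= res$grid$p - 1e-12))
  expect_setequal(unique(res$grid$direction), c("forward", "reverse"))
})
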