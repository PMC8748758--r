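#' Compute clumping-and-thresholding polygenic scores
#'
#' Raw score for individual i is `sum_j beta_j * dosage_ij` over the
#' clump-retained variants with `p <= p_threshold`. Weight alleles are
#' reconciled against the panel's counted alleles: when the effect
#' allele is the panel's other allele (directly or as its strand
#' complement) the dosage is replaced by `2 - dosage`. Missing dosages
#' are imputed as `2 * eaf` (cohort mean when eaf is absent).
#'
#' @param panel target [genotype_panel()].
#' @param weights `sumstats` table supplying betas, p-values and alleles.
#' @param clump optional `clump_result`; restricts scoring to its
#'   retained variants.
#' @param p_threshold p-value cutoff, default 1 (all variants).
#' @return data.frame with `individual_id`, `raw`, `score` (mean 0,
#'   SD 1 across the cohort); attribute `n_variants_used`.
#' @export
compute_scores <- function(panel, weights, clump = NULL, p_threshold = 1) {
  w <- as.data.frame(weights)
  if (!is.null(clump)) {
    w <- w[w$variant_id %in% clump$retained$variant_id, , drop = FALSE]
  }
  w <- w[!is.na(w$p_value) & w$p_value <= p_threshold, , drop = FALSE]
  idx <- match(w$variant_id, panel$map$variant_id)
  w <- w[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (nrow(w) == 0) {
    stop("zero variants pass p_threshold = ", p_threshold,
         "; use a higher threshold")
  }
  x <- panel$dosage[, idx, drop = FALSE]
  counted <- panel$map$counted_allele[idx]
  match_ea <- w$effect_allele == counted |
    complement_base(w$effect_allele) == counted
  x[, !match_ea] <- 2 - x[, !match_ea, drop = FALSE]
  if (anyNA(x)) {
    fill <- ifelse(is.na(w$eaf), colMeans(x, na.rm = TRUE), 2 * w$eaf)
    # eaf refers to the effect allele, which is the counted orientation here
    nas <- which(is.na(x), arr.ind = TRUE)
    x[nas] <- fill[nas[, 2]]
  }
  raw <- unname(drop(x %*% w$beta))
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) stop("zero-variance score; cannot standardize")
  out <- data.frame(individual_id = panel$individual_ids,
                    raw = raw,
                    score = (raw - mean(raw)) / s,
                    stringsAsFactors = FALSE)
  attr(out, "n_variants_used") <- nrow(w)
  out
}

nagelkerke_r2 <- function(fit, ll0, n) {
  ll1 <- as.numeric(stats::logLik(fit))
  (1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0))
}

check_glm <- function(fit, label) {
  if (!fit$converged) stop(label, " logistic model did not converge")
  mu <- fit$fitted.values
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    stop(label, " logistic model shows (quasi-)separation")
  }
  fit
}

#' Increase in Nagelkerke pseudo-R2 attributable to a score
#'
#' Fits logistic models `outcome ~ covariates` and
#' `outcome ~ covariates + score` and returns the difference of their
#' Nagelkerke R2 values, `R2_N = [1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`
#' with `L0` the intercept-only likelihood. When the score is
#' standardized, `exp(coefficient)` is the odds ratio per SD.
#'
#' @param outcome binary 0/1 vector.
#' @param scores numeric score vector.
#' @param covariates data.frame or matrix of covariates (may be NULL).
#' @return list: `delta_r2`, `r2_full`, `r2_reduced`, `coef`, `se`,
#'   `or_per_sd`, `or_ci` (Wald 95%), `p`.
#' @export
nagelkerke_delta_r2 <- function(outcome, scores, covariates = NULL) {
  outcome <- as.numeric(outcome)
  n <- length(outcome)
  if (stats::sd(scores) == 0) {
    # constant score adds nothing to the model
    return(list(delta_r2 = 0, r2_full = NA_real_, r2_reduced = NA_real_,
                coef = 0, se = NA_real_, or_per_sd = 1,
                or_ci = c(NA_real_, NA_real_), p = NA_real_))
  }
  dat <- data.frame(.y = outcome, .score = as.numeric(scores))
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    # drop constant columns (e.g. sex inside a single-sex stratum)
    keep <- vapply(cov_df, function(v) length(unique(v)) > 1, logical(1))
    cov_df <- cov_df[, keep, drop = FALSE]
    dat <- cbind(dat, cov_df)
  } else {
    cov_df <- NULL
  }
  cov_terms <- if (!is.null(cov_df) && ncol(cov_df)) {
    paste(colnames(cov_df), collapse = " + ")
  } else "1"
  f_red <- stats::as.formula(paste(".y ~", cov_terms))
  f_full <- stats::as.formula(paste(".y ~", cov_terms, "+ .score"))
  fit0 <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat)
  ll0 <- as.numeric(stats::logLik(fit0))
  fit_red <- check_glm(stats::glm(f_red, family = stats::binomial(),
                                  data = dat), "reduced")
  fit_full <- check_glm(stats::glm(f_full, family = stats::binomial(),
                                   data = dat), "full")
  r2_red <- nagelkerke_r2(fit_red, ll0, n)
  r2_full <- nagelkerke_r2(fit_full, ll0, n)
  cf <- summary(fit_full)$coefficients
  b <- cf[".score", "Estimate"]
  se <- cf[".score", "Std. Error"]
  list(delta_r2 = r2_full - r2_red,
       r2_full = r2_full, r2_reduced = r2_red,
       coef = b, se = se,
       or_per_sd = exp(b),
       or_ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
       p = cf[".score", "Pr(>|z|)"])
}

#' Convert observed-scale R2 to the liability scale
#'
#' Ascertainment-corrected transformation for case-control samples
#' (Lee et al. 2012): with population prevalence `K`, sample case
#' fraction `P`, liability threshold `t = qnorm(1 - K)` and `z =
#' dnorm(t)`,
#' `C = K(1-K)/z^2 * K(1-K)/(P(1-P))`,
#' `theta = m (P-K)/(1-K) * (m (P-K)/(1-K) - t)` with `m = z/K`, and
#' `R2_liab = R2_obs C / (1 + R2_obs theta C)`. When `P = K` (no
#' ascertainment) `theta = 0` and the map reduces to the unascertained
#' scaling.
#'
#' @param r2_obs observed-scale R2 in `[0, 1)`.
#' @param K population prevalence in (0, 1).
#' @param P case fraction of the sample in (0, 1).
#' @return liability-scale R2.
#' @export
observed_to_liability <- function(r2_obs, K, P) {
  if (any(K <= 0 | K >= 1) || any(P <= 0 | P >= 1)) {
    stop("K and P must lie in (0, 1)")
  }
  if (any(r2_obs < 0 | r2_obs >= 1)) stop("r2_obs must lie in [0, 1)")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  m <- z / K
  C <- K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - t)
  r2_obs * C / (1 + r2_obs * theta * C)
}

#' Bootstrap normal-interval CI for the Nagelkerke delta-R2
#'
#' Resamples individuals with replacement, recomputes the delta-R2 per
#' replicate, and reports `estimate +/- 1.96 x bootstrap SD` (the
#' normal-interval method). Replicates that fail (non-convergence,
#' separation, degenerate outcome) are redrawn up to 100 extra times
#' before a hard error.
#'
#' @inheritParams nagelkerke_delta_r2
#' @param n_boot bootstrap replicates, default 5000.
#' @param seed integer seed; the run is reproducible given it.
#' @param conf confidence level, default 0.95.
#' @return list: `estimate`, `ci`, `boot_sd`, `boot` (replicate values).
#' @export
bootstrap_r2_ci <- function(outcome, scores, covariates = NULL,
                            n_boot = 5000, seed = 1, conf = 0.95) {
  set.seed(seed)
  est <- nagelkerke_delta_r2(outcome, scores, covariates)$delta_r2
  n <- length(outcome)
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  boot <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch({
        sc <- scores[idx]
        if (stats::sd(sc) == 0 || length(unique(outcome[idx])) < 2) {
          stop("degenerate resample")
        }
        nagelkerke_delta_r2(outcome[idx], sc,
                            if (is.null(cov_df)) NULL else
                              cov_df[idx, , drop = FALSE])$delta_r2
      }, error = function(e) NA_real_)
      if (!is.na(val)) break
      redraws <- redraws + 1L
      if (redraws > 100L) stop("more than 100 failed bootstrap redraws")
    }
    boot[b] <- val
  }
  sd_b <- if (n_boot > 1) stats::sd(boot) else 0
  if (n_boot == 1) warning("n_boot = 1: CI collapses to the point estimate")
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = est, ci = est + c(-1, 1) * zq * sd_b,
       boot_sd = sd_b, boot = boot, seed = seed)
}

#' Decile odds-ratio profile of a polygenic score
#'
#' Ranks individuals into 10 equal-size score bins (stable ties on
#' `(score, individual_id)`) and contrasts each decile against the
#' median 5th decile with a covariate-adjusted logistic regression.
#'
#' @inheritParams nagelkerke_delta_r2
#' @param individual_ids optional ids for deterministic tie-breaking.
#' @return data.frame with one row per decile: `decile`, `n`, `n_cases`,
#'   `or`, `or_lo`, `or_hi`, `p` (reference decile has `or = 1`;
#'   non-estimable contrasts are `NA`).
#' @export
decile_or_analysis <- function(scores, outcome, covariates = NULL,
                               individual_ids = NULL) {
  n <- length(scores)
  if (n < 100) stop("need >= 10 individuals per decile (n >= 100)")
  if (is.null(individual_ids)) individual_ids <- seq_len(n)
  ord <- order(scores, individual_ids)
  sizes <- rep(n %/% 10, 10)
  extra <- n %% 10
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  decile <- integer(n)
  decile[ord] <- rep(1:10, times = sizes)
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)

  rows <- lapply(1:10, function(d) {
    nd <- sum(decile == d)
    ncase <- sum(outcome[decile == d] == 1)
    if (d == 5) {
      return(data.frame(decile = d, n = nd, n_cases = ncase, or = 1,
                        or_lo = NA_real_, or_hi = NA_real_, p = NA_real_))
    }
    sel <- decile %in% c(5, d)
    y <- outcome[sel]
    ind <- as.numeric(decile[sel] == d)
    res <- tryCatch({
      dat <- data.frame(.y = y, .d = ind)
      if (!is.null(cov_df)) {
        cc <- cov_df[sel, , drop = FALSE]
        keep <- vapply(cc, function(v) length(unique(v)) > 1, logical(1))
        dat <- cbind(dat, cc[, keep, drop = FALSE])
      }
      f <- stats::as.formula(paste(".y ~", paste(setdiff(colnames(dat), ".y"),
                                                 collapse = " + ")))
      fit <- check_glm(stats::glm(f, family = stats::binomial(), data = dat),
                       paste0("decile ", d))
      cf <- summary(fit)$coefficients
      b <- cf[".d", "Estimate"]; se <- cf[".d", "Std. Error"]
      c(exp(b), exp(b - 1.96 * se), exp(b + 1.96 * se), cf[".d", "Pr(>|z|)"])
    }, error = function(e) rep(NA_real_, 4))
    data.frame(decile = d, n = nd, n_cases = ncase, or = res[1],
               or_lo = res[2], or_hi = res[3], p = res[4])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sex-stratified bootstrap comparison of liability-scale R2
#'
#' For each sex stratum, draws `n_boot` subsamples of `n_case` cases and
#' `n_control` controls, computes each partition score's Nagelkerke
#' delta-R2 (covariates adjusted; constant columns such as sex are
#' dropped within a stratum), converts it to the liability scale with
#' the stratum's prevalence, and contrasts the male and female bootstrap
#' distributions with a two-sided t-test. The t-test is applied to the
#' bootstrap distributions themselves, exactly as the source procedure
#' prescribes; see the methods vignette for why that is anti-conservative.
#'
#' @param scores_by_partition named list of score vectors (one per
#'   partition), all aligned to `outcome`.
#' @param outcome binary 0/1 vector.
#' @param covariates data.frame of covariates (should not include sex).
#' @param sex vector with levels `"male"`/`"female"` (or any two labels;
#'   the first sorted level is reported first).
#' @param n_boot resamples per stratum, default 5000.
#' @param n_case,n_control subsample sizes, default 500 each; reduced
#'   with a warning when a stratum is smaller.
#' @param K_by_sex named numeric prevalence per sex, default 0.01 both.
#' @param seed integer seed.
#' @return named list per partition: `mean` (per sex), `sd`, `t`, `p`,
#'   `boot` (matrix of the two bootstrap distributions).
#' @export
sex_bootstrap_compare <- function(scores_by_partition, outcome, covariates,
                                  sex, n_boot = 5000, n_case = 500,
                                  n_control = 500,
                                  K_by_sex = c(male = 0.01, female = 0.01),
                                  seed = 1) {
  sex <- as.character(sex)
  sexes <- sort(unique(sex))
  if (length(sexes) != 2) stop("both sex strata must be present")
  if (is.null(names(K_by_sex))) names(K_by_sex) <- sexes
  set.seed(seed)
  cov_df <- if (is.null(covariates)) NULL else as.data.frame(covariates)

  draw_stratum <- function(sx) {
    cases <- which(sex == sx & outcome == 1)
    ctrls <- which(sex == sx & outcome == 0)
    if (length(cases) == 0 || length(ctrls) == 0) {
      stop("sex stratum '", sx, "' lacks cases or controls")
    }
    nc <- n_case; nh <- n_control
    if (length(cases) < nc) {
      warning("stratum '", sx, "': only ", length(cases),
              " cases; subsample size reduced")
      nc <- length(cases)
    }
    if (length(ctrls) < nh) {
      warning("stratum '", sx, "': only ", length(ctrls),
              " controls; subsample size reduced")
      nh <- length(ctrls)
    }
    list(cases = cases, ctrls = ctrls, nc = nc, nh = nh)
  }
  strata <- lapply(sexes, draw_stratum)
  names(strata) <- sexes

  res <- lapply(names(scores_by_partition), function(part) {
    sc <- scores_by_partition[[part]]
    boot <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                   dimnames = list(NULL, sexes))
    for (sx in sexes) {
      st <- strata[[sx]]
      K <- K_by_sex[[sx]]
      P <- st$nc / (st$nc + st$nh)
      for (b in seq_len(n_boot)) {
        idx <- c(sample(st$cases, st$nc, replace = length(st$cases) < st$nc),
                 sample(st$ctrls, st$nh, replace = length(st$ctrls) < st$nh))
        r2 <- tryCatch(
          nagelkerke_delta_r2(outcome[idx], sc[idx],
                              if (is.null(cov_df)) NULL else
                                cov_df[idx, , drop = FALSE])$delta_r2,
          error = function(e) NA_real_)
        boot[b, sx] <- if (is.na(r2)) NA_real_ else
          observed_to_liability(max(r2, 0), K, P)
      }
    }
    ok <- stats::complete.cases(boot)
    tt <- stats::t.test(boot[ok, 1], boot[ok, 2])
    list(mean = colMeans(boot, na.rm = TRUE),
         sd = apply(boot, 2, stats::sd, na.rm = TRUE),
         t = unname(tt$statistic), p = tt$p.value, boot = boot)
  })
  names(res) <- names(scores_by_partition)
  res
}
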