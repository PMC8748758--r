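#' Select MR instruments by p-threshold and stringent clumping
#'
#' Filters the exposure summary statistics at `p_threshold` and clumps
#' the survivors with the conventional MR parameters (r2 0.001, 10 Mb
#' window) so instruments are mutually LD-independent.
#'
#' @param exposure `sumstats` table for the exposure.
#' @param p_threshold instrument significance threshold, default 5e-8.
#' @param clump_r2,clump_kb clumping parameters, defaults 0.001 / 10000.
#' @param panel reference [genotype_panel()].
#' @return character vector of instrument variant ids (attribute
#'   `clump` holds the full `clump_result`).
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8,
                               clump_r2 = 0.001, clump_kb = 10000, panel) {
  cand <- exposure[!is.na(exposure$p_value) &
                     exposure$p_value < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no instruments at p < ", p_threshold,
         "; consider the explicit fallback threshold 5e-6")
  }
  cl <- greedy_clump(cand, panel, r2_threshold = clump_r2,
                     window_kb = clump_kb, p_col = "p_value")
  ids <- cl$retained$variant_id
  if (length(ids) == 0) {
    stop("no instruments survive clumping; consider the explicit fallback ",
         "threshold 5e-6")
  }
  structure(ids, clump = cl)
}

#' Build a harmonized instrument set for two-sample MR
#'
#' Takes exposure/outcome effects from a harmonized pair table (trait 1
#' = exposure), restricts to the selected instruments, and orients each
#' instrument so `beta_exposure > 0` (negating both betas; estimates are
#' invariant, Egger requires the convention). Wald ratio SEs use the
#' first-order delta method `se_outcome / |beta_exposure|`.
#'
#' @param merged `merged_pair` from [harmonize_pair()] with the exposure
#'   as trait 1.
#' @param instrument_ids variant ids from [select_instruments()].
#' @return An `instrument_set` data.frame: `variant_id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `wald_ratio`, `wald_se`.
#' @export
make_instrument_set <- function(merged, instrument_ids) {
  d <- retained_pairs(merged)
  d <- d[d$variant_id %in% instrument_ids, , drop = FALSE]
  d <- d[d$beta_1 != 0, , drop = FALSE]
  flip <- d$beta_1 < 0
  be <- ifelse(flip, -d$beta_1, d$beta_1)
  bo <- ifelse(flip, -d$beta_2, d$beta_2)
  out <- data.frame(variant_id = d$variant_id,
                    beta_exposure = be, se_exposure = d$se_1,
                    beta_outcome = bo, se_outcome = d$se_2,
                    wald_ratio = bo / be,
                    wald_se = d$se_2 / abs(be),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("instrument_set", "data.frame"))
}

mr_result <- function(method, beta, se, p, n_instruments, extra = list()) {
  c(list(method = method, beta = beta, se = se, p = p,
         n_instruments = n_instruments), extra)
}

#' Inverse-variance-weighted MR estimate
#'
#' Zero-intercept weighted regression of outcome betas on exposure
#' betas with weights `1/se_outcome^2`; multiplicative random-effects
#' SE with the residual scale floored at 1 (never below fixed-effect).
#' A single instrument collapses to its Wald ratio, labelled so.
#'
#' @param instruments `instrument_set`.
#' @return list: `method`, `beta`, `se`, `p`, `n_instruments`.
#' @export
ivw_estimate <- function(instruments) {
  J <- nrow(instruments)
  if (J == 0) stop("empty instrument set")
  if (J == 1) {
    return(mr_result("WaldRatio", instruments$wald_ratio,
                     instruments$wald_se,
                     2 * stats::pnorm(-abs(instruments$wald_ratio /
                                             instruments$wald_se)), 1L))
  }
  x <- instruments$beta_exposure
  y <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  b <- sum(w * x * y) / sum(w * x^2)
  sigma2 <- sum(w * (y - b * x)^2) / (J - 1)
  se <- sqrt(max(1, sigma2) / sum(w * x^2))
  mr_result("IVW", b, se, 2 * stats::pnorm(-abs(b / se)), J)
}

#' MR-Egger regression estimate and intercept (pleiotropy) test
#'
#' Weighted regression of outcome on exposure betas with a free
#' intercept (instruments oriented exposure-positive); the intercept
#' estimates average directional pleiotropy. SEs are multiplicative
#' random effects (residual scale floored at 1); p-values use the t
#' distribution with J-2 df.
#'
#' @param instruments `instrument_set` with >= 3 instruments.
#' @return list with `beta`, `se`, `p` for the slope plus
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
egger_estimate <- function(instruments) {
  J <- nrow(instruments)
  if (J < 3) stop("MR-Egger requires at least 3 instruments")
  x <- instruments$beta_exposure
  y <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  X <- cbind(1, x)
  A <- crossprod(X * sqrt(w))
  b <- solve(A, crossprod(X * sqrt(w), y * sqrt(w)))
  resid <- y - drop(X %*% b)
  sigma2 <- sum(w * resid^2) / (J - 2)
  V <- solve(A) * max(1, sigma2)
  slope <- b[2]; slope_se <- sqrt(V[2, 2])
  int <- b[1]; int_se <- sqrt(V[1, 1])
  mr_result("Egger", slope, slope_se,
            2 * stats::pt(-abs(slope / slope_se), df = J - 2), J,
            extra = list(intercept = int, intercept_se = int_se,
                         intercept_p = 2 * stats::pt(-abs(int / int_se),
                                                     df = J - 2)))
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  below <- max(which(s < 0.5))
  # linear interpolation on the cumulative weight at 0.5
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

#' Weighted-median MR estimate
#'
#' Weighted median of the per-instrument Wald ratios with
#' inverse-variance weights `1/wald_se^2`, interpolated on the
#' cumulative weight at 0.5; SE by parametric bootstrap of the
#' instrument betas.
#'
#' @param instruments `instrument_set` with >= 3 instruments.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed.
#' @return list: `method`, `beta`, `se`, `p`, `n_instruments`.
#' @export
weighted_median_estimate <- function(instruments, n_boot = 1000, seed = 1) {
  J <- nrow(instruments)
  if (J < 3) stop("weighted median requires at least 3 instruments")
  w <- 1 / instruments$wald_se^2
  b <- weighted_median_point(instruments$wald_ratio, w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    be <- stats::rnorm(J, instruments$beta_exposure, instruments$se_exposure)
    bo <- stats::rnorm(J, instruments$beta_outcome, instruments$se_outcome)
    ok <- be != 0
    r <- bo[ok] / be[ok]
    wi <- (be[ok] / instruments$se_outcome[ok])^2
    weighted_median_point(r, wi)
  }, numeric(1))
  se <- stats::sd(boot)
  mr_result("WeightedMedian", b, se, 2 * stats::pnorm(-abs(b / se)), J)
}

mode_point <- function(ratios, weights, bandwidth_factor) {
  disp <- min(stats::sd(ratios), stats::mad(ratios))
  if (disp == 0) disp <- max(stats::sd(ratios), stats::mad(ratios))
  if (disp == 0) return(ratios[1])
  s <- bandwidth_factor * 0.9 * disp * length(ratios)^(-1 / 5)
  grid <- seq(min(ratios) - 3 * s, max(ratios) + 3 * s, length.out = 2048)
  dens <- vapply(grid, function(g) {
    sum(weights * stats::dnorm(g, mean = ratios, sd = s))
  }, numeric(1))
  grid[which.max(dens)]
}

#' Mode-based MR estimate (simple or weighted)
#'
#' Mode of the kernel-smoothed density of Wald ratios; normal kernel
#' with a modified Silverman bandwidth `phi * 0.9 * min(sd, mad) *
#' J^(-1/5)`. The weighted variant uses inverse-variance weights,
#' the simple variant equal weights. SE by parametric bootstrap.
#'
#' @param instruments `instrument_set` with >= 3 instruments.
#' @param weighted logical; inverse-variance weights if TRUE.
#' @param bandwidth_factor bandwidth multiplier phi, default 1.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed.
#' @return list: `method`, `beta`, `se`, `p`, `n_instruments`.
#' @export
mode_estimate <- function(instruments, weighted = TRUE,
                          bandwidth_factor = 1, n_boot = 1000, seed = 1) {
  J <- nrow(instruments)
  if (J < 3) stop("mode estimator requires at least 3 instruments")
  wts <- if (weighted) 1 / instruments$wald_se^2 else rep(1, J)
  wts <- wts / sum(wts)
  b <- mode_point(instruments$wald_ratio, wts, bandwidth_factor)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    be <- stats::rnorm(J, instruments$beta_exposure, instruments$se_exposure)
    bo <- stats::rnorm(J, instruments$beta_outcome, instruments$se_outcome)
    ok <- be != 0
    r <- bo[ok] / be[ok]
    wi <- if (weighted) (be[ok] / instruments$se_outcome[ok])^2 else
      rep(1, sum(ok))
    mode_point(r, wi / sum(wi), bandwidth_factor)
  }, numeric(1))
  se <- stats::sd(boot)
  mr_result(if (weighted) "WeightedMode" else "SimpleMode", b, se,
            2 * stats::pnorm(-abs(b / se)), J)
}

#' Cochran's Q heterogeneity and leave-one-out diagnostics
#'
#' `Q = sum_j w_j (ratio_j - beta_hat)^2` with `w_j = 1/wald_se_j^2`,
#' compared to chi-square with J-1 (IVW) or J-2 (Egger) df. The
#' leave-one-out table refits IVW J times, omitting one instrument each.
#'
#' @param instruments `instrument_set`.
#' @param fitted fitted result from [ivw_estimate()] or
#'   [egger_estimate()]; determines the Q reference value and df.
#' @return list: `Q`, `df`, `q_p`, `leave_one_out` data.frame
#'   (`omitted`, `beta`, `se`, `p`).
#' @export
heterogeneity_diagnostics <- function(instruments, fitted) {
  J <- nrow(instruments)
  w <- 1 / instruments$wald_se^2
  if (identical(fitted$method, "Egger")) {
    pred <- (fitted$intercept + fitted$beta * instruments$beta_exposure) /
      instruments$beta_exposure
    df <- J - 2
  } else {
    pred <- rep(fitted$beta, J)
    df <- J - 1
  }
  Q <- sum(w * (instruments$wald_ratio - pred)^2)
  q_p <- if (df > 0) stats::pchisq(Q, df = df, lower.tail = FALSE) else NA_real_
  loo <- do.call(rbind, lapply(seq_len(J), function(j) {
    fit <- ivw_estimate(instruments[-j, , drop = FALSE])
    data.frame(omitted = instruments$variant_id[j], beta = fit$beta,
               se = fit$se, p = fit$p, stringsAsFactors = FALSE)
  }))
  rownames(loo) <- NULL
  list(Q = Q, df = df, q_p = q_p, leave_one_out = loo)
}

#' MR-PRESSO global test, outlier detection and corrected estimate
#'
#' The observed residual sum of squares is computed from leave-one-out
#' IVW predictions with outcome-variance weights; its null distribution
#' is built from `n_sim` parametric simulations of instrument betas
#' under the fitted (no-pleiotropy) model. Per-instrument outlier
#' p-values are Bonferroni-thresholded at `outlier_alpha`; the corrected
#' estimate is IVW on the surviving instruments.
#'
#' @param instruments `instrument_set` with >= 4 instruments.
#' @param n_sim parametric simulations, default 1000.
#' @param outlier_alpha familywise outlier level, default 0.05.
#' @param seed integer seed.
#' @return list: `global_p`, `outlier_ids`, `outlier_p` (per
#'   instrument, Bonferroni-adjusted), `corrected` (IVW on
#'   non-outliers), `uncorrected`.
#' @export
mr_presso <- function(instruments, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 1) {
  J <- nrow(instruments)
  if (J < 4) stop("MR-PRESSO requires at least 4 instruments")
  w <- 1 / instruments$se_outcome^2
  loo_beta <- vapply(seq_len(J), function(j) {
    ivw_estimate(instruments[-j, , drop = FALSE])$beta
  }, numeric(1))
  res_obs <- w * (instruments$beta_outcome -
                    loo_beta * instruments$beta_exposure)^2
  rss_obs <- sum(res_obs)

  set.seed(seed)
  sim_res <- matrix(NA_real_, nrow = n_sim, ncol = J)
  for (s in seq_len(n_sim)) {
    be <- stats::rnorm(J, instruments$beta_exposure, instruments$se_exposure)
    bo <- stats::rnorm(J, loo_beta * instruments$beta_exposure,
                       instruments$se_outcome)
    sim <- instruments
    sim$beta_exposure <- be
    sim$beta_outcome <- bo
    sim$wald_ratio <- bo / be
    sim$wald_se <- sim$se_outcome / abs(be)
    lb <- vapply(seq_len(J), function(j) {
      ivw_estimate(sim[-j, , drop = FALSE])$beta
    }, numeric(1))
    sim_res[s, ] <- w * (bo - lb * be)^2
  }
  rss_sim <- rowSums(sim_res)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_raw <- vapply(seq_len(J), function(j) {
    (1 + sum(sim_res[, j] >= res_obs[j])) / (n_sim + 1)
  }, numeric(1))
  p_bonf <- pmin(1, p_raw * J)
  outliers <- which(p_bonf < outlier_alpha)
  if (length(outliers) == J) stop("no instruments survive outlier removal")
  corrected <- if (length(outliers)) {
    ivw_estimate(instruments[-outliers, , drop = FALSE])
  } else {
    ivw_estimate(instruments)
  }
  list(global_p = global_p,
       outlier_ids = instruments$variant_id[outliers],
       outlier_p = stats::setNames(p_bonf, instruments$variant_id),
       corrected = corrected,
       uncorrected = ivw_estimate(instruments))
}

run_mr_direction <- function(exposure, outcome, panel, config) {
  merged <- harmonize_pair(exposure, outcome,
                           palindrome_policy = config$palindrome_policy)
  ids <- select_instruments(exposure, p_threshold = config$p_threshold,
                            clump_r2 = config$clump_r2,
                            clump_kb = config$clump_kb, panel = panel)
  instr <- make_instrument_set(merged, ids)
  J <- nrow(instr)
  fits <- list(ivw = ivw_estimate(instr))
  if (J >= 3) {
    fits$egger <- egger_estimate(instr)
    fits$weighted_median <- weighted_median_estimate(instr,
                                                     n_boot = config$n_boot,
                                                     seed = config$seed)
    fits$simple_mode <- mode_estimate(instr, weighted = FALSE,
                                      n_boot = config$n_boot,
                                      seed = config$seed)
    fits$weighted_mode <- mode_estimate(instr, weighted = TRUE,
                                        n_boot = config$n_boot,
                                        seed = config$seed)
  }
  diag <- heterogeneity_diagnostics(instr, fits$ivw)
  presso <- if (J >= 4) {
    tryCatch(mr_presso(instr, n_sim = config$n_presso_sim,
                       seed = config$seed),
             error = function(e) NULL)
  } else NULL
  list(instruments = instr, fits = fits, diagnostics = diag,
       presso = presso)
}

#' Bidirectional two-sample MR suite
#'
#' Runs the full estimator and diagnostic suite in both directions
#' (exposure -> outcome and the reverse) and applies Benjamini-Hochberg
#' FDR across the direction x method grid.
#'
#' @param exposure,outcome validated `sumstats` tables for the two
#'   traits (an identical pair is refused).
#' @param panel reference [genotype_panel()] for clumping.
#' @param config list overriding defaults: `p_threshold` (5e-8),
#'   `clump_r2` (0.001), `clump_kb` (10000), `palindrome_policy`,
#'   `n_boot` (1000), `n_presso_sim` (1000), `seed` (1).
#' @return list: `forward`, `reverse` (each as the per-direction
#'   bundle), `grid` data.frame (direction, method, beta, se, p, p_fdr,
#'   significant).
#' @export
run_bidirectional <- function(exposure, outcome, panel, config = list()) {
  defaults <- list(p_threshold = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
                   palindrome_policy = "drop_ambiguous_freq",
                   n_boot = 1000, n_presso_sim = 1000, seed = 1)
  config <- utils::modifyList(defaults, config)
  same <- identical(exposure$variant_id, outcome$variant_id) &&
    isTRUE(all.equal(exposure$beta, outcome$beta)) &&
    isTRUE(all.equal(exposure$se, outcome$se))
  if (same) stop("exposure and outcome are the same trait; self-run refused")

  fwd <- run_mr_direction(exposure, outcome, panel, config)
  rev <- run_mr_direction(outcome, exposure, panel, config)

  collect <- function(bundle, direction) {
    rows <- lapply(bundle$fits, function(f) {
      data.frame(direction = direction, method = f$method, beta = f$beta,
                 se = f$se, p = f$p, n_instruments = f$n_instruments,
                 stringsAsFactors = FALSE)
    })
    if (!is.null(bundle$presso)) {
      f <- bundle$presso$corrected
      rows <- c(rows, list(data.frame(direction = direction,
                                      method = "PRESSO-corrected",
                                      beta = f$beta, se = f$se, p = f$p,
                                      n_instruments = f$n_instruments,
                                      stringsAsFactors = FALSE)))
    }
    do.call(rbind, rows)
  }
  grid <- rbind(collect(fwd, "forward"), collect(rev, "reverse"))
  grid$p_fdr <- bh_fdr(grid$p)
  grid$significant <- grid$p_fdr < 0.05
  rownames(grid) <- NULL
  list(forward = fwd, reverse = rev, grid = grid)
}
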