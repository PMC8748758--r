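#' Simulation configuration for the two-trait synthetic world
#'
#' Defaults encode the emulated study: a large binary-trait discovery
#' GWAS (82,315 = 35,476 cases + 46,839 controls), a very large
#' quantitative conditioning-trait GWAS (487,647), a target case-control
#' cohort of 1,927 cases and 1,561 controls ascertained from a 1%
#' prevalence liability-threshold model, a conditioning-trait
#' SNP-heritability of 4.2%, and sharing parameters calibrated so the
#' expected genetic correlation is ~0.17 (with independently drawn
#' shared effect magnitudes, `rg ~= frac_shared * (2 f_conc - 1) * 2/pi`).
#' The genome itself (variant count, LD-block size, AR(1) correlation,
#' MAF range) is a desk-scale stand-in, not an emulation of real LD.
#'
#' @param m_variants number of variants, default 2000.
#' @param n_gwas1,n_gwas2 discovery GWAS sizes (focal, conditioning).
#' @param n_cases,n_controls target-cohort composition.
#' @param n_ref reference-panel individuals, default 500.
#' @param ld_block_size variants per LD block, default 20.
#' @param ar_rho within-block AR(1) latent correlation, default 0.9.
#' @param maf_range minor-allele-frequency bounds, default c(0.05, 0.5).
#' @param h2_trait1,h2_trait2 heritabilities (liability scale for the
#'   binary focal trait), defaults 0.24 and 0.042.
#' @param prop_causal fraction of variants causal per trait, default 0.1.
#' @param frac_shared fraction of focal-trait causal variants shared
#'   with the conditioning trait, default 0.4.
#' @param frac_concordant_of_shared fraction of shared causal variants
#'   with same-sign effects, default 0.834.
#' @param prevalence population prevalence K; a named length-2 vector
#'   (`male`, `female`) makes it sex-specific. Default 0.01.
#' @param sex_effect_scale multiplier on the genetic effect SD in
#'   females relative to males, default 1.
#' @param seed integer master seed (< 2^31), default 1.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m_variants = 2000, n_gwas1 = 82315, n_gwas2 = 487647,
                       n_cases = 1927, n_controls = 1561, n_ref = 500,
                       ld_block_size = 20, ar_rho = 0.9,
                       maf_range = c(0.05, 0.5),
                       h2_trait1 = 0.24, h2_trait2 = 0.042,
                       prop_causal = 0.1, frac_shared = 0.4,
                       frac_concordant_of_shared = 0.834,
                       prevalence = 0.01, sex_effect_scale = 1, seed = 1) {
  cfg <- list(m_variants = as.integer(m_variants), n_gwas1 = n_gwas1,
              n_gwas2 = n_gwas2, n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls), n_ref = as.integer(n_ref),
              ld_block_size = as.integer(ld_block_size), ar_rho = ar_rho,
              maf_range = maf_range, h2_trait1 = h2_trait1,
              h2_trait2 = h2_trait2, prop_causal = prop_causal,
              frac_shared = frac_shared,
              frac_concordant_of_shared = frac_concordant_of_shared,
              prevalence = prevalence, sex_effect_scale = sex_effect_scale,
              seed = as.integer(seed))
  fracs <- c(cfg$prop_causal, cfg$frac_shared, cfg$frac_concordant_of_shared)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (any(c(cfg$h2_trait1, cfg$h2_trait2) < 0) ||
      any(c(cfg$h2_trait1, cfg$h2_trait2) >= 1)) {
    stop("heritabilities must lie in [0, 1)")
  }
  if (cfg$ar_rho < 0 || cfg$ar_rho >= 1) stop("ar_rho must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

k_by_sex <- function(cfg) {
  K <- cfg$prevalence
  if (length(K) == 1) c(male = unname(K), female = unname(K)) else
    c(male = unname(K[["male"]]), female = unname(K[["female"]]))
}

# Deterministic variant layout shared by every generator: blocks laid
# round-robin over chromosomes 1..22, 1 kb spacing within a block and a
# 2 Mb gap between consecutive blocks on a chromosome, so blocks are
# separated beyond the default clumping and LD windows.
variant_layout <- function(cfg) {
  m <- cfg$m_variants
  bs <- cfg$ld_block_size
  n_blocks <- ceiling(m / bs)
  block <- rep(seq_len(n_blocks), each = bs)[seq_len(m)]
  chrom <- ((block - 1) %% 22) + 1
  block_on_chr <- (block - 1) %/% 22
  within <- stats::ave(block, block, FUN = seq_along)
  pos <- 1e6 + block_on_chr * 2e6 + (within - 1) * 1000
  data.frame(variant_id = sprintf("snp%06d", seq_len(m)),
             chromosome = as.character(chrom),
             position = as.integer(pos),
             counted_allele = "A", other_allele = "G",
             block = block, stringsAsFactors = FALSE)
}

draw_mafs <- function(cfg) {
  stats::runif(cfg$m_variants, cfg$maf_range[1], cfg$maf_range[2])
}

#' Draw the true two-trait effect architecture
#'
#' Causal variants are sampled per trait; a `frac_shared` fraction of
#' the focal trait's causal set also affects the conditioning trait.
#' Shared pairs get independently drawn effect magnitudes with signs
#' forced concordant for a `frac_concordant_of_shared` fraction and
#' discordant for the rest. Effects are on the standardized-genotype
#' scale and rescaled so each trait's summed squared effects equal its
#' configured heritability. Realized heritabilities and the realized
#' genetic correlation are recomputed from the effects (and, when a
#' panel is supplied, from its empirical LD).
#'
#' @param config a [sim_config()].
#' @param panel optional [genotype_panel()] from
#'   [simulate_genotype_panel()]; enables LD-aware realized quantities.
#' @return A `ground_truth` list: `effects` data.frame (`variant_id`,
#'   `label`, `b1`, `b2` on the standardized scale), `realized_h2_1`,
#'   `realized_h2_2`, `realized_rg`.
#' @export
simulate_true_effects <- function(config, panel = NULL) {
  cfg <- config
  set.seed(cfg$seed + 11L)
  m <- cfg$m_variants
  n_causal <- round(cfg$prop_causal * m)
  if (n_causal < 1) stop("prop_causal * m_variants must be >= 1")
  lay <- variant_layout(cfg)

  causal1 <- sample.int(m, n_causal)
  n_shared <- round(cfg$frac_shared * n_causal)
  shared <- if (n_shared > 0) causal1[seq_len(n_shared)] else integer(0)
  # conditioning trait: shared causals plus its own specific set of the
  # same total size, drawn from the remaining variants
  pool2 <- setdiff(seq_len(m), causal1)
  n_spec2 <- min(length(pool2), n_causal - n_shared)
  spec2 <- if (n_spec2 > 0) sample(pool2, n_spec2) else integer(0)

  b1 <- numeric(m); b2 <- numeric(m)
  b1[causal1] <- stats::rnorm(n_causal)
  b2[shared] <- stats::rnorm(n_shared)
  b2[spec2] <- stats::rnorm(n_spec2)
  # force sign structure on shared pairs
  if (n_shared > 0) {
    n_conc <- round(cfg$frac_concordant_of_shared * n_shared)
    conc <- shared[seq_len(n_conc)]
    disc <- setdiff(shared, conc)
    b2[conc] <- sign(b1[conc]) * abs(b2[conc])
    b2[disc] <- -sign(b1[disc]) * abs(b2[disc])
  } else {
    conc <- disc <- integer(0)
  }
  scale_to <- function(b, h2) {
    ss <- sum(b^2)
    if (ss > 0 && h2 > 0) b * sqrt(h2 / ss) else b * 0
  }
  b1 <- scale_to(b1, cfg$h2_trait1)
  b2 <- scale_to(b2, cfg$h2_trait2)

  label <- rep("null", m)
  label[causal1] <- "trait1_specific"
  label[spec2] <- "trait2_specific"
  label[conc] <- "shared_concordant"
  label[disc] <- "shared_discordant"

  if (!is.null(panel)) {
    xs <- scale(panel$dosage)
    g1 <- drop(xs %*% b1); g2 <- drop(xs %*% b2)
    vg1 <- stats::var(g1); vg2 <- stats::var(g2)
    h2_1 <- vg1 / (vg1 + 1 - cfg$h2_trait1)
    h2_2 <- vg2 / (vg2 + 1 - cfg$h2_trait2)
    rg <- if (vg1 > 0 && vg2 > 0) stats::cov(g1, g2) / sqrt(vg1 * vg2) else 0
  } else {
    h2_1 <- sum(b1^2); h2_2 <- sum(b2^2)
    den <- sqrt(sum(b1^2) * sum(b2^2))
    rg <- if (den > 0) sum(b1 * b2) / den else 0
  }
  structure(list(effects = data.frame(variant_id = lay$variant_id,
                                      label = label, b1 = b1, b2 = b2,
                                      stringsAsFactors = FALSE),
                 realized_h2_1 = h2_1, realized_h2_2 = h2_2,
                 realized_rg = rg),
            class = "ground_truth")
}

# Latent AR(1) haplotype pair thresholded to genotype dosages.
draw_block_genotypes <- function(n, block_sizes, rho, thresholds) {
  m <- sum(block_sizes)
  gen_latent <- function() {
    z <- matrix(stats::rnorm(n * m), nrow = n)
    off <- 0
    for (bs in block_sizes) {
      if (bs > 1) {
        for (j in 2:bs) {
          z[, off + j] <- rho * z[, off + j - 1] +
            sqrt(1 - rho^2) * z[, off + j]
        }
      }
      off <- off + bs
    }
    z
  }
  z1 <- gen_latent(); z2 <- gen_latent()
  t_mat <- matrix(thresholds, nrow = n, ncol = m, byrow = TRUE)
  (z1 > t_mat) + (z2 > t_mat)
}

#' Simulate an LD-blocked reference genotype panel
#'
#' Genotypes arise from two latent AR(1) Gaussian haplotypes per block
#' thresholded at each variant's allele frequency, giving dosages in
#' {0,1,2} with exponentially decaying within-block LD and independence
#' across blocks. Block positions are spaced so that default clumping
#' and LD-score windows never span two blocks.
#'
#' @param config a [sim_config()].
#' @param n number of individuals, default `config$n_ref`.
#' @param seed_offset internal offset so panels drawn for different
#'   purposes are independent; leave at default for the LD reference.
#' @return A [genotype_panel()] with allele frequencies stored in
#'   `map$maf`.
#' @export
simulate_genotype_panel <- function(config, n = config$n_ref,
                                    seed_offset = 23L) {
  cfg <- config
  set.seed(cfg$seed + seed_offset)
  lay <- variant_layout(cfg)
  mafs <- draw_mafs(cfg)
  block_sizes <- as.integer(table(lay$block))
  thr <- stats::qnorm(1 - mafs)
  dose <- draw_block_genotypes(n, block_sizes, cfg$ar_rho, thr)
  map <- lay[, c("variant_id", "chromosome", "position", "counted_allele",
                 "other_allele")]
  map$maf <- mafs
  genotype_panel(dose, map)
}

#' Simulate two GWAS summary-statistics tables from the architecture
#'
#' Marginal (LD-convolved) standardized effects are computed per block
#' against the panel's realized correlation, `beta_marg = R b`; sampling
#' noise is added at the `1/sqrt(n)` scale with within-block correlation
#' `R`, mirroring one-cohort marginal estimation. Effects are then
#' rescaled to the per-allele scale using the panel dosage SDs. The
#' binary focal trait is emitted on the log-odds scale through the
#' liability-to-log-odds slope `dnorm(t)/(K(1-K))` at prevalence K
#' (recorded as mode `liability_approx`).
#'
#' @param config a [sim_config()].
#' @param truth [simulate_true_effects()] output from the same config.
#' @param panel [simulate_genotype_panel()] output from the same config.
#' @return list of two `sumstats` tables, `trait1` (focal, log-odds) and
#'   `trait2` (conditioning, linear scale); attribute `mode`.
#' @export
simulate_gwas_sumstats <- function(config, truth, panel) {
  cfg <- config
  set.seed(cfg$seed + 37L)
  lay <- variant_layout(cfg)
  m <- cfg$m_variants
  xs <- scale(panel$dosage)
  sds <- attr(xs, "scaled:scale")
  if (any(sds == 0)) stop("monomorphic variant in panel; increase n_ref")

  marg_and_noise <- function(b, n) {
    bm <- numeric(m)
    noise <- numeric(m)
    for (blk in unique(lay$block)) {
      sel <- which(lay$block == blk)
      R <- stats::cor(panel$dosage[, sel, drop = FALSE])
      bm[sel] <- drop(R %*% b[sel])
      ch <- chol(R + diag(1e-8, length(sel)))
      noise[sel] <- drop(crossprod(ch, stats::rnorm(length(sel)))) / sqrt(n)
    }
    list(bm = bm, noise = noise)
  }
  build <- function(b, n, logodds_factor = 1) {
    mn <- marg_and_noise(b, n)
    beta_std <- mn$bm + mn$noise
    se_std <- rep(1 / sqrt(n), m)
    beta <- beta_std / sds * logodds_factor
    se <- se_std / sds * logodds_factor
    z <- beta / se
    as_sumstats(data.frame(
      variant_id = lay$variant_id, chromosome = lay$chromosome,
      position = lay$position, effect_allele = lay$counted_allele,
      other_allele = lay$other_allele, beta = beta, se = se,
      p_value = pmax(2 * stats::pnorm(-abs(z)), 1e-300),
      eaf = colMeans(panel$dosage) / 2, n = n,
      stringsAsFactors = FALSE))
  }
  K <- mean(k_by_sex(cfg))
  t <- stats::qnorm(1 - K)
  lo_factor <- stats::dnorm(t) / (K * (1 - K))
  out <- list(trait1 = build(truth$effects$b1, cfg$n_gwas1, lo_factor),
              trait2 = build(truth$effects$b2, cfg$n_gwas2))
  attr(out, "mode") <- "liability_approx"
  out
}

#' Simulate an ascertained liability-threshold case-control cohort
#'
#' Fresh genotypes are drawn from the same block structure; liability is
#' the standardized genetic score (multiplied by `sex_effect_scale` in
#' females) plus a normal residual of variance `1 - h2`, and an
#' individual is a case when liability exceeds the upper-K normal
#' quantile for their sex. Individuals are drawn in chunks until the
#' requested cases and controls are filled (hard error after 200
#' chunks). Sex is Bernoulli(0.5); age and ten ancestry components are
#' drawn independent of liability, so covariate adjustment is exercised
#' without confounding.
#'
#' @param config a [sim_config()].
#' @param truth [simulate_true_effects()] output from the same config.
#' @return list: `panel` ([genotype_panel()] of the cohort),
#'   `phenotypes` data.frame (`individual_id`, `case_status`, `sex`,
#'   `age`, `mds1`..`mds10`).
#' @export
simulate_target_cohort <- function(config, truth) {
  cfg <- config
  set.seed(cfg$seed + 53L)
  lay <- variant_layout(cfg)
  Ks <- k_by_sex(cfg)
  b1 <- truth$effects$b1
  h2 <- sum(b1^2)
  resid_sd <- sqrt(max(0, 1 - h2))

  # frequencies and thresholds must match the discovery world
  set.seed(cfg$seed + 23L)  # same draw as the reference panel's mafs
  mafs <- draw_mafs(cfg)
  set.seed(cfg$seed + 53L)
  thr <- stats::qnorm(1 - mafs)
  block_sizes <- as.integer(table(lay$block))
  mu <- 2 * mafs
  sd_theory <- sqrt(pmax(1e-12, 2 * mafs * (1 - mafs)))

  chunk <- max(1000L, cfg$n_cases + cfg$n_controls)
  need_cases <- cfg$n_cases; need_ctrls <- cfg$n_controls
  acc_dose <- list(); acc_phe <- list()
  got_cases <- 0L; got_ctrls <- 0L
  for (it in seq_len(200L)) {
    dose <- draw_block_genotypes(chunk, block_sizes, cfg$ar_rho, thr)
    xs <- sweep(sweep(dose, 2, mu), 2, sd_theory, "/")
    g <- drop(xs %*% b1)
    sex <- ifelse(stats::runif(chunk) < 0.5, "male", "female")
    gs <- ifelse(sex == "female", cfg$sex_effect_scale * g, g)
    liab <- gs + stats::rnorm(chunk, sd = resid_sd)
    # keep liability unit-variance within each sex so the upper-K normal
    # quantile yields prevalence K for both; sex scaling reallocates the
    # genetic share of liability rather than shifting prevalence
    sd_sex <- ifelse(sex == "female",
                     sqrt(cfg$sex_effect_scale^2 * h2 + 1 - h2), 1)
    liab <- liab / sd_sex
    case <- as.integer(liab > stats::qnorm(1 - Ks[sex]))
    take_case <- which(case == 1)[seq_len(min(sum(case == 1),
                                              need_cases - got_cases))]
    take_ctrl <- which(case == 0)[seq_len(min(sum(case == 0),
                                              need_ctrls - got_ctrls))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      acc_dose[[length(acc_dose) + 1L]] <- dose[take, , drop = FALSE]
      acc_phe[[length(acc_phe) + 1L]] <-
        data.frame(case_status = case[take], sex = sex[take],
                   stringsAsFactors = FALSE)
      got_cases <- got_cases + length(take_case)
      got_ctrls <- got_ctrls + length(take_ctrl)
    }
    if (got_cases >= need_cases && got_ctrls >= need_ctrls) break
  }
  if (got_cases < need_cases || got_ctrls < need_ctrls) {
    stop("could not ascertain the requested cohort; ",
         "increase prevalence or reduce n_cases/n_controls")
  }
  dose <- do.call(rbind, acc_dose)
  phe <- do.call(rbind, acc_phe)
  n <- nrow(phe)
  ids <- sprintf("ind%05d", seq_len(n))
  phe <- data.frame(individual_id = ids, phe,
                    age = stats::rnorm(n, 40, 12),
                    stringsAsFactors = FALSE)
  for (k in 1:10) phe[[paste0("mds", k)]] <- stats::rnorm(n)
  map <- lay[, c("variant_id", "chromosome", "position", "counted_allele",
                 "other_allele")]
  map$maf <- mafs
  list(panel = genotype_panel(dose, map, individual_ids = ids),
       phenotypes = phe)
}
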