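#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Computes `p_(i) * m / i` over the sorted p-values, enforces
#' monotonicity from the largest down, and returns the adjusted values
#' in input order. Implemented directly (and cross-checked in the test
#' suite against an independent implementation).
#'
#' @param p_values numeric vector with every element in (0, 1].
#' @return adjusted p-values, same order and length as the input.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  ranks <- rank(p, ties.method = "first")
  ord <- order(ranks, decreasing = TRUE)
  adj <- numeric(m)
  running <- 1
  # step-up: from the largest rank downwards, adj = min(running, p * m / rank)
  for (j in ord) {
    running <- min(running, p[j] * m / ranks[j])
    adj[j] <- running
  }
  adj
}

read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- trimws(kv[1])
    val <- trimws(gsub('^"|"$', "", trimws(kv[2])))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Run the full dissection pipeline on a simulated world
#'
#' Orchestrates simulate -> harmonize -> partition -> clump and the
#' requested analyses (`prs`, `h2`, `cov`, `mr`) on synthetic data with
#' known ground truth, collecting every estimate into a long-format
#' result grid with per-analysis BH-FDR, plus a reproducibility
#' manifest. Stage failures abort with the failing stage named.
#'
#' @param config a [sim_config()], a list of [sim_config()] overrides,
#'   or the path of a `key = value` text file of the same.
#' @param analyses character subset of `c("prs", "h2", "cov", "mr")`.
#' @param prs_thresholds p-value grid for the score analyses.
#' @param alpha conditioning-trait dissection threshold, default 0.05.
#' @param exclude_mhc drop chr6:25-34 Mb before scoring, default TRUE.
#' @param out_dir optional directory: result grid, partition table and
#'   manifest are written there as TSV/JSON.
#' @return list: `grid` (data.frame: analysis, label, method, estimate,
#'   se, p, p_fdr, significant), `partition`, `truth`, `manifest`, and
#'   the per-analysis raw objects.
#' @export
run_pipeline <- function(config = list(),
                         analyses = c("prs", "h2", "cov", "mr"),
                         prs_thresholds = c(5e-8, 5e-5, 1e-3, 0.01, 0.05,
                                            0.1, 0.2, 0.5, 1),
                         alpha = 0.05, exclude_mhc = TRUE, out_dir = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.character(config)) config <- read_config_file(config)
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_msg <- function(...) message("[pleioslice] ", ...)

  log_msg("stage simulate (seed ", config$seed, ", m = ",
          config$m_variants, ")")
  truth <- stage("simulate", simulate_true_effects(config))
  panel <- stage("simulate", simulate_genotype_panel(config))
  gwas <- stage("simulate", simulate_gwas_sumstats(config, truth, panel))

  log_msg("stage harmonize")
  merged <- stage("harmonize", harmonize_pair(gwas$trait1, gwas$trait2))
  if (exclude_mhc) merged <- exclude_region(merged)

  log_msg("stage partition (alpha = ", alpha, ")")
  part <- stage("partition", assign_partitions(merged, alpha = alpha))
  psum <- partition_summary(part)

  results <- list()
  grid_rows <- list()

  ld <- NULL
  if (any(c("h2", "cov") %in% analyses)) {
    log_msg("stage ld-scores")
    ld <- stage("h2", compute_ld_scores(panel, part))
  }
  if ("h2" %in% analyses) {
    log_msg("stage h2")
    fit <- stage("h2", fit_stratified_h2(gwas$trait1, ld, part))
    results$h2 <- fit
    a <- fit$annotations
    grid_rows$h2 <- data.frame(analysis = "h2", label = a$annotation,
                               method = "stratified_ldsc",
                               estimate = a$enrichment, se = a$enrichment_se,
                               p = a$enrichment_p, stringsAsFactors = FALSE)
  }
  if ("cov" %in% analyses) {
    log_msg("stage cov")
    cov_res <- stage("cov", stratified_cross_trait_covariance(
      pair_zscores(merged, 1), pair_zscores(merged, 2), ld, part,
      n1 = config$n_gwas1, n2 = config$n_gwas2))
    results$cov <- cov_res
    grid_rows$cov <- data.frame(analysis = "cov", label = cov_res$annotation,
                                method = "stratified_covariance",
                                estimate = cov_res$rho, se = cov_res$se,
                                p = cov_res$wald_p, stringsAsFactors = FALSE)
  }
  if ("prs" %in% analyses) {
    log_msg("stage cohort + prs")
    cohort <- stage("prs", simulate_target_cohort(config, truth))
    cl <- stage("prs", greedy_clump(retained_pairs(merged), panel,
                                    p_col = "p_1"))
    covars <- cohort$phenotypes[, c("sex", "age", paste0("mds", 1:10))]
    covars$sex <- as.numeric(covars$sex == "female")
    P <- mean(cohort$phenotypes$case_status)
    K <- mean(k_by_sex(config))
    weights_all <- retained_pairs(merged)
    prs_rows <- list()
    for (lab in c("ALL", "noLNL", "CONC", "DISC")) {
      ids <- if (lab == "ALL") part$variant_id else
        part$variant_id[part$partition == lab]
      w <- weights_all[weights_all$variant_id %in% ids, , drop = FALSE]
      w <- data.frame(variant_id = w$variant_id, chromosome = w$chromosome,
                      position = w$position, effect_allele = w$effect_allele,
                      other_allele = w$other_allele, beta = w$beta_1,
                      se = w$se_1, p_value = w$p_1, eaf = w$eaf_1,
                      n = w$n_1, stringsAsFactors = FALSE)
      for (thr in prs_thresholds) {
        fit <- tryCatch({
          sc <- compute_scores(cohort$panel, as_sumstats(w), clump = cl,
                               p_threshold = thr)
          r <- nagelkerke_delta_r2(cohort$phenotypes$case_status, sc$score,
                                   covars)
          data.frame(analysis = "prs", label = lab,
                     method = paste0("p<", format(thr)),
                     estimate = observed_to_liability(max(r$delta_r2, 0),
                                                      K, P),
                     se = NA_real_, p = r$p, stringsAsFactors = FALSE)
        }, error = function(e) NULL)
        if (!is.null(fit)) prs_rows[[paste(lab, thr)]] <- fit
      }
    }
    results$prs_cohort <- cohort
    grid_rows$prs <- do.call(rbind, prs_rows)
  }
  if ("mr" %in% analyses) {
    log_msg("stage mr")
    mr_res <- stage("mr", run_bidirectional(
      gwas$trait2, gwas$trait1, panel,
      config = list(seed = config$seed)))
    results$mr <- mr_res
    g <- mr_res$grid
    grid_rows$mr <- data.frame(analysis = "mr", label = g$direction,
                               method = g$method, estimate = g$beta,
                               se = g$se, p = g$p, stringsAsFactors = FALSE)
  }

  grid <- do.call(rbind, grid_rows)
  rownames(grid) <- NULL
  # FDR families follow the source figure groupings: one family per
  # analysis batch
  grid$p_fdr <- NA_real_
  for (an in unique(grid$analysis)) {
    sel <- grid$analysis == an & !is.na(grid$p)
    grid$p_fdr[sel] <- bh_fdr(pmin(1, pmax(grid$p[sel], 1e-300)))
  }
  grid$significant <- !is.na(grid$p_fdr) & grid$p_fdr < 0.05

  manifest <- list(
    package_version = as.character(utils::packageVersion("pleioslice")),
    config = unclass(config), alpha = alpha,
    analyses = analyses, prs_thresholds = prs_thresholds,
    exclude_mhc = exclude_mhc,
    partition_counts = stats::setNames(as.list(psum$n), psum$partition),
    realized = list(h2_1 = truth$realized_h2_1, h2_2 = truth$realized_h2_2,
                    rg = truth$realized_rg))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(grid, file.path(out_dir, "result_grid.tsv"),
                       sep = "\t", quote = FALSE)
    write_partition(part, file.path(out_dir, "partitions.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(list(grid = grid, partition = part, partition_summary = psum,
         truth = truth, manifest = manifest), results)
}
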