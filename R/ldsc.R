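annotation_frame <- function(annotations) {
  a <- as.data.frame(annotations)
  if (!all(c("variant_id", "partition") %in% names(a))) {
    stop("annotations need columns variant_id and partition")
  }
  data.frame(variant_id = as.character(a$variant_id),
             partition = as.character(a$partition),
             stringsAsFactors = FALSE)
}

#' Compute annotation-stratified LD scores from a reference panel
#'
#' For variant j and annotation c, `l(j,c) = sum_{k in c, |pos_k -
#' pos_j| <= window} r2_adj(j,k)` on the same chromosome, using the
#' unbiased estimator `r2_adj = r2 - (1 - r2)/(n_ref - 2)`. The variant's
#' own (self) term contributes 1 to its total score and to its own
#' annotation's column. Monomorphic variants have no defined correlation
#' and are dropped with a count.
#'
#' @param panel reference [genotype_panel()] (>= 50 individuals
#'   recommended for a stable estimator).
#' @param annotations data.frame `variant_id`, `partition` (e.g. a
#'   [assign_partitions()] result); variants without a label form an
#'   implicit `"other"` category for the per-annotation columns.
#' @param window_kb half-window in kb, default 1000.
#' @return An `ldscore_table` data.frame: `variant_id`, `chromosome`,
#'   `position`, `L_total`, then one `L_<annotation>` column per label;
#'   attributes `n_ref`, `annotation_names`, `n_dropped_monomorphic`.
#' @export
compute_ld_scores <- function(panel, annotations = NULL, window_kb = 1000) {
  map <- panel$map
  x <- panel$dosage
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  sds <- apply(x, 2, stats::sd)
  mono <- sds == 0
  n_dropped <- sum(mono)
  if (n_dropped > 0) {
    x <- x[, !mono, drop = FALSE]
    map <- map[!mono, , drop = FALSE]
  }
  n_ref <- nrow(x)
  x <- scale(x)
  m <- ncol(x)
  window_bp <- window_kb * 1000

  if (is.null(annotations)) {
    ann <- rep("ALL", m)
  } else {
    a <- annotation_frame(annotations)
    ann <- a$partition[match(map$variant_id, a$variant_id)]
    ann[is.na(ann)] <- "other"
  }
  levs <- sort(unique(ann))
  Lc <- matrix(0, nrow = m, ncol = length(levs),
               dimnames = list(NULL, levs))
  Ltot <- numeric(m)

  ord <- order(map$chromosome, map$position)
  pos <- map$position[ord]; chr <- map$chromosome[ord]
  xs <- x[, ord, drop = FALSE]
  anns <- ann[ord]
  adj <- function(r2) r2 - (1 - r2) / (n_ref - 2)
  for (j in seq_len(m)) {
    lo <- j; hi <- j
    while (lo > 1 && chr[lo - 1] == chr[j] &&
           pos[j] - pos[lo - 1] <= window_bp) lo <- lo - 1
    while (hi < m && chr[hi + 1] == chr[j] &&
           pos[hi + 1] - pos[j] <= window_bp) hi <- hi + 1
    nb <- lo:hi
    r <- crossprod(xs[, j], xs[, nb, drop = FALSE]) / (n_ref - 1)
    r2a <- adj(drop(r)^2)
    r2a[nb == j] <- 1  # self term: exact, no bias correction
    Ltot[j] <- sum(r2a)
    tot_c <- tapply(r2a, factor(anns[nb], levels = levs), sum,
                    default = 0)
    Lc[j, ] <- tot_c
  }
  out <- data.frame(variant_id = map$variant_id[ord],
                    chromosome = chr, position = pos,
                    L_total = Ltot, stringsAsFactors = FALSE)
  for (lv in levs) out[[paste0("L_", lv)]] <- Lc[, lv]
  rownames(out) <- NULL  # table is emitted in genome (chromosome, position) order
  structure(out, n_ref = n_ref, annotation_names = levs,
            n_dropped_monomorphic = n_dropped,
            class = c("ldscore_table", "data.frame"))
}

# Weighted least squares with per-block crossproducts, enabling fast
# delete-one-block jackknife refits.
wls_jackknife <- function(X, y, w, blocks) {
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  nb <- max(blocks)
  p <- ncol(X)
  A_tot <- crossprod(Xw)
  b_tot <- crossprod(Xw, yw)
  A_blk <- array(0, dim = c(p, p, nb))
  b_blk <- matrix(0, nrow = p, ncol = nb)
  for (g in seq_len(nb)) {
    sel <- blocks == g
    A_blk[, , g] <- crossprod(Xw[sel, , drop = FALSE])
    b_blk[, g] <- crossprod(Xw[sel, , drop = FALSE], yw[sel])
  }
  theta <- drop(solve(A_tot, b_tot))
  theta_del <- matrix(0, nrow = nb, ncol = p)
  for (g in seq_len(nb)) {
    theta_del[g, ] <- drop(solve(A_tot - A_blk[, , g], b_tot - b_blk[, g]))
  }
  list(coef = theta, delete_one = theta_del, n_blocks = nb)
}

jackknife_se <- function(del) {
  nb <- nrow(del)
  ctr <- colMeans(del)
  sqrt((nb - 1) / nb * colSums(sweep(del, 2, ctr)^2))
}

make_blocks <- function(n, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, n %/% 2L))
  sort(rep_len(seq_len(n_blocks), n))
}

#' Fit stratified LD-score regression for partitioned heritability
#'
#' Regresses per-variant chi-square statistics on annotation LD scores
#' under `E[chi2_j] = N sum_c tau_c l(j,c) + intercept`, with a free
#' intercept and heteroskedasticity weights `1 / (max(L_total, 1) *
#' max(1, chi2_hat)^2)` obtained from a first-pass fit. Per-annotation
#' heritability is `h2_c = tau_c M_c`; enrichment is the h2 share over
#' the SNP share. Standard errors come from a delete-one-block
#' jackknife over genome-contiguous blocks.
#'
#' @param sumstats `sumstats` table for the trait (needs `n` filled).
#' @param ld `ldscore_table` from [compute_ld_scores()].
#' @param annotations data.frame `variant_id`, `partition`; must cover
#'   the regression variants and be disjoint.
#' @param n_blocks jackknife blocks, default 200 (reduced with a
#'   warning when fewer than 10 variants per block are available).
#' @return A `strat_h2` list: `annotations` data.frame (`annotation`,
#'   `M`, `tau`, `tau_se`, `h2`, `h2_se`, `h2_share`, `h2_share_se`,
#'   `snp_share`, `enrichment`, `enrichment_se`, `enrichment_p`),
#'   `h2_total`, `h2_total_se`, `intercept`, `intercept_se`, `n_snps`,
#'   `n_blocks`.
#' @export
fit_stratified_h2 <- function(sumstats, ld, annotations = NULL,
                              n_blocks = 200) {
  ss <- as.data.frame(sumstats)
  idx <- match(ld$variant_id, ss$variant_id)
  keep <- !is.na(idx)
  ldm <- ld[keep, , drop = FALSE]
  ss <- ss[idx[keep], , drop = FALSE]
  m <- nrow(ldm)
  if (m < 20) stop("too few overlapping variants for LD-score regression")
  if (m < 10 * n_blocks) {
    n_blocks <- max(2L, m %/% 10L)
    warning("reduced jackknife blocks to ", n_blocks)
  }
  ord <- order(ldm$chromosome, ldm$position)
  ldm <- ldm[ord, , drop = FALSE]
  ss <- ss[ord, , drop = FALSE]
  chi2 <- (ss$beta / ss$se)^2
  N <- stats::median(ss$n, na.rm = TRUE)
  if (!is.finite(N)) stop("sumstats n column required for h2 estimation")

  if (is.null(annotations)) {
    levs <- "ALL"
    Amat <- matrix(ldm$L_total, ncol = 1, dimnames = list(NULL, "ALL"))
    member <- matrix(TRUE, nrow = m, ncol = 1, dimnames = list(NULL, "ALL"))
  } else {
    a <- annotation_frame(annotations)
    ann <- a$partition[match(ldm$variant_id, a$variant_id)]
    ann[is.na(ann)] <- "other"
    levs <- sort(unique(ann))
    Amat <- as.matrix(ldm[, paste0("L_", levs), drop = FALSE])
    colnames(Amat) <- levs
    member <- outer(ann, levs, "==")
    colnames(member) <- levs
  }
  M_c <- colSums(member)
  if (any(M_c == 0)) stop("annotation with zero variants in regression set")

  X <- cbind(intercept = 1, N * Amat)
  blocks <- make_blocks(m, n_blocks)
  # pass 1: overcounting weights only
  w0 <- 1 / pmax(ldm$L_total, 1)
  fit0 <- stats::lm.wfit(X, chi2, w0)
  pred <- pmax(1, drop(X %*% fit0$coefficients))
  w <- 1 / (pmax(ldm$L_total, 1) * pred^2)
  jk <- wls_jackknife(X, chi2, w, blocks)

  tau <- jk$coef[-1]
  intercept <- jk$coef[1]
  derive <- function(theta) {
    tau_i <- theta[-1]
    h2_i <- tau_i * M_c
    tot <- sum(h2_i)
    share <- if (tot != 0) h2_i / tot else rep(NA_real_, length(h2_i))
    enr <- share / (M_c / m)
    c(theta[1], tau_i, h2_i, tot, share, enr)
  }
  full_stats <- derive(jk$coef)
  del_stats <- t(apply(jk$delete_one, 1, derive))
  ses <- jackknife_se(del_stats)
  k <- length(levs)
  i_tau <- 1 + seq_len(k)
  i_h2 <- 1 + k + seq_len(k)
  i_tot <- 2 + 2 * k
  i_share <- i_tot + seq_len(k)
  i_enr <- i_tot + k + seq_len(k)

  enr <- full_stats[i_enr]
  enr_se <- ses[i_enr]
  enr_p <- 2 * stats::pnorm(-abs((enr - 1) / ifelse(enr_se > 0, enr_se, Inf)))
  tau_se <- ses[i_tau]
  ann_df <- data.frame(
    annotation = levs, M = M_c,
    tau = tau, tau_se = tau_se,
    tau_p = 2 * stats::pnorm(-abs(tau / ifelse(tau_se > 0, tau_se, Inf))),
    h2 = full_stats[i_h2], h2_se = ses[i_h2],
    h2_share = full_stats[i_share], h2_share_se = ses[i_share],
    snp_share = M_c / m,
    enrichment = enr, enrichment_se = enr_se, enrichment_p = enr_p,
    stringsAsFactors = FALSE)
  rownames(ann_df) <- NULL
  structure(list(annotations = ann_df,
                 h2_total = full_stats[i_tot], h2_total_se = ses[i_tot],
                 intercept = full_stats[1], intercept_se = ses[1],
                 n_snps = m, n_gwas = N, n_blocks = jk$n_blocks),
            class = "strat_h2")
}

#' @export
print.strat_h2 <- function(x, ...) {
  cat("stratified LD-score regression: h2 =", signif(x$h2_total, 4),
      "(SE", signif(x$h2_total_se, 3), "), intercept =",
      signif(x$intercept, 4), "\n")
  print(x$annotations[, c("annotation", "M", "h2_share", "enrichment",
                          "enrichment_p")])
  invisible(x)
}

#' Heritability enrichment ratio
#'
#' Enrichment of an annotation is its share of SNP-heritability divided
#' by its share of variants.
#'
#' @param h2_share fraction of total h2 in the annotation.
#' @param snp_share fraction of variants in the annotation (> 0).
#' @return `h2_share / snp_share`.
#' @export
enrichment_ratio <- function(h2_share, snp_share) {
  if (any(snp_share <= 0)) stop("snp_share must be > 0")
  h2_share / snp_share
}

#' One-sided contrast of a gene-set coefficient inside vs outside a partition
#'
#' Tests whether the gene-set annotation's per-variant coefficient (tau)
#' estimated inside a variant partition exceeds the same coefficient
#' estimated outside it, using the jackknife SEs of both fits:
#' `z = (tau_in - tau_out) / sqrt(se_in^2 + se_out^2)`, one-sided
#' `p = P(Z > z)`.
#'
#' @param result_inside,result_outside `strat_h2` fits sharing the
#'   gene-set annotation.
#' @param gene_set_annotation annotation label present in both fits.
#' @return list: `difference`, `se`, `z`, `p`.
#' @export
seg_contrast_test <- function(result_inside, result_outside,
                              gene_set_annotation) {
  pull <- function(res) {
    i <- match(gene_set_annotation, res$annotations$annotation)
    if (is.na(i)) stop("annotation '", gene_set_annotation,
                       "' absent from a fit")
    c(res$annotations$tau[i], res$annotations$tau_se[i])
  }
  a <- pull(result_inside); b <- pull(result_outside)
  diff <- a[1] - b[1]
  se <- sqrt(a[2]^2 + b[2]^2)
  z <- if (se > 0) diff / se else 0
  list(difference = diff, se = se, z = z, p = stats::pnorm(-z))
}

#' Delete-one-block jackknife for a genome-ordered statistic
#'
#' Splits observations (assumed in genome order) into contiguous blocks
#' and recomputes the statistic with each block removed.
#' `SE = sqrt((n-1)/n * sum((theta_(i) - mean)^2))` over the `n`
#' delete-one estimates; p is two-sided normal against zero.
#'
#' @param x vector, matrix or data.frame of observations in genome order.
#' @param statistic_fn function of a subset of `x` returning a scalar.
#' @param n_blocks number of contiguous blocks (>= 2).
#' @return list: `estimate`, `se`, `p`, `delete_one`, `degenerate`
#'   (TRUE when the statistic is constant across blocks, in which case
#'   `p` is reported as 0 with that flag).
#' @export
block_jackknife <- function(x, statistic_fn, n_blocks) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  if (n_blocks < 2) stop("need at least 2 blocks")
  blocks <- make_blocks(n, n_blocks)
  nb <- max(blocks)
  take <- function(sel) if (is.null(dim(x))) x[sel] else x[sel, , drop = FALSE]
  est <- statistic_fn(take(rep(TRUE, n)))
  del <- vapply(seq_len(nb), function(g) statistic_fn(take(blocks != g)),
                numeric(1))
  se <- jackknife_se(matrix(del, ncol = 1))
  degenerate <- se == 0
  p <- if (degenerate) 0 else 2 * stats::pnorm(-abs(est / se))
  list(estimate = est, se = se, p = p, delete_one = del,
       degenerate = degenerate)
}
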