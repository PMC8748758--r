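#' Annotation-stratified cross-trait genetic covariance
#'
#' Method-of-moments fit, restricted to each annotation's variants, of
#' `E[z1_j z2_j] = sqrt(n1 n2) rho_c l(j,c) / M_c + c0`, where the free
#' intercept `c0` absorbs sample overlap and phenotypic correlation.
#' This is cross-trait stratified LD-score regression, functionally
#' standing in for GNOVA's estimator: same estimand, jackknife-based
#' inference. Standard errors come from a delete-one-block jackknife
#' over genome-contiguous blocks inside the annotation; p-values are
#' two-sided Wald tests.
#'
#' @param z1,z2 data.frames with `variant_id` and `z` (z-scores
#'   harmonized to a shared effect allele; use
#'   `with(retained_pairs(m), ...)` with `beta_k/se_k`).
#' @param ld `ldscore_table` from [compute_ld_scores()].
#' @param annotation_set data.frame `variant_id`, `partition`; each
#'   label is fitted separately. `NULL` fits the whole genome as `ALL`.
#' @param n1,n2 GWAS sample sizes of the two traits.
#' @param n_blocks jackknife blocks, default 200 (auto-reduced; an
#'   annotation under 50 variants is an error).
#' @return A `covariance_result` data.frame: `annotation`, `M`, `rho`,
#'   `se`, `z`, `wald_p`.
#' @export
stratified_cross_trait_covariance <- function(z1, z2, ld,
                                              annotation_set = NULL,
                                              n1, n2, n_blocks = 200) {
  z1 <- data.frame(variant_id = as.character(z1$variant_id),
                   z = as.numeric(z1$z), stringsAsFactors = FALSE)
  z2 <- data.frame(variant_id = as.character(z2$variant_id),
                   z = as.numeric(z2$z), stringsAsFactors = FALSE)
  i2 <- match(z1$variant_id, z2$variant_id)
  keep <- !is.na(i2)
  z1 <- z1[keep, ]; z2 <- z2[i2[keep], ]
  il <- match(z1$variant_id, ld$variant_id)
  keep <- !is.na(il)
  z1 <- z1[keep, ]; z2 <- z2[keep, ]
  ldm <- ld[il[keep], , drop = FALSE]
  ord <- order(ldm$chromosome, ldm$position)
  z1 <- z1[ord, ]; z2 <- z2[ord, ]; ldm <- ldm[ord, , drop = FALSE]

  if (is.null(annotation_set)) {
    ann <- rep("ALL", nrow(ldm))
    lcol <- function(lv) ldm$L_total
  } else {
    a <- annotation_frame(annotation_set)
    ann <- a$partition[match(ldm$variant_id, a$variant_id)]
    lcol <- function(lv) {
      col <- paste0("L_", lv)
      if (!col %in% names(ldm)) stop("LD-score table lacks column ", col)
      ldm[[col]]
    }
  }
  levs <- sort(unique(ann[!is.na(ann)]))

  rows <- lapply(levs, function(lv) {
    sel <- which(!is.na(ann) & ann == lv)
    M <- length(sel)
    if (M < 50) stop("annotation '", lv, "' too small (", M, " variants)")
    nb <- n_blocks
    if (M < 10 * nb) nb <- max(2L, M %/% 10L)
    y <- z1$z[sel] * z2$z[sel]
    xv <- sqrt(n1 * n2) * lcol(lv)[sel] / M
    X <- cbind(intercept = 1, rho = xv)
    blocks <- make_blocks(M, nb)
    jk <- wls_jackknife(X, y, rep(1, M), blocks)
    rho <- jk$coef["rho"]
    se <- jackknife_se(jk$delete_one)[2]
    zstat <- if (se > 0) rho / se else 0
    data.frame(annotation = lv, M = M, rho = unname(rho), se = se,
               z = zstat, wald_p = 2 * stats::pnorm(-abs(zstat)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("covariance_result", "data.frame"))
}

#' Z-scores of a harmonized pair table, one trait at a time
#'
#' @param merged `merged_pair` table.
#' @param trait 1 (focal) or 2 (conditioning/secondary).
#' @return data.frame `variant_id`, `z` over retained rows.
#' @export
pair_zscores <- function(merged, trait = 1) {
  d <- retained_pairs(merged)
  if (trait == 1) {
    data.frame(variant_id = d$variant_id, z = d$beta_1 / d$se_1,
               stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = d$variant_id, z = d$beta_2 / d$se_2,
               stringsAsFactors = FALSE)
  }
}
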