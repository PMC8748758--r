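#' Dissect focal-trait variants by their effects in the conditioning trait
#'
#' Labels each harmonized variant by the conditioning-trait p-value and
#' the concordance of effect signs on the shared effect allele:
#' `noLNL` when `p_2 >= alpha`; otherwise `CONC` when the two betas share
#' a sign, `DISC` when they oppose, and `excluded_zero_beta` when either
#' beta is exactly zero (strict sign inequalities define concordance, so
#' a zero fits neither set).
#'
#' @param merged `merged_pair` table from [harmonize_pair()]; only
#'   retained (harmonized) rows are labelled.
#' @param alpha conditioning-trait significance level, default 0.05.
#' @return A `partition_assignment` data.frame with `variant_id`,
#'   `partition`, `p_conditioning`, `sign_focal`, `sign_conditioning`;
#'   attribute `counts` holds per-partition totals.
#' @export
assign_partitions <- function(merged, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  d <- retained_pairs(merged)
  s1 <- sign(d$beta_1)
  s2 <- sign(d$beta_2)
  part <- ifelse(d$p_2 >= alpha, "noLNL",
                 ifelse(s1 * s2 == 1, "CONC",
                        ifelse(s1 * s2 == -1, "DISC", "excluded_zero_beta")))
  out <- data.frame(variant_id = d$variant_id,
                    partition = part,
                    p_conditioning = d$p_2,
                    sign_focal = s1,
                    sign_conditioning = s2,
                    stringsAsFactors = FALSE)
  counts <- table(factor(part, levels = c("noLNL", "CONC", "DISC",
                                          "excluded_zero_beta")))
  structure(out, counts = counts, alpha = alpha,
            class = c("partition_assignment", "data.frame"))
}

#' Partition counts and fractions
#'
#' @param assignment `partition_assignment` from [assign_partitions()].
#' @return data.frame with `partition`, `n`, `fraction` (fractions sum
#'   to 1 over a non-empty assignment).
#' @export
partition_summary <- function(assignment) {
  lv <- c("noLNL", "CONC", "DISC", "excluded_zero_beta")
  n <- as.integer(table(factor(assignment$partition, levels = lv)))
  total <- sum(n)
  data.frame(partition = lv, n = n,
             fraction = if (total > 0) n / total else rep(0, length(lv)),
             stringsAsFactors = FALSE)
}

#' Greedy LD clumping against a reference panel
#'
#' Repeatedly takes the smallest-p unassigned variant as an index and
#' removes every unassigned variant on the same chromosome within
#' `window_kb` of it whose squared dosage correlation in the panel
#' exceeds `r2_threshold`. Ties on p break by (chromosome, position,
#' variant_id) ascending, so the result is deterministic and independent
#' of input row order.
#'
#' @param table data.frame with `variant_id`, `chromosome`, `position`
#'   and a p-value column.
#' @param panel reference [genotype_panel()]; variants absent from it
#'   are dropped with a warning and counted.
#' @param r2_threshold squared-correlation threshold (removal requires
#'   `r2 > r2_threshold`), default 0.1.
#' @param window_kb half-window around the index variant in kb,
#'   default 500.
#' @param p_col name of the ranking p-value column, default `p_value`
#'   (use e.g. `"p_1"` on a merged table).
#' @return A `clump_result` list: `retained` (data.frame in selection
#'   order), `members` (named list of removed partners per index),
#'   `params`, `n_missing_panel`.
#' @export
greedy_clump <- function(table, panel, r2_threshold = 0.1, window_kb = 500,
                         p_col = "p_value") {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!p_col %in% names(table)) stop("no column '", p_col, "' in table")
  d <- data.frame(variant_id = as.character(table$variant_id),
                  chromosome = as.character(table$chromosome),
                  position = as.integer(table$position),
                  p = as.numeric(table[[p_col]]),
                  stringsAsFactors = FALSE)
  in_panel <- d$variant_id %in% panel$map$variant_id
  n_missing <- sum(!in_panel)
  if (n_missing > 0) {
    warning(n_missing, " variant(s) absent from the reference panel; dropped")
    d <- d[in_panel, , drop = FALSE]
  }
  if (nrow(d) == 0) {
    return(structure(list(retained = d[, c("variant_id", "chromosome",
                                           "position", "p")],
                          members = list(),
                          params = list(r2_threshold = r2_threshold,
                                        window_kb = window_kb, p_col = p_col),
                          n_missing_panel = n_missing),
                     class = "clump_result"))
  }
  # deterministic processing order: p, then chromosome, position, id
  ord <- order(d$p, d$chromosome, d$position, d$variant_id)
  d <- d[ord, , drop = FALSE]
  window_bp <- window_kb * 1000

  # centred/scaled dosages for fast correlations (column means imputed)
  x <- panel$dosage[, d$variant_id, drop = FALSE]
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  x <- scale(x)
  nref <- nrow(x)

  state <- rep.int(0L, nrow(d))   # 0 unassigned, 1 retained, 2 removed
  members <- list()
  for (i in seq_len(nrow(d))) {
    if (state[i] != 0L) next
    state[i] <- 1L
    cand <- which(state == 0L & d$chromosome == d$chromosome[i] &
                    abs(d$position - d$position[i]) <= window_bp)
    if (length(cand)) {
      xi <- x[, i]
      if (anyNA(xi)) next  # monomorphic index: no LD computable
      r <- crossprod(xi, x[, cand, drop = FALSE]) / (nref - 1)
      r2 <- drop(r)^2
      r2[is.na(r2)] <- 0
      hit <- cand[r2 > r2_threshold]
      state[hit] <- 2L
      members[[d$variant_id[i]]] <- d$variant_id[hit]
    } else {
      members[[d$variant_id[i]]] <- character(0)
    }
  }
  retained <- d[state == 1L, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(retained = retained, members = members,
                 params = list(r2_threshold = r2_threshold,
                               window_kb = window_kb, p_col = p_col),
                 n_missing_panel = n_missing),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("clump_result:", nrow(x$retained), "index variants (r2 >",
      x$params$r2_threshold, ", +/-", x$params$window_kb, "kb)\n")
  invisible(x)
}

#' Write a partition assignment as a two-column TSV
#' @param assignment `partition_assignment`.
#' @param path output path.
#' @export
write_partition <- function(assignment, path) {
  data.table::fwrite(assignment[, c("variant_id", "partition")], path,
                     sep = "\t", quote = FALSE)
  invisible(path)
}
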