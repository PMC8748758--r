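# Small programmatic fixtures shared across the suite.

toy_sumstats_df <- function(n = 5, seed = 1, chromosome = "1") {
  set.seed(seed)
  data.frame(
    variant_id = paste0("rs", seq_len(n)),
    chromosome = chromosome,
    position = seq_len(n) * 1000L,
    effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C", "C"), length.out = n),
    beta = round(stats::rnorm(n, 0, 0.1), 4),
    se = round(stats::runif(n, 0.01, 0.05), 4),
    p_value = round(stats::runif(n, 0.001, 0.999), 4),
    eaf = round(stats::runif(n, 0.1, 0.9), 4),
    n = 10000,
    stringsAsFactors = FALSE
  )
}

toy_sumstats <- function(...) as_sumstats(toy_sumstats_df(...))

# panel of independent binomial dosages; optionally exact duplicate columns
toy_panel <- function(n_ind = 120, n_var = 10, seed = 1,
                      duplicate = NULL, chromosome = "1",
                      spacing = 1000L) {
  set.seed(seed)
  dose <- matrix(stats::rbinom(n_ind * n_var, 2, 0.4), nrow = n_ind)
  if (!is.null(duplicate)) {
    for (k in seq_along(duplicate)) {
      dose[, duplicate[[k]][2]] <- dose[, duplicate[[k]][1]]
    }
  }
  map <- data.frame(variant_id = paste0("rs", seq_len(n_var)),
                    chromosome = chromosome,
                    position = seq_len(n_var) * spacing,
                    counted_allele = "A", other_allele = "G",
                    stringsAsFactors = FALSE)
  genotype_panel(dose, map)
}

# independent brute-force greedy clump over the full r2 matrix
oracle_clump <- function(table, panel, r2_threshold, window_kb,
                         p_col = "p_value") {
  d <- data.frame(variant_id = as.character(table$variant_id),
                  chromosome = as.character(table$chromosome),
                  position = as.integer(table$position),
                  p = as.numeric(table[[p_col]]),
                  stringsAsFactors = FALSE)
  d <- d[d$variant_id %in% panel$map$variant_id, ]
  d <- d[order(d$p, d$chromosome, d$position, d$variant_id), ]
  x <- panel$dosage[, d$variant_id, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(x))^2
  r2[is.na(r2)] <- 0
  assigned <- rep(FALSE, nrow(d))
  retained <- character(0)
  for (i in seq_len(nrow(d))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    retained <- c(retained, d$variant_id[i])
    for (j in seq_len(nrow(d))) {
      if (assigned[j]) next
      if (d$chromosome[j] == d$chromosome[i] &&
          abs(d$position[j] - d$position[i]) <= window_kb * 1000 &&
          r2[i, j] > r2_threshold) {
        assigned[j] <- TRUE
      }
    }
  }
  retained
}

# independent logistic ML via iteratively reweighted least squares,
# used as the likelihood oracle for the Nagelkerke formula
oracle_logistic_loglik <- function(y, X) {
  X <- cbind(rep(1, length(y)), X)
  b <- rep(0, ncol(X))
  for (it in 1:100) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
    b <- b_new
  }
  eta <- drop(X %*% b)
  sum(y * eta - log(1 + exp(eta)))
}

# a harmonized pair table built directly (bypassing file IO)
make_merged <- function(n = 100, seed = 1, p2 = NULL, beta1 = NULL,
                        beta2 = NULL, chromosome = "1") {
  set.seed(seed)
  if (is.null(beta1)) beta1 <- stats::rnorm(n, 0, 0.1)
  if (is.null(beta2)) beta2 <- stats::rnorm(n, 0, 0.1)
  if (is.null(p2)) p2 <- stats::runif(n)
  t1 <- as_sumstats(data.frame(
    variant_id = paste0("v", seq_len(n)), chromosome = chromosome,
    position = seq_len(n) * 1000L, effect_allele = "A", other_allele = "G",
    beta = beta1, se = 0.02, p_value = stats::runif(n), eaf = 0.3, n = 50000))
  t2 <- as_sumstats(data.frame(
    variant_id = paste0("v", seq_len(n)), chromosome = chromosome,
    position = seq_len(n) * 1000L, effect_allele = "A", other_allele = "G",
    beta = beta2, se = 0.02, p_value = p2, eaf = 0.3, n = 50000))
  harmonize_pair(t1, t2)
}
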