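# Canonical column order for summary-statistics tables.
SUMSTATS_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                   "other_allele", "beta", "se", "p_value", "eaf", "n")
MANDATORY_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                    "other_allele", "beta", "se")

BASES <- c("A", "C", "G", "T")

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Construct a validated GWAS summary-statistics table
#'
#' Applies the field contracts (single-base alleles, `se > 0`, `p` in
#' `(0, 1]`, `eaf` in `[0, 1]`, unique variant ids) and drops offending
#' rows, keeping a per-reason tally in the `"drop_counts"` attribute.
#' Missing p-values are filled from the two-sided normal tail of
#' `z = beta / se`.
#'
#' @param df data.frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `beta`, `se`, and
#'   optionally `p_value`, `eaf`, `n`.
#' @return A `sumstats` data.frame (input row order preserved) with
#'   attributes `drop_counts` (named integer vector) and `n_input`.
#' @export
as_sumstats <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(SUMSTATS_COLS, names(df))) df[[col]] <- NA
  df <- df[, SUMSTATS_COLS]
  df$variant_id <- as.character(df$variant_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("beta", "se", "p_value", "eaf", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  n_input <- nrow(df)

  drops <- c(missing_field = 0L, bad_alleles = 0L, nonpositive_se = 0L,
             p_out_of_range = 0L, eaf_out_of_range = 0L, duplicate_id = 0L)
  bad_missing <- is.na(df$variant_id) | is.na(df$chromosome) |
    is.na(df$position) | is.na(df$beta) | is.na(df$se) |
    is.na(df$effect_allele) | is.na(df$other_allele)
  bad_allele <- !bad_missing &
    (!(df$effect_allele %in% BASES) | !(df$other_allele %in% BASES) |
       df$effect_allele == df$other_allele)
  bad_se <- !bad_missing & !bad_allele & df$se <= 0
  # fill missing p from z before range-checking
  fill <- is.na(df$p_value) & !bad_missing & !bad_se
  df$p_value[fill] <- pmax(2 * stats::pnorm(-abs(df$beta[fill] / df$se[fill])),
                           1e-300)
  bad_p <- !bad_missing & !bad_allele & !bad_se &
    (df$p_value <= 0 | df$p_value > 1)
  bad_eaf <- !bad_missing & !bad_allele & !bad_se & !bad_p &
    (!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1))
  bad <- bad_missing | bad_allele | bad_se | bad_p | bad_eaf
  dup <- duplicated(df$variant_id) & !bad
  drops["missing_field"] <- sum(bad_missing)
  drops["bad_alleles"] <- sum(bad_allele)
  drops["nonpositive_se"] <- sum(bad_se)
  drops["p_out_of_range"] <- sum(bad_p)
  drops["eaf_out_of_range"] <- sum(bad_eaf)
  drops["duplicate_id"] <- sum(dup)

  out <- df[!(bad | dup), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, drop_counts = drops, n_input = n_input,
            class = c("sumstats", "data.frame"))
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or whitespace-delimited file with a header (gzip
#' accepted), renames columns through `column_map`, optionally converts
#' odds ratios to log-odds, and validates the result via [as_sumstats()].
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names
#'   (e.g. `beta`) to column names in the file (e.g. `c(beta = "OR")`).
#'   Columns whose file name already matches are found automatically.
#' @param effect_transform `"none"` (default) or `"log"` to take
#'   `beta = log(value)` for files reporting odds ratios.
#' @return A `sumstats` table; see [as_sumstats()] for attributes.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          effect_transform = c("none", "log")) {
  effect_transform <- match.arg(effect_transform)
  if (!file.exists(path)) stop("cannot read summary-statistics file: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE,
                                        showProgress = FALSE))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop("column_map names missing column '", src, "' for field '",
             canon, "'")
      }
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (effect_transform == "log") df$beta <- log(as.numeric(df$beta))
  as_sumstats(df)
}

#' Write a summary-statistics table to a tab-delimited file
#'
#' Uses a fixed significant-digit float format so output is byte-stable
#' and `read_sumstats(write_sumstats(x))` round-trips field-for-field.
#'
#' @param table `sumstats` table.
#' @param path output path (`.gz` suffix compresses).
#' @export
write_sumstats <- function(table, path) {
  df <- as.data.frame(table)[, SUMSTATS_COLS]
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write summary-statistics file: ", path)
  invisible(path)
}

#' Harmonize two summary-statistics tables onto shared effect alleles
#'
#' Inner-joins the two tables on `variant_id` and re-expresses trait 2 on
#' trait 1's allele coding: identical coding is kept, swapped alleles
#' flip (`beta2 -> -beta2`, `eaf2 -> 1 - eaf2`), strand complements are
#' resolved before either, and anything unresolvable is dropped as a
#' mismatch. Palindromic (A/T, C/G) variants cannot be strand-resolved
#' and are handled by `palindrome_policy`.
#'
#' @param t1,t2 validated `sumstats` tables.
#' @param palindrome_policy `"drop_ambiguous_freq"` (default: drop
#'   palindromic variants whose eaf in either trait is missing or inside
#'   `ambiguous_eaf`), `"drop_all"`, or `"keep"` (literal allele match).
#' @param ambiguous_eaf closed frequency window treated as strand-ambiguous.
#' @return A `merged_pair` data.frame with one row per overlapping
#'   variant: trait-1 coordinates and alleles, `beta_1/se_1/p_1/eaf_1/n_1`,
#'   harmonized `beta_2/se_2/p_2/eaf_2/n_2`, and `harmonization_action`
#'   in `unchanged/flipped/dropped_palindromic/dropped_mismatch`.
#'   Dropped rows keep their label but `NA` trait-2 effects; use
#'   [retained_pairs()] for the analysis-ready subset.
#' @export
harmonize_pair <- function(t1, t2,
                           palindrome_policy = c("drop_ambiguous_freq",
                                                 "drop_all", "keep"),
                           ambiguous_eaf = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  d1 <- as.data.frame(t1)
  d2 <- as.data.frame(t2)
  idx2 <- match(d1$variant_id, d2$variant_id)
  keep <- !is.na(idx2)
  if (!any(keep)) stop("no overlapping variants between the two tables")
  d1 <- d1[keep, , drop = FALSE]
  d2 <- d2[idx2[keep], , drop = FALSE]

  ea1 <- d1$effect_allele; oa1 <- d1$other_allele
  ea2 <- d2$effect_allele; oa2 <- d2$other_allele

  same <- ea2 == ea1 & oa2 == oa1
  swap <- ea2 == oa1 & oa2 == ea1
  csame <- complement_base(ea2) == ea1 & complement_base(oa2) == oa1
  cswap <- complement_base(ea2) == oa1 & complement_base(oa2) == ea1
  pal <- is_palindromic(ea1, oa1)

  action <- rep("dropped_mismatch", nrow(d1))
  # palindromic variants: strand cannot be resolved, so only literal
  # matches are considered, subject to policy
  if (palindrome_policy == "drop_all") {
    action[pal] <- ifelse(same[pal] | swap[pal], "dropped_palindromic",
                          "dropped_mismatch")
  } else if (palindrome_policy == "drop_ambiguous_freq") {
    amb <- function(f) is.na(f) | (f >= ambiguous_eaf[1] & f <= ambiguous_eaf[2])
    ambiguous <- amb(d1$eaf) | amb(d2$eaf)
    ok_pal <- pal & (same | swap)
    action[ok_pal & ambiguous] <- "dropped_palindromic"
    action[ok_pal & !ambiguous & same] <- "unchanged"
    action[ok_pal & !ambiguous & swap] <- "flipped"
  } else { # keep
    action[pal & same] <- "unchanged"
    action[pal & swap] <- "flipped"
  }
  action[!pal & (same | csame)] <- "unchanged"
  action[!pal & (swap | cswap)] <- "flipped"

  beta2 <- d2$beta
  eaf2 <- d2$eaf
  flip <- action == "flipped"
  beta2[flip] <- -beta2[flip]
  eaf2[flip] <- 1 - eaf2[flip]
  dropped <- !(action %in% c("unchanged", "flipped"))
  beta2[dropped] <- NA_real_
  eaf2[dropped] <- NA_real_

  out <- data.frame(
    variant_id = d1$variant_id,
    chromosome = d1$chromosome,
    position = d1$position,
    effect_allele = ea1,
    other_allele = oa1,
    beta_1 = d1$beta, se_1 = d1$se, p_1 = d1$p_value,
    eaf_1 = d1$eaf, n_1 = d1$n,
    beta_2 = beta2, se_2 = ifelse(dropped, NA_real_, d2$se),
    p_2 = ifelse(dropped, NA_real_, d2$p_value),
    eaf_2 = eaf2, n_2 = ifelse(dropped, NA_real_, d2$n),
    harmonization_action = action,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            action_counts = table(factor(action, levels = c(
              "unchanged", "flipped", "dropped_palindromic",
              "dropped_mismatch"))),
            class = c("merged_pair", "data.frame"))
}

#' Retained rows of a harmonized pair table
#'
#' @param merged `merged_pair` table from [harmonize_pair()].
#' @return The rows whose `harmonization_action` is `unchanged` or
#'   `flipped`, i.e. the variants usable downstream.
#' @export
retained_pairs <- function(merged) {
  out <- merged[merged$harmonization_action %in% c("unchanged", "flipped"), ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove variants inside a genomic region
#'
#' Coordinates are 1-based and the interval is closed; a variant at
#' either boundary is removed. The customary use is excluding the
#' extended MHC (chr6:25,000,000-34,000,000 on GRCh37) before scoring.
#'
#' @param table any data.frame with `chromosome` and `position` columns
#'   (`sumstats` and `merged_pair` tables included).
#' @param chromosome chromosome label to match.
#' @param start_bp,end_bp closed interval bounds, `start_bp < end_bp`.
#' @return The table without the matching rows; attribute `n_excluded`
#'   holds the removal count.
#' @export
exclude_region <- function(table, chromosome = "6",
                           start_bp = 25e6, end_bp = 34e6) {
  if (start_bp >= end_bp) stop("start_bp must be < end_bp")
  hit <- table$chromosome == as.character(chromosome) &
    table$position >= start_bp & table$position <= end_bp
  out <- table[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(hit)
  class(out) <- class(table)
  out
}

#' Read a BED-style region file as 1-based closed intervals
#'
#' BED files are 0-based half-open; internally every interval is 1-based
#' closed, so start gains 1 and end is kept.
#'
#' @param path 3+ column BED file (chrom, chromStart, chromEnd), no header.
#' @return data.frame with `chromosome`, `start_bp`, `end_bp`.
#' @export
read_bed_regions <- function(path) {
  bed <- as.data.frame(data.table::fread(path, header = FALSE,
                                         showProgress = FALSE))
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns")
  data.frame(chromosome = sub("^chr", "", as.character(bed[[1]])),
             start_bp = as.integer(bed[[2]]) + 1L,
             end_bp = as.integer(bed[[3]]),
             stringsAsFactors = FALSE)
}
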