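#' Construct a genotype panel
#'
#' A light container for a dosage matrix (individuals x variants, values
#' in `[0, 2]`, `NA` allowed) plus the per-variant map. The counted
#' allele is the allele whose copies the dosage counts; scoring
#' reconciles it against summary-statistics effect alleles.
#'
#' @param dosage numeric matrix, individuals in rows, variants in columns.
#' @param map data.frame with `variant_id`, `chromosome`, `position`,
#'   `counted_allele` and optionally `other_allele`; row order must match
#'   the dosage columns.
#' @param individual_ids optional character vector; defaults to existing
#'   rownames or `ind_1..n`.
#' @return A `genotype_panel` list with elements `dosage`, `map`,
#'   `individual_ids`.
#' @export
genotype_panel <- function(dosage, map, individual_ids = NULL) {
  dosage <- as.matrix(dosage)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (ncol(dosage) != nrow(map)) {
    stop("dosage has ", ncol(dosage), " variants but map has ", nrow(map))
  }
  needed <- c("variant_id", "chromosome", "position", "counted_allele")
  missing_cols <- setdiff(needed, names(map))
  if (length(missing_cols)) {
    stop("panel map missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  map$variant_id <- as.character(map$variant_id)
  map$chromosome <- as.character(map$chromosome)
  map$position <- as.integer(map$position)
  if (anyDuplicated(map$variant_id)) stop("duplicate variant ids in panel map")
  if (is.null(individual_ids)) {
    individual_ids <- rownames(dosage)
    if (is.null(individual_ids)) {
      individual_ids <- paste0("ind_", seq_len(nrow(dosage)))
    }
  }
  dimnames(dosage) <- list(individual_ids, map$variant_id)
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  structure(list(dosage = dosage, map = map,
                 individual_ids = individual_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "variants\n")
  invisible(x)
}

#' Read a plain-text dosage panel
#'
#' Expects two tab-delimited files: a dosage matrix with a header of
#' variant ids and first column `individual_id`, and a variant map with
#' columns `variant_id`, `chromosome`, `position`, `counted_allele`.
#'
#' @param dosage_path,map_path file paths.
#' @return A [genotype_panel()].
#' @export
read_dosage_panel <- function(dosage_path, map_path) {
  d <- as.data.frame(data.table::fread(dosage_path, header = TRUE,
                                       showProgress = FALSE))
  map <- as.data.frame(data.table::fread(map_path, header = TRUE,
                                         showProgress = FALSE))
  ids <- as.character(d[[1]])
  mat <- as.matrix(d[, -1, drop = FALSE])
  map <- map[match(colnames(mat), as.character(map$variant_id)), ,
             drop = FALSE]
  if (anyNA(map$variant_id)) stop("dosage columns missing from map file")
  genotype_panel(mat, map, individual_ids = ids)
}

#' Write a panel as plain-text dosage + map files
#'
#' @param panel a [genotype_panel()].
#' @param dosage_path,map_path output paths.
#' @export
write_dosage_panel <- function(panel, dosage_path, map_path) {
  d <- data.frame(individual_id = panel$individual_ids,
                  panel$dosage, check.names = FALSE)
  data.table::fwrite(d, dosage_path, sep = "\t", quote = FALSE)
  data.table::fwrite(panel$map, map_path, sep = "\t", quote = FALSE)
  invisible(dosage_path)
}

#' Read a PLINK1 binary fileset as a genotype panel
#'
#' Decodes the SNP-major `.bed` 2-bit encoding directly; the counted
#' allele is the bim A1 allele, matching PLINK's convention.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` trio.
#' @return A [genotype_panel()] (missing genotypes as `NA`).
#' @export
read_plink_panel <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE)
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(fam_df); m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file: ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bytes_per_var <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) < bytes_per_var * m) stop("truncated .bed file")
  # per-byte lookup: 4 genotypes, 2 bits each, little-endian pairs;
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  codes <- c(2, NA, 1, 0)
  lut <- matrix(0, nrow = 256, ncol = 4)
  for (b in 0:255) {
    lut[b + 1, ] <- codes[c(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
                            bitwAnd(bitwShiftR(b, 4L), 3L),
                            bitwAnd(bitwShiftR(b, 6L), 3L)) + 1L]
  }
  mat <- matrix(NA_real_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    chunk <- as.integer(body[((j - 1) * bytes_per_var + 1):(j * bytes_per_var)])
    g <- as.vector(t(lut[chunk + 1L, , drop = FALSE]))
    mat[, j] <- g[seq_len(n)]
  }
  map <- data.frame(variant_id = as.character(bim_df[[2]]),
                    chromosome = as.character(bim_df[[1]]),
                    position = as.integer(bim_df[[4]]),
                    counted_allele = as.character(bim_df[[5]]),
                    other_allele = as.character(bim_df[[6]]),
                    stringsAsFactors = FALSE)
  genotype_panel(mat, map, individual_ids = as.character(fam_df[[2]]))
}
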