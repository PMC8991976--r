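#' @importFrom stats rnorm runif rbinom prcomp pt pnorm qnorm sd var predict
#' @importFrom utils head read.table write.table
NULL

# Integer codes for diploid biallelic genotype calls. MISSING is stored as NA
# in the call matrix; the codes below are the non-missing classes.
GT_REF_HOM <- 0L
GT_HET     <- 1L
GT_ALT_HOM <- 2L

#' Genotype call class labels
#'
#' The three non-missing diploid genotype classes, in dosage order of the
#' alternate allele (0, 1, 2).
#' @export
genotype_classes <- function() c("REF_HOM", "HET", "ALT_HOM")

#' Construct a genotype table
#'
#' A genotype table holds diploid biallelic SNP calls for a set of lines
#' (accessions), together with the SNP map giving each marker's chromosome,
#' 1-based base-pair position and ref/alt alleles.
#'
#' @param calls integer matrix, lines x SNPs; values 0 (ref-hom), 1 (het),
#'   2 (alt-hom) or `NA` (missing call).
#' @param line_ids character vector of unique line identifiers (rows).
#' @param snp_map data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`;
#'   one row per SNP, in the column order of `calls`. Positions must be
#'   strictly increasing within a chromosome and ids unique.
#' @return An object of class `genotype_table` with elements `calls`,
#'   `line_ids` and `snp_map`.
#' @export
genotype_table <- function(calls, line_ids, snp_map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  line_ids <- as.character(line_ids)
  stopifnot(is.data.frame(snp_map))
  required <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(required %in% names(snp_map)))
    stop("snp_map must have columns: ", paste(required, collapse = ", "))
  snp_map <- as.data.frame(snp_map)[, required]
  snp_map$chrom <- as.character(snp_map$chrom)
  snp_map$pos <- as.integer(snp_map$pos)
  snp_map$id <- as.character(snp_map$id)
  if (nrow(calls) != length(line_ids))
    stop("calls has ", nrow(calls), " rows but there are ", length(line_ids), " line ids")
  if (ncol(calls) != nrow(snp_map))
    stop("calls has ", ncol(calls), " columns but snp_map has ", nrow(snp_map), " SNPs")
  if (anyDuplicated(line_ids)) stop("duplicate line ids")
  if (anyDuplicated(snp_map$id)) stop("duplicate SNP ids")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("calls must be 0, 1, 2 or NA")
  for (ch in unique(snp_map$chrom)) {
    p <- snp_map$pos[snp_map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on ", ch)
  }
  if (any(snp_map$ref == snp_map$alt)) stop("ref and alt alleles must differ")
  dimnames(calls) <- list(line_ids, snp_map$id)
  structure(list(calls = calls, line_ids = line_ids, snp_map = snp_map),
            class = "genotype_table")
}

#' @export
#' @method print genotype_table
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", length(x$line_ids), " lines x ", nrow(x$snp_map),
      " SNPs on ", length(unique(x$snp_map$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Per-SNP minor allele frequency
#'
#' MAF is computed over non-missing calls only: the alternate-allele
#' frequency is the mean alt-allele dosage / 2, and the minor allele is
#' whichever of ref/alt is rarer. SNPs with all calls missing get `NA`.
#'
#' @param table a [genotype_table()].
#' @return numeric vector, one MAF in \[0, 0.5\] per SNP.
#' @export
snp_maf <- function(table) {
  af <- colMeans(table$calls, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Per-SNP missing-call rate
#' @param table a [genotype_table()].
#' @return numeric vector of missing fractions per SNP.
#' @export
snp_missing_rate <- function(table) colMeans(is.na(table$calls))

#' Per-line missing-call rate
#' @param table a [genotype_table()].
#' @return numeric vector of missing fractions per line.
#' @export
line_missing_rate <- function(table) rowMeans(is.na(table$calls))

#' Alt-allele dosage matrix
#'
#' Returns the lines x SNPs matrix of alternate-allele dosages (0/1/2).
#' Missing calls are either kept as `NA` or imputed to the per-SNP mean
#' dosage, the standard coding for PCA and single-marker scans.
#'
#' @param table a [genotype_table()].
#' @param impute `"none"` or `"mean"`.
#' @return numeric matrix with line ids as rownames and SNP ids as colnames.
#' @export
dosage_matrix <- function(table, impute = c("none", "mean")) {
  impute <- match.arg(impute)
  d <- table$calls
  storage.mode(d) <- "double"
  if (impute == "mean" && anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

#' Subset a genotype table
#'
#' @param table a [genotype_table()].
#' @param lines character vector of line ids or logical/integer row index.
#' @param snps character vector of SNP ids or logical/integer column index.
#' @return a new `genotype_table` in the induced order.
#' @export
subset_table <- function(table, lines = NULL, snps = NULL) {
  ri <- seq_along(table$line_ids)
  ci <- seq_len(nrow(table$snp_map))
  if (!is.null(lines)) {
    ri <- if (is.character(lines)) match(lines, table$line_ids) else ri[lines]
    if (anyNA(ri)) stop("unknown line id(s)")
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, table$snp_map$id) else ci[snps]
    if (anyNA(ci)) stop("unknown SNP id(s)")
  }
  genotype_table(table$calls[ri, ci, drop = FALSE],
                 table$line_ids[ri],
                 table$snp_map[ci, , drop = FALSE])
}

#' Construct a phenotype table
#'
#' One value per line for a single named trait. Categorical values are
#' stored as character labels, continuous ones as numerics.
#'
#' @param line_id character vector of line ids (no duplicates).
#' @param value trait values, character/factor (categorical) or numeric.
#' @param trait_name name of the trait.
#' @param trait_type one of `"binary"`, `"multiclass"`, `"continuous"`.
#' @param class_labels optional explicit label set for categorical traits;
#'   defaults to the sorted unique values.
#' @return a data.frame of class `phenotype_table` with columns `line_id`,
#'   `trait_name`, `value` and attributes `trait_type`, `class_labels`.
#' @export
phenotype_table <- function(line_id, value, trait_name,
                            trait_type = c("binary", "multiclass", "continuous"),
                            class_labels = NULL) {
  trait_type <- match.arg(trait_type)
  line_id <- as.character(line_id)
  if (anyDuplicated(line_id)) stop("duplicate line ids in phenotype table")
  if (length(value) != length(line_id)) stop("value length != line_id length")
  if (trait_type == "continuous") {
    value <- as.numeric(value)
  } else {
    value <- as.character(value)
    if (is.null(class_labels)) class_labels <- sort(unique(value))
    if (trait_type == "binary" && length(class_labels) != 2)
      stop("binary trait must have exactly 2 class labels")
    if (trait_type == "multiclass" && length(class_labels) < 3)
      stop("multiclass trait must have >= 3 class labels")
  }
  out <- data.frame(line_id = line_id, trait_name = trait_name,
                    value = value, stringsAsFactors = FALSE)
  attr(out, "trait_type") <- trait_type
  attr(out, "class_labels") <- class_labels
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Trait type of a phenotype table
#' @param pheno a [phenotype_table()].
#' @return `"binary"`, `"multiclass"` or `"continuous"`.
#' @export
trait_type <- function(pheno) attr(pheno, "trait_type")
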