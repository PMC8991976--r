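# VCF / phenotype I/O and the preprocessing filters applied before model
# building: line-level missingness exclusion, SNP-level MAF and missingness
# filters, sequential thinning, one-hot encoding with an invertible feature
# index, holdout splitting, and region-based SNP extraction.

#' Write a genotype table as VCFv4.2
#'
#' Emits one sample column per line with a GT-only FORMAT field; missing
#' calls are written as `./.`. Contig headers are taken from the map's
#' chromosomes (lengths from the map's `chrom_lengths` attribute when
#' present, otherwise the maximum observed position).
#'
#' @param table a [genotype_table()].
#' @param path output path for the uncompressed VCF text file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  map <- table$snp_map
  chroms <- unique(map$chrom)
  lens <- attr(map, "chrom_lengths")
  if (is.null(lens))
    lens <- vapply(chroms, function(ch) max(map$pos[map$chrom == ch]), numeric(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gsbench",
    sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(lens[chroms])),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$line_ids), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[table$calls + 1L],
                   nrow = nrow(table$calls))
  gt_str[is.na(table$calls)] <- "./."
  body <- paste(map$chrom, map$pos, map$id, map$ref, map$alt, ".", ".", ".",
                "GT", apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF file into a genotype table
#'
#' Accepts diploid biallelic SNP records with GT fields. GT values `0/0`
#' (or `0|0`) map to ref-hom, `0/1`/`1/0` to het, `1/1` to alt-hom and
#' `./.` to missing. Multi-allelic or non-SNP records and malformed GT
#' values are rejected with a message identifying the record.
#'
#' @param vcf_path path to a VCF file (plain or bgzipped).
#' @return a [genotype_table()] with SNPs in file order.
#' @export
read_vcf_to_table <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bad <- which(is.na(alt) | grepl(",", alt) | nchar(ref) != 1 | nchar(alt) != 1)
  if (length(bad))
    stop("non-biallelic-SNP record(s) at ", paste0(fix[bad[1], "CHROM"], ":",
         fix[bad[1], "POS"]), (if (length(bad) > 1) sprintf(" and %d more", length(bad) - 1)))
  gt <- v@gt[, -1, drop = FALSE]  # drop FORMAT column
  line_ids <- colnames(gt)
  # strip any extra colon-separated fields, keep GT
  gt <- sub(":.*$", "", gt)
  gt <- gsub("\\|", "/", gt)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)
  known <- matrix(gt %in% names(code), nrow(gt))
  known[is.na(gt)] <- TRUE  # absent call treated as missing
  if (!all(known)) {
    ij <- which(!known, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt[ij[1], ij[2]], "' at record ", fix[ij[1], "POS"],
         " sample ", line_ids[ij[2]])
  }
  calls <- matrix(code[gt], nrow = nrow(gt))
  calls[is.na(gt)] <- NA_integer_
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == "."))
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix[, "CHROM"], "_", fix[, "POS"]), ids)
  snp_map <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                        id = ids, ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_table(t(calls), line_ids, snp_map)
}

#' Exclude lines by missing-call fraction
#'
#' Retains lines whose fraction of missing calls is at most `max_missing`
#' (lines with *over* the threshold are excluded; the boundary is kept).
#' Line order is preserved.
#'
#' @param table a [genotype_table()].
#' @param max_missing maximum tolerated missing fraction (default 0.01,
#'   i.e. lines with over 1\% missing data are excluded).
#' @return the filtered `genotype_table`; attribute `n_removed` records the
#'   number of excluded lines.
#' @export
filter_lines <- function(table, max_missing = 0.01) {
  keep <- line_missing_rate(table) <= max_missing
  out <- subset_table(table, lines = keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Filter SNPs on minor allele frequency and missingness
#'
#' Retains SNPs with MAF >= `maf_min` (computed over non-missing calls;
#' the minor allele is the rarer one) and missing-call rate strictly below
#' `max_missing_rate`. SNPs whose calls are all missing are removed and
#' counted in the `n_all_missing` attribute.
#'
#' @param table a [genotype_table()].
#' @param maf_min minimum MAF (default 0.05).
#' @param max_missing_rate exclusive upper bound on missing rate (default 0.10).
#' @return the filtered `genotype_table`; attributes `n_removed` and
#'   `n_all_missing` record removal counts.
#' @export
filter_snps <- function(table, maf_min = 0.05, max_missing_rate = 0.10) {
  miss <- snp_missing_rate(table)
  all_missing <- miss >= 1
  maf <- snp_maf(table)
  maf[all_missing] <- -Inf
  keep <- !all_missing & maf >= maf_min & miss < max_missing_rate
  if (any(all_missing))
    message(sum(all_missing), " SNP(s) with all calls missing removed")
  out <- subset_table(table, snps = keep)
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_all_missing") <- sum(all_missing)
  out
}

#' Thin SNPs sequentially
#'
#' Keeps SNPs at ordinal positions 1, 1 + keep_every, 1 + 2*keep_every, ...
#' in genome order — the "1 in k sequential SNPs" density reduction used to
#' shrink marker panels to a tractable input size (the default removes 95\%
#' of SNPs).
#'
#' @param table a [genotype_table()].
#' @param keep_every keep one SNP in this many (>= 1; 1 is the identity).
#' @return the thinned `genotype_table`.
#' @export
thin_sequential <- function(table, keep_every = 20L) {
  if (keep_every < 1) stop("keep_every must be >= 1")
  idx <- seq(1L, nrow(table$snp_map), by = as.integer(keep_every))
  subset_table(table, snps = idx)
}

#' One-hot encode genotype calls
#'
#' Emits, per SNP, one binary indicator column per genotype class observed
#' at that SNP among REF_HOM / HET / ALT_HOM (classes absent from the sample
#' emit no column, avoiding constant features). A missing call encodes as
#' all zeros across that SNP's columns. The feature index is an invertible
#' map from column to (SNP, genotype class, rendered allele pair).
#'
#' @param table a [genotype_table()].
#' @return an object of class `feature_matrix`: list with `values` (lines x
#'   features 0/1 matrix, line ids as rownames, feature ids as colnames) and
#'   `feature_index` (data.frame: `feature_id`, `snp_id`, `class`, `chrom`,
#'   `pos`, `ref`, `alt`, `allele`).
#' @export
one_hot_encode <- function(table) {
  map <- table$snp_map
  m <- nrow(map)
  cls <- genotype_classes()
  blocks <- vector("list", m)
  index <- vector("list", m)
  for (j in seq_len(m)) {
    col <- table$calls[, j]
    present <- sort(unique(col[!is.na(col)]))
    if (length(present) == 0) { blocks[[j]] <- NULL; next }
    b <- matrix(0L, nrow(table$calls), length(present))
    for (k in seq_along(present)) b[, k] <- as.integer(!is.na(col) & col == present[k])
    fid <- paste0(map$id[j], "|", cls[present + 1L])
    colnames(b) <- fid
    blocks[[j]] <- b
    allele <- vapply(present, function(g) switch(as.character(g),
      "0" = paste0(map$ref[j], "/", map$ref[j]),
      "1" = paste0(map$ref[j], "/", map$alt[j]),
      "2" = paste0(map$alt[j], "/", map$alt[j])), character(1))
    index[[j]] <- data.frame(feature_id = fid, snp_id = map$id[j],
                             class = cls[present + 1L], chrom = map$chrom[j],
                             pos = map$pos[j], ref = map$ref[j], alt = map$alt[j],
                             allele = allele, stringsAsFactors = FALSE)
  }
  values <- do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
  if (is.null(values)) values <- matrix(0L, nrow(table$calls), 0)
  rownames(values) <- table$line_ids
  feature_index <- do.call(rbind, index[!vapply(index, is.null, logical(1))])
  if (is.null(feature_index))
    feature_index <- data.frame(feature_id = character(), snp_id = character(),
                                class = character(), chrom = character(),
                                pos = integer(), ref = character(),
                                alt = character(), allele = character())
  rownames(feature_index) <- NULL
  structure(list(values = values, feature_index = feature_index),
            class = "feature_matrix")
}

#' @export
#' @method print feature_matrix
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix: ", nrow(x$values), " lines x ", ncol(x$values),
      " one-hot features (", length(unique(x$feature_index$snp_id)),
      " SNPs)\n", sep = "")
  invisible(x)
}

#' Decode a one-hot feature back to its SNP and genotype
#'
#' Inverts [one_hot_encode()]: given a feature id emitted by the encoder,
#' returns the SNP id, genotype class and the allele pair rendered from the
#' ref/alt alleles (e.g. ALT_HOM at ref=A, alt=T renders as "T/T").
#'
#' @param index the `feature_index` of a [one_hot_encode()] result (or the
#'   `feature_matrix` itself).
#' @param feature_id one or more feature ids.
#' @return data.frame with columns `feature_id`, `snp_id`, `class`,
#'   `chrom`, `pos`, `allele`.
#' @export
decode_feature <- function(index, feature_id) {
  if (inherits(index, "feature_matrix")) index <- index$feature_index
  pos <- match(feature_id, index$feature_id)
  if (anyNA(pos))
    stop("unknown feature id(s): ",
         paste(feature_id[is.na(pos)], collapse = ", "))
  index[pos, c("feature_id", "snp_id", "class", "chrom", "pos", "allele")]
}

#' Random holdout split
#'
#' Excludes a fraction of lines uniformly at random (without replacement)
#' as a holdout set used only for final evaluation; the rest form the
#' training set. The holdout size is round-half-up of `fraction * n`.
#'
#' @param line_ids character vector of line ids (>= 5).
#' @param fraction holdout fraction in (0, 1); default 0.2.
#' @param seed integer seed; the split is deterministic given the seed.
#' @param stratify_by optional vector (same length as `line_ids`) of class
#'   labels; when given, sampling is proportional within each class.
#' @return list of class `holdout_split` with `train_line_ids`,
#'   `holdout_line_ids`, `seed`.
#' @export
holdout_split <- function(line_ids, fraction = 0.2, seed = 1L, stratify_by = NULL) {
  n <- length(line_ids)
  if (n < 5) stop("need at least 5 lines to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_hold <- floor(fraction * n + 0.5)
  if (n_hold < 1 || n_hold >= n)
    stop("fraction ", fraction, " yields an empty train or holdout set at n = ", n)
  set.seed(as.integer(seed))
  if (is.null(stratify_by)) {
    hold <- sample(line_ids, n_hold)
  } else {
    stopifnot(length(stratify_by) == n)
    hold <- unlist(lapply(split(line_ids, stratify_by), function(ids) {
      k <- floor(length(ids) * fraction + 0.5)
      sample(ids, min(k, length(ids) - 1L))
    }), use.names = FALSE)
  }
  structure(list(train_line_ids = setdiff(line_ids, hold),
                 holdout_line_ids = hold, seed = as.integer(seed)),
            class = "holdout_split")
}

#' Construct a region set
#'
#' Closed 1-based genomic intervals (VCF convention) used to extract SNP
#' subsets.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start <= end`, both inclusive.
#' @return data.frame of class `region_set` with columns `chrom`, `start`,
#'   `end`.
#' @export
region_set <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("region start must be <= end")
  if (any(start < 1)) stop("regions are 1-based; start must be >= 1")
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("region_set", "data.frame"))
}

#' Extract SNPs falling in a set of regions
#'
#' Retains exactly the SNPs whose (chrom, pos) falls inside any closed
#' interval of the region set, preserving genome order; a SNP covered by
#' several regions is kept once.
#'
#' @param table a [genotype_table()].
#' @param regions a [region_set()]; must be non-empty and reference only
#'   chromosomes present in the table's map.
#' @return the reduced `genotype_table`; attribute `retained_fraction`
#'   records the fraction of SNPs kept.
#' @export
extract_regions <- function(table, regions) {
  if (!nrow(regions)) stop("empty region set")
  unknown <- setdiff(unique(regions$chrom), unique(table$snp_map$chrom))
  if (length(unknown))
    stop("region on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  map <- table$snp_map
  keep <- rep(FALSE, nrow(map))
  for (i in seq_len(nrow(regions))) {
    keep <- keep | (map$chrom == regions$chrom[i] &
                    map$pos >= regions$start[i] & map$pos <= regions$end[i])
  }
  out <- subset_table(table, snps = keep)
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Write / read a region set as TSV
#'
#' Three-column TSV (chrom, start, end); coordinates are 1-based closed
#' intervals, stated in the header comment.
#'
#' @param regions a [region_set()].
#' @param path file path.
#' @return `path` (write) or a `region_set` (read).
#' @export
write_regions <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend (1-based, closed intervals)", con)
  write.table(regions, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("chrom", "start", "end"),
                   stringsAsFactors = FALSE)
  region_set(df$chrom, df$start, df$end)
}

#' Write / read a phenotype table as CSV
#'
#' Headered CSV with columns `line_id`, `trait_name`, `value`; categorical
#' values as strings, continuous as decimals.
#'
#' @param pheno a [phenotype_table()].
#' @param path file path.
#' @param trait_type trait type to assume when reading (`"auto"` infers:
#'   numeric-parseable values are continuous, otherwise categorical).
#' @return `path` (write) or a `phenotype_table` (read).
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno)[, c("line_id", "trait_name", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path, trait_type = "auto") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(line_id = "character", value = "character"))
  vals <- df$value
  num <- suppressWarnings(as.numeric(vals))
  if (trait_type == "auto")
    trait_type <- if (!anyNA(num)) "continuous" else
      if (length(unique(vals)) == 2) "binary" else "multiclass"
  if (trait_type == "continuous") vals <- num
  phenotype_table(df$line_id, vals, df$trait_name[1], trait_type)
}

#' Write the genotype table as a structured CSV
#'
#' Lines as rows, SNP ids as column headers, calls rendered as allele pairs
#' (e.g. "A/T"); missing calls rendered as "./.". Mirrors the tab-separated
#' genotype export commonly produced from a VCF before model building.
#'
#' @param table a [genotype_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(table, path) {
  map <- table$snp_map
  out <- matrix("./.", nrow(table$calls), ncol(table$calls))
  for (g in 0:2) {
    idx <- which(!is.na(table$calls) & table$calls == g, arr.ind = TRUE)
    if (!nrow(idx)) next
    a1 <- if (g == 2) map$alt else map$ref
    a2 <- if (g == 0) map$ref else map$alt
    out[idx] <- paste0(a1[idx[, 2]], "/", a2[idx[, 2]])
  }
  df <- data.frame(line_id = table$line_ids, out, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("line_id", map$id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
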