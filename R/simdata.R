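# Synthetic genotype/phenotype generator.
#
# The generator emulates the statistical structure a marker-based prediction
# study assumes: many biallelic SNPs with base-pair positions on several
# chromosomes, a bounded minor-allele-frequency spectrum, local LD blocks,
# sporadic missing calls, near-Mendelian categorical traits driven by one or
# two major loci, and polygenic continuous traits at a target heritability.

#' Simulate a genome map
#'
#' Draws `snps_per_chrom` distinct SNP positions uniformly on each of
#' `n_chrom` chromosomes of length `chrom_length_bp`, sorts them, and
#' assigns ref/alt alleles drawn from A/C/G/T (always distinct).
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param snps_per_chrom SNPs per chromosome (>= 1).
#' @param chrom_length_bp chromosome length in bp (>= snps_per_chrom).
#' @param seed integer seed; the map is deterministic given the arguments.
#' @return data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   positions strictly increasing within a chromosome.
#' @export
simulate_genome_map <- function(n_chrom, snps_per_chrom, chrom_length_bp, seed = 1L) {
  if (n_chrom < 1 || snps_per_chrom < 1 || chrom_length_bp < 1)
    stop("n_chrom, snps_per_chrom and chrom_length_bp must all be >= 1")
  if (chrom_length_bp < snps_per_chrom)
    stop("chrom_length_bp too small for ", snps_per_chrom, " distinct positions")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  maps <- lapply(seq_len(n_chrom), function(ci) {
    chrom <- sprintf("chr%02d", ci)
    pos <- sort(sample.int(chrom_length_bp, snps_per_chrom))
    ref <- sample(bases, snps_per_chrom, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    data.frame(chrom = chrom, pos = pos,
               id = sprintf("%s_%09d", chrom, pos),
               ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <-
    stats::setNames(rep(chrom_length_bp, n_chrom), sprintf("chr%02d", seq_len(n_chrom)))
  out
}

#' Simulation configuration
#'
#' @param n_lines number of lines (accessions) to simulate.
#' @param maf_range length-2 numeric in (0, 0.5\]: target minor allele
#'   frequencies are drawn uniformly from this range.
#' @param ld_block_span_bp span of an LD block in bp; chromosomes are tiled
#'   into blocks of this width and SNPs within a block share a latent
#'   haplotype signal.
#' @param within_block_correlation latent haplotype correlation in \[0, 1):
#'   0 gives independent SNPs, values near 1 give strong local LD.
#' @param missing_rate per-call missing probability in \[0, 0.1).
#' @param n_subpop 1 (default, no structure) or 2 for a two-subpopulation
#'   mode used to exercise PC covariates in the association scan.
#' @param subpop_divergence allele-frequency divergence between the two
#'   subpopulations (each subpopulation's allele frequency is shifted by
#'   +/- half this amount, clipped to \[0.01, 0.99\]).
#' @param seed integer seed fixing all downstream randomness.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 500L,
                       maf_range = c(0.05, 0.5),
                       ld_block_span_bp = 150000L,
                       within_block_correlation = 0.8,
                       missing_rate = 0.005,
                       n_subpop = 1L,
                       subpop_divergence = 0,
                       seed = 1L) {
  stopifnot(n_lines >= 2, length(maf_range) == 2)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  if (within_block_correlation < 0 || within_block_correlation >= 1)
    stop("within_block_correlation must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 0.1)
    stop("missing_rate must be in [0, 0.1)")
  if (!n_subpop %in% c(1L, 2L)) stop("n_subpop must be 1 or 2")
  structure(list(n_lines = as.integer(n_lines), maf_range = maf_range,
                 ld_block_span_bp = as.integer(ld_block_span_bp),
                 within_block_correlation = within_block_correlation,
                 missing_rate = missing_rate, n_subpop = as.integer(n_subpop),
                 subpop_divergence = subpop_divergence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes on a genome map
#'
#' Each line receives two haplotypes. Within each LD block (a tile of
#' `ld_block_span_bp` on the chromosome) a haplotype carries one latent
#' Gaussian signal; each SNP's allele indicator thresholds a mixture of the
#' block signal and independent per-SNP noise, so the per-SNP allele
#' frequency exactly matches its target while adjacent SNPs inside a block
#' are correlated (tunable local r-squared) and SNPs in different blocks are
#' independent. Genotype = sum of the two allele draws (near Hardy-Weinberg).
#' Missing calls are dropped uniformly at random at `missing_rate`.
#'
#' @param map genome map from [simulate_genome_map()].
#' @param cfg a [sim_config()].
#' @return a [genotype_table()] of `cfg$n_lines` x `nrow(map)` calls.
#' @export
simulate_genotypes <- function(map, cfg) {
  if (!is.data.frame(map) || nrow(map) == 0) stop("empty genome map")
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_lines
  m <- nrow(map)
  # target alt-allele frequencies: draw MAF then randomly orient
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  flip <- runif(m) < 0.5
  p_alt <- ifelse(flip, 1 - maf, maf)
  # subpopulation-specific frequencies
  if (cfg$n_subpop == 2L) {
    half <- cfg$subpop_divergence / 2
    p_sub <- cbind(pmin(pmax(p_alt - half, 0.01), 0.99),
                   pmin(pmax(p_alt + half, 0.01), 0.99))
    subpop <- rep(c(1L, 2L), length.out = n)
  } else {
    p_sub <- cbind(p_alt, p_alt)
    subpop <- rep(1L, n)
  }
  block <- paste0(map$chrom, "_b", map$pos %/% cfg$ld_block_span_bp)
  block_id <- match(block, unique(block))
  n_block <- max(block_id)
  rho <- cfg$within_block_correlation
  calls <- matrix(0L, n, m)
  for (hap in 1:2) {
    z_block <- matrix(rnorm(n * n_block), n, n_block)
    eps <- matrix(rnorm(n * m), n, m)
    latent <- sqrt(rho) * z_block[, block_id, drop = FALSE] + sqrt(1 - rho) * eps
    thr <- qnorm(t(p_sub[, subpop, drop = FALSE]))  # n x m per-line thresholds
    calls <- calls + (latent < thr)
  }
  storage.mode(calls) <- "integer"
  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(n * m) < cfg$missing_rate, n, m)
    calls[drop] <- NA_integer_
  }
  tab <- genotype_table(calls, sprintf("line%04d", seq_len(n)), map)
  attr(tab, "subpop") <- subpop
  tab
}

#' Trait model
#'
#' Describes how a trait arises from causal loci.
#'
#' For categorical kinds, `causal_loci` is a named list mapping SNP id to a
#' penetrance matrix: 3 rows (REF_HOM, HET, ALT_HOM) x `n_classes` columns,
#' each row a probability distribution over class labels. With two causal
#' loci the per-locus class distributions are averaged before sampling.
#'
#' For `polygenic-continuous`, `causal_loci` is a data.frame with columns
#' `snp` and `effect` (effect per alt-allele dosage on the 0/1/2 scale).
#'
#' @param kind one of `"monogenic-categorical"`, `"oligogenic-categorical"`,
#'   `"polygenic-continuous"`.
#' @param causal_loci see Details.
#' @param heritability target h-squared in \[0, 1\] (continuous only).
#' @param n_classes number of classes (categorical only, >= 2).
#' @param class_labels optional class label vector (categorical only).
#' @return a list of class `trait_model`.
#' @export
trait_model <- function(kind = c("monogenic-categorical", "oligogenic-categorical",
                                 "polygenic-continuous"),
                        causal_loci, heritability = NULL, n_classes = NULL,
                        class_labels = NULL) {
  kind <- match.arg(kind)
  if (kind == "polygenic-continuous") {
    stopifnot(is.data.frame(causal_loci), all(c("snp", "effect") %in% names(causal_loci)))
    if (is.null(heritability) || heritability < 0 || heritability > 1)
      stop("heritability must be in [0, 1] for continuous traits")
  } else {
    stopifnot(is.list(causal_loci), length(causal_loci) >= 1, !is.null(names(causal_loci)))
    n_loci_max <- if (kind == "monogenic-categorical") 1L else 2L
    if (length(causal_loci) > n_loci_max)
      stop(kind, " allows at most ", n_loci_max, " causal loci")
    for (pen in causal_loci) {
      pen <- as.matrix(pen)
      if (nrow(pen) != 3) stop("penetrance matrix needs 3 rows (REF_HOM, HET, ALT_HOM)")
      if (any(abs(rowSums(pen) - 1) > 1e-8)) stop("penetrance rows must sum to 1")
      if (is.null(n_classes)) n_classes <- ncol(pen)
      if (ncol(pen) != n_classes) stop("penetrance columns must equal n_classes")
    }
    if (n_classes < 2) stop("n_classes must be >= 2")
    if (is.null(class_labels)) class_labels <- paste0("class", seq_len(n_classes))
  }
  structure(list(kind = kind, causal_loci = causal_loci,
                 heritability = heritability, n_classes = n_classes,
                 class_labels = class_labels),
            class = "trait_model")
}

#' Dominant two-class penetrance matrix
#'
#' Convenience constructor for a near-Mendelian dominant trait: carriers of
#' the alt allele (HET or ALT_HOM) show class 2 with probability
#' `penetrance`, non-carriers show class 1 with the same probability.
#' `penetrance = 1` gives a fully deterministic (degenerate) trait.
#'
#' @param penetrance probability in (0.5, 1\] of showing the genotype's class.
#' @return 3 x 2 penetrance matrix.
#' @export
dominant_penetrance <- function(penetrance = 1) {
  stopifnot(penetrance > 0.5, penetrance <= 1)
  rbind(REF_HOM = c(penetrance, 1 - penetrance),
        HET     = c(1 - penetrance, penetrance),
        ALT_HOM = c(1 - penetrance, penetrance))
}

.causal_dosages <- function(genotypes, snp_ids) {
  idx <- match(snp_ids, genotypes$snp_map$id)
  if (anyNA(idx))
    stop("causal locus absent from genotype table: ",
         paste(snp_ids[is.na(idx)], collapse = ", "))
  d <- genotypes$calls[, idx, drop = FALSE]
  storage.mode(d) <- "double"
  # a missing call at a causal locus acts through the mean dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    ij <- which(is.na(d), arr.ind = TRUE)
    d[ij] <- mu[ij[, 2]]
  }
  d
}

#' Simulate a categorical trait
#'
#' Each line's class label is drawn from the penetrance row selected by its
#' genotype at the causal locus (per-locus class distributions are averaged
#' when there are two loci). Missing causal calls use the rounded mean
#' dosage.
#'
#' @param genotypes a [genotype_table()].
#' @param trait a categorical [trait_model()].
#' @param seed integer seed.
#' @param trait_name trait name for the output table.
#' @return a [phenotype_table()] with one label per line.
#' @export
simulate_categorical_trait <- function(genotypes, trait, seed = 1L,
                                       trait_name = "trait") {
  stopifnot(inherits(trait, "trait_model"))
  if (trait$kind == "polygenic-continuous")
    stop("trait kind must be categorical")
  set.seed(as.integer(seed))
  d <- .causal_dosages(genotypes, names(trait$causal_loci))
  d <- round(d)
  n <- nrow(d)
  k <- trait$n_classes
  probs <- matrix(0, n, k)
  for (j in seq_along(trait$causal_loci)) {
    pen <- as.matrix(trait$causal_loci[[j]])
    probs <- probs + pen[d[, j] + 1L, , drop = FALSE]
  }
  probs <- probs / length(trait$causal_loci)
  u <- runif(n)
  cum <- t(apply(probs, 1, cumsum))
  cls <- 1L + rowSums(u > cum + 1e-12)
  cls <- pmin(cls, k)
  ttype <- if (k == 2) "binary" else "multiclass"
  phenotype_table(genotypes$line_ids, trait$class_labels[cls], trait_name,
                  ttype, class_labels = trait$class_labels)
}

#' Simulate a polygenic continuous trait
#'
#' The genetic value of a line is the sum over causal loci of alt-allele
#' dosage times effect size. Gaussian noise is added with variance scaled so
#' the genetic variance fraction matches the target heritability, then the
#' trait is shifted so its mean is strictly positive (three genetic-scale
#' standard deviations above zero), since the error metric downstream
#' divides by the trait mean.
#'
#' @param genotypes a [genotype_table()].
#' @param trait a `polygenic-continuous` [trait_model()].
#' @param seed integer seed.
#' @param trait_name trait name for the output table.
#' @return a [phenotype_table()]; attribute `genetic_value` carries the true
#'   per-line genetic values for calibration checks.
#' @export
simulate_continuous_trait <- function(genotypes, trait, seed = 1L,
                                      trait_name = "trait") {
  stopifnot(inherits(trait, "trait_model"))
  if (trait$kind != "polygenic-continuous")
    stop("trait kind must be polygenic-continuous")
  h2 <- trait$heritability
  if (h2 < 0 || h2 > 1) stop("heritability must be in [0, 1]")
  set.seed(as.integer(seed))
  d <- .causal_dosages(genotypes, trait$causal_loci$snp)
  g <- as.numeric(d %*% trait$causal_loci$effect)
  vg <- var(g)
  if (vg == 0 && h2 > 0)
    stop("causal loci are monomorphic: genetic variance is zero")
  n <- length(g)
  if (h2 == 0) {
    scale_sd <- if (vg > 0) sqrt(vg) else 1
    y <- rnorm(n, 0, scale_sd)
    g_used <- rep(0, n)
  } else if (h2 == 1) {
    y <- g
    g_used <- g
  } else {
    ve <- vg * (1 - h2) / h2
    y <- g + rnorm(n, 0, sqrt(ve))
    g_used <- g
  }
  y <- y - mean(y) + 3 * sd(y)  # strictly positive mean
  out <- phenotype_table(genotypes$line_ids, y, trait_name, "continuous")
  attr(out, "genetic_value") <- g_used
  out
}
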