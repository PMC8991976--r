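# Shared fixture builders: tables constructed in code, no stored binaries.

# a small simulated table with defaults tuned for fast tests
toy_table <- function(n_lines = 30, n_snps = 40, n_chrom = 2, seed = 1,
                      missing_rate = 0.02, ...) {
  map <- simulate_genome_map(n_chrom, ceiling(n_snps / n_chrom), 2e6,
                             seed = seed)
  simulate_genotypes(map, sim_config(n_lines = n_lines,
                                     missing_rate = missing_rate,
                                     seed = seed + 1, ...))
}

# a fully random table (uniform random calls incl. missing) for fuzz tests;
# unlike toy_table it has no LD or HWE structure
random_table <- function(seed, n_lines = 20, n_snps = 50, p_missing = 0.1) {
  set.seed(seed)
  pos <- sort(sample.int(1e6, n_snps))
  map <- data.frame(chrom = "chr01", pos = pos,
                    id = sprintf("s%04d", seq_len(n_snps)),
                    ref = "A", alt = "T", stringsAsFactors = FALSE)
  calls <- matrix(sample(c(0:2, NA), n_lines * n_snps, replace = TRUE,
                         prob = c(rep((1 - p_missing) / 3, 3), p_missing)),
                  n_lines, n_snps)
  genotype_table(calls, sprintf("L%03d", seq_len(n_lines)), map)
}

# build a table directly from a call matrix on a default single-chromosome map
table_from_calls <- function(calls, pos = NULL) {
  n_snps <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n_snps) * 1000L
  map <- data.frame(chrom = "chr01", pos = pos,
                    id = sprintf("s%04d", seq_len(n_snps)),
                    ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_table(calls, sprintf("L%03d", seq_len(nrow(calls))), map)
}

# a monogenic fully-penetrant trait; the causal SNP is chosen with alt-allele
# frequency nearest 0.35 so both phenotype classes are well populated
monogenic_setup <- function(n_lines = 300, n_snps = 100, seed = 7,
                            penetrance = 1, ...) {
  map <- simulate_genome_map(1, n_snps, 5e6, seed = seed)
  tab <- simulate_genotypes(map, sim_config(n_lines = n_lines,
                                            missing_rate = 0,
                                            seed = seed + 1, ...))
  alt_freq <- colMeans(tab$calls) / 2
  causal <- map$id[which.min(abs(alt_freq - 0.35))]
  tm <- trait_model("monogenic-categorical",
                    stats::setNames(list(dominant_penetrance(penetrance)), causal))
  ph <- simulate_categorical_trait(tab, tm, seed = seed + 2)
  list(table = tab, map = map, causal = causal, pheno = ph)
}

# align phenotype values to a table's line order
pheno_vector <- function(pheno, table) {
  pheno$value[match(table$line_ids, pheno$line_id)]
}

# exhaustive ROI oracle: all-pairs gap graph, connected components via BFS,
# distinct-SNP size filter (independent of cluster_rois' chaining)
oracle_rois <- function(ranked, max_gap_bp = 100000, min_size = 3) {
  agg <- unique(ranked[, c("snp_id", "chrom", "pos")])
  out <- list()
  for (ch in unique(agg$chrom)) {
    sub <- agg[agg$chrom == ch, ]
    n <- nrow(sub)
    adj <- abs(outer(sub$pos, sub$pos, "-")) <= max_gap_bp
    seen <- rep(FALSE, n)
    for (s in seq_len(n)) {
      if (seen[s]) next
      comp <- s
      queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & !seen)
        seen[nb] <- TRUE
        comp <- c(comp, nb); queue <- c(queue, nb)
      }
      if (length(comp) >= min_size)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = min(sub$pos[comp]), end = max(sub$pos[comp]),
          n_snps = length(comp))
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer(), n_snps = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), ]
}
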