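test_that("VCF write then read is the identity", {
  tab <- toy_table(n_lines = 12, n_snps = 30, seed = 3)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(tab, path)
  back <- read_vcf_to_table(path)
  expect_identical(back$calls, tab$calls)
  expect_identical(back$line_ids, tab$line_ids)
  expect_equal(back$snp_map, tab$snp_map, ignore_attr = TRUE)
})

test_that("a hand-written VCF fixture parses to the expected calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "chr1\t100\tsnp1\tA\tT\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tsnp2\tG\tC\t.\t.\t.\tGT\t./.\t1/0\t0/0"), path)
  tab <- read_vcf_to_table(path)
  expect_equal(unname(tab$calls[, "snp1"]), c(0L, 1L, 2L))
  expect_equal(unname(tab$calls[, "snp2"]), c(NA_integer_, 1L, 0L))
  expect_identical(tab$line_ids, c("A", "B", "C"))
  expect_identical(tab$snp_map$ref, c("A", "G"))
})

test_that("multi-allelic and malformed records are rejected with identifying messages", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA",
    "chr1\t100\tsnp1\tA\tT,G\t.\t.\t.\tGT\t0/1"), path)
  expect_error(read_vcf_to_table(path), "chr1:100")

  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA",
    "chr1\t100\tsnp1\tAC\tT\t.\t.\t.\tGT\t0/1"), path)
  expect_error(read_vcf_to_table(path), "SNP")

  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA",
    "chr1\t100\tsnp1\tA\tT\t.\t.\t.\tGT\t0/3"), path)
  expect_error(read_vcf_to_table(path), "malformed GT")
})

test_that("line filter excludes strictly-over-threshold lines only", {
  calls <- matrix(0L, 3, 100)
  calls[2, 1:2] <- NA  # 2% missing -> excluded (over 1%)
  calls[3, 1] <- NA    # exactly 1% -> retained
  tab <- table_from_calls(calls)
  out <- filter_lines(tab)
  expect_identical(out$line_ids, c("L001", "L003"))
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("SNP filter applies MAF and missing-rate rules", {
  calls <- matrix(1L, 100, 4)              # all-HET: MAF 0.5
  calls[1:9, 2] <- 1L; calls[, 2] <- 0L; calls[1:9, 2] <- 1L  # 9 alt / 200 = 0.045
  calls[1:11, 3] <- NA                     # 11% missing
  calls[, 4] <- NA                         # all missing
  tab <- table_from_calls(calls)
  expect_message(out <- filter_snps(tab), "all calls missing")
  expect_identical(out$snp_map$id, "s0001")
  expect_equal(attr(out, "n_removed"), 3L)
  expect_equal(attr(out, "n_all_missing"), 1L)
})

test_that("filters match a naive per-cell recount on fuzzed tables", {
  for (s in 1:300) {
    tab <- random_table(s)
    out <- filter_snps(filter_lines(tab, 0.1), 0.2, 0.3)
    # naive oracle: recount per cell
    keep_lines <- apply(tab$calls, 1, function(r) mean(is.na(r)) <= 0.1)
    sub <- tab$calls[keep_lines, , drop = FALSE]
    keep_snps <- apply(sub, 2, function(col) {
      nm <- col[!is.na(col)]
      if (!length(nm)) return(FALSE)
      af <- sum(nm) / (2 * length(nm))
      min(af, 1 - af) >= 0.2 && mean(is.na(col)) < 0.3
    })
    expect_identical(out$calls,
                     tab$calls[keep_lines, keep_snps, drop = FALSE])
  }
})

test_that("sequential thinning keeps 1-in-k SNPs in genome order", {
  tab <- table_from_calls(matrix(0L, 2, 10000))
  thinned <- thin_sequential(tab, 20)
  expect_equal(nrow(thinned$snp_map), 500)
  expect_identical(thinned$snp_map$id, tab$snp_map$id[seq(1, 10000, by = 20)])

  expect_identical(thin_sequential(tab, 1)$snp_map, tab$snp_map)
  tab23 <- table_from_calls(matrix(0L, 2, 23))
  expect_equal(nrow(thin_sequential(tab23, 20)$snp_map), 2)
  expect_error(thin_sequential(tab, 0), "keep_every")
})

test_that("filters then thinning equals recomputation on the surviving subset", {
  tab <- random_table(99, n_lines = 40, n_snps = 80)
  a <- thin_sequential(filter_snps(filter_lines(tab, 0.1), 0.1, 0.3), 3)
  keep_lines <- line_missing_rate(tab) <= 0.1
  manual <- subset_table(tab, lines = keep_lines)
  keep <- snp_maf(manual) >= 0.1 & snp_missing_rate(manual) < 0.3 &
    snp_missing_rate(manual) < 1
  manual <- subset_table(manual, snps = which(keep)[seq(1, sum(keep), by = 3)])
  expect_identical(a$calls, manual$calls)
})

test_that("one-hot encoding produces the identity pattern and invertible index", {
  calls <- matrix(c(0L, 1L, 2L), 3, 1)
  tab <- table_from_calls(calls)
  fm <- one_hot_encode(tab)
  expect_equal(unname(fm$values), diag(3), ignore_attr = TRUE)
  expect_identical(fm$feature_index$class, c("REF_HOM", "HET", "ALT_HOM"))
  expect_identical(fm$feature_index$allele, c("A/A", "A/T", "T/T"))

  dec <- decode_feature(fm, fm$feature_index$feature_id)
  expect_identical(dec$feature_id, fm$feature_index$feature_id)
  expect_error(decode_feature(fm, "s9999|HET"), "unknown feature")
})

test_that("one-hot row sums are 1 for non-missing calls and 0 for missing", {
  for (s in 1:50) {
    tab <- random_table(s, n_lines = 15, n_snps = 20)
    fm <- one_hot_encode(tab)
    expect_equal(sum(fm$values), sum(!is.na(tab$calls)))  # conservation
    for (snp in unique(fm$feature_index$snp_id)) {
      cols <- fm$feature_index$feature_id[fm$feature_index$snp_id == snp]
      rs <- rowSums(fm$values[, cols, drop = FALSE])
      expect_identical(unname(rs), as.numeric(!is.na(tab$calls[, snp])))
    }
    # encode -> decode round trip over every emitted feature
    dec <- decode_feature(fm, fm$feature_index$feature_id)
    expect_identical(dec$snp_id, fm$feature_index$snp_id)
    expect_identical(dec$class, fm$feature_index$class)
  }
})

test_that("a stale feature id after re-encoding a filtered table errors", {
  tab <- toy_table(n_lines = 20, n_snps = 30, seed = 5)
  fm_full <- one_hot_encode(tab)
  reduced <- thin_sequential(tab, 7)
  fm_red <- one_hot_encode(reduced)
  stale <- setdiff(fm_full$feature_index$feature_id,
                   fm_red$feature_index$feature_id)[1]
  expect_error(decode_feature(fm_red, stale), "unknown feature")
})

test_that("holdout split sizes, disjointness and determinism", {
  ids <- sprintf("L%04d", 1:1000)
  sp <- holdout_split(ids, 0.2, seed = 42)
  expect_length(sp$holdout_line_ids, 200)
  expect_length(sp$train_line_ids, 800)
  expect_length(intersect(sp$train_line_ids, sp$holdout_line_ids), 0)
  expect_setequal(c(sp$train_line_ids, sp$holdout_line_ids), ids)
  sp2 <- holdout_split(ids, 0.2, seed = 42)
  expect_identical(sp, sp2)
  expect_error(holdout_split(ids[1:4], 0.2, 1), "at least 5")
  expect_error(holdout_split(ids, 0, 1), "fraction")
  expect_error(holdout_split(ids[1:8], 0.01, 1), "empty")
})

test_that("region extraction respects closed intervals and genome order", {
  calls <- matrix(0L, 2, 4)
  tab <- table_from_calls(calls, pos = c(50000L, 150000L, 240000L, 300000L))
  out <- extract_regions(tab, region_set("chr01", 100000, 240000))
  expect_identical(out$snp_map$pos, c(150000L, 240000L))
  expect_equal(attr(out, "retained_fraction"), 0.5)

  whole <- extract_regions(tab, region_set("chr01", 1, 400000))
  expect_identical(whole$snp_map, tab$snp_map)

  two <- extract_regions(tab, region_set(c("chr01", "chr01"),
                                         c(40000, 290000), c(60000, 310000)))
  expect_identical(two$snp_map$pos, c(50000L, 300000L))

  expect_error(extract_regions(tab, region_set(character(), integer(), integer())),
               "empty")
  expect_error(extract_regions(tab, region_set("chrX", 1, 10)), "unknown chrom")
})

test_that("region and phenotype file round trips preserve content", {
  rs <- region_set(c("chr01", "chr02"), c(100, 5000), c(900, 6000))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_regions(rs, p)
  expect_equal(as.data.frame(read_regions(p)), as.data.frame(rs))

  ph <- phenotype_table(c("a", "b", "c"), c(1.5, 2.25, 3), "oil", "continuous")
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(ph, pcsv)
  back <- read_phenotypes(pcsv)
  expect_equal(back$value, ph$value)
  expect_identical(trait_type(back), "continuous")

  phc <- phenotype_table(c("a", "b"), c("purple", "white"), "flower", "binary")
  write_phenotypes(phc, pcsv)
  backc <- read_phenotypes(pcsv)
  expect_identical(backc$value, phc$value)
  expect_identical(trait_type(backc), "binary")
})

test_that("genotype CSV renders calls as allele pairs", {
  calls <- matrix(c(0L, 1L, 2L, NA), 4, 1)
  tab <- table_from_calls(calls)
  p <- withr::local_tempfile(fileext = ".csv")
  write_genotype_csv(tab, p)
  df <- read.csv(p, check.names = FALSE)
  expect_identical(df[["s0001"]], c("A/A", "A/T", "T/T", "./."))
})
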