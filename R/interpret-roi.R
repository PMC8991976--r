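# Gain-based interpretation of a fitted tree-ensemble model: rank the
# one-hot features by gain, decode them back to SNPs, chain top-ranked SNPs
# into Regions of Importance (ROIs), and turn ROIs into target regions for
# input reduction.

#' Rank one-hot features of a fitted XGBoost model by gain
#'
#' Extracts per-feature gain (the total training-objective improvement
#' attributed to splits on the feature, normalised over the model) from the
#' fitted booster, keeps the `top_n` highest, and decodes each feature to
#' its SNP, genotype class and allele pair through the feature index. Every
#' one-hot column is its own ranked entry, so one SNP can appear more than
#' once. Ties in gain are broken by (chrom, pos) ascending for a stable
#' ranking.
#'
#' @param fit a [crossval_fit()] result with family `"XGB"`, or a raw
#'   xgboost booster.
#' @param feature_index the `feature_index` of the [one_hot_encode()] result
#'   the model was trained on (or the `feature_matrix`).
#' @param top_n number of top features to keep (default 20). If the model
#'   used fewer features, all used features are returned.
#' @return data.frame of class `ranked_snps`: `rank`, `feature_id`,
#'   `snp_id`, `chrom`, `pos`, `class`, `allele`, `gain` (non-increasing).
#' @export
rank_features_by_gain <- function(fit, feature_index, top_n = 20L) {
  booster <- if (inherits(fit, "cv_fit")) {
    if (fit$family != "XGB")
      stop("gain-based ranking requires an XGBoost model; got ", fit$family)
    fit$fitted
  } else fit
  if (inherits(feature_index, "feature_matrix"))
    feature_index <- feature_index$feature_index
  imp <- as.data.frame(xgboost::xgb.importance(model = booster))
  if (!nrow(imp)) {
    out <- data.frame(rank = integer(), feature_id = character(),
                      snp_id = character(), chrom = character(),
                      pos = integer(), class = character(),
                      allele = character(), gain = numeric())
    class(out) <- c("ranked_snps", "data.frame")
    return(out)
  }
  unknown <- setdiff(imp$Feature, feature_index$feature_id)
  if (length(unknown))
    stop("model was trained on a different feature set; unknown feature(s): ",
         paste(head(unknown, 3), collapse = ", "))
  dec <- decode_feature(feature_index, imp$Feature)
  out <- data.frame(feature_id = imp$Feature, snp_id = dec$snp_id,
                    chrom = dec$chrom, pos = dec$pos, class = dec$class,
                    allele = dec$allele, gain = imp$Gain,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gain, out$chrom, out$pos), ]
  out <- head(out, top_n)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("ranked_snps", "data.frame")
  out
}

#' Cluster top-ranked SNPs into Regions of Importance
#'
#' Per chromosome, SNPs are chained by single linkage: two SNPs join the
#' same cluster when their gap is at most `max_gap_bp` (every member is
#' within `max_gap_bp` of its nearest other member). Clusters holding at
#' least `min_size` distinct SNPs become ROIs; duplicate ranked entries of
#' one SNP (several genotype classes of the same marker) count once toward
#' the size. The ROI span is the min/max member position; ROIs are returned
#' sorted by summed gain, descending.
#'
#' @param ranked a [rank_features_by_gain()] result (needs `snp_id`,
#'   `chrom`, `pos`, `gain`).
#' @param max_gap_bp maximum nearest-neighbour gap inside an ROI
#'   (default 100000).
#' @param min_size minimum number of distinct SNPs (default 3).
#' @return data.frame of class `roi_set`: `chrom`, `start`, `end`,
#'   `n_snps`, `sum_gain`, `snp_ids` (comma-joined member ids). Empty input
#'   gives an empty set.
#' @export
cluster_rois <- function(ranked, max_gap_bp = 100000L, min_size = 3L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), sum_gain = numeric(),
                      snp_ids = character(), stringsAsFactors = FALSE)
  class(empty) <- c("roi_set", "data.frame")
  if (is.null(ranked) || !nrow(ranked)) return(empty)
  # one row per distinct SNP; gain summed over its ranked entries
  agg <- stats::aggregate(gain ~ snp_id + chrom + pos, data = ranked, FUN = sum)
  rois <- list()
  for (ch in unique(agg$chrom)) {
    sub <- agg[agg$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    gaps <- diff(sub$pos)
    cluster <- cumsum(c(1L, as.integer(gaps > max_gap_bp)))
    for (cl in unique(cluster)) {
      mem <- sub[cluster == cl, ]
      if (nrow(mem) < min_size) next
      rois[[length(rois) + 1L]] <- data.frame(
        chrom = ch, start = min(mem$pos), end = max(mem$pos),
        n_snps = nrow(mem), sum_gain = sum(mem$gain),
        snp_ids = paste(mem$snp_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rois)) return(empty)
  out <- do.call(rbind, rois)
  out <- out[order(-out$sum_gain), ]
  rownames(out) <- NULL
  class(out) <- c("roi_set", "data.frame")
  out
}

#' Turn ROIs (or top-ranked SNPs) into target regions for input reduction
#'
#' Each ROI span is extended by `flank_bp` on both sides (clipped at
#' position 1). When no ROI exists for a trait, the fallback path takes a
#' window of `fallback_window_bp` either side of each top-ranked SNP.
#' Overlapping or book-ended intervals are merged.
#'
#' @param rois a [cluster_rois()] result (possibly empty).
#' @param ranked a [rank_features_by_gain()] result; must be non-empty.
#' @param flank_bp flank added to each ROI (default 0).
#' @param fallback_window_bp half-width of the per-SNP fallback window
#'   (default 250000).
#' @return a [region_set()]; attribute `used_fallback` records whether the
#'   fallback path was taken.
#' @export
define_target_regions <- function(rois, ranked, flank_bp = 0L,
                                  fallback_window_bp = 250000L) {
  if (is.null(ranked) || !nrow(ranked)) stop("ranked SNP list is empty")
  used_fallback <- is.null(rois) || !nrow(rois)
  if (!used_fallback) {
    chrom <- rois$chrom
    start <- pmax(1L, rois$start - as.integer(flank_bp))
    end <- rois$end + as.integer(flank_bp)
  } else {
    snps <- unique(ranked[, c("chrom", "pos")])
    chrom <- snps$chrom
    start <- pmax(1L, snps$pos - as.integer(fallback_window_bp))
    end <- snps$pos + as.integer(fallback_window_bp)
  }
  merged <- do.call(rbind, lapply(unique(chrom), function(ch) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start[chrom == ch],
                                           end = end[chrom == ch]))
    data.frame(chrom = ch, start = IRanges::start(ir), end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  }))
  out <- region_set(merged$chrom, merged$start, merged$end)
  attr(out, "used_fallback") <- used_fallback
  out
}

#' Write ranked SNPs as TSV
#'
#' Columns: rank, feature_id, snp_id, chrom, pos, class, allele, gain — a
#' bar-chart-ready export of the gain ranking.
#'
#' @param ranked a [rank_features_by_gain()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ranked_snps <- function(ranked, path) {
  write.table(as.data.frame(ranked), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
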