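#' Default quality-control thresholds
#'
#' Sample-level rules: minimum mean coverage 60x (tumor) and 20x (normal);
#' minimum tumor/normal SNP genotype correlation 0.80; at most 70% of
#' somatic variants present in gnomAD (contamination guard); minimum tumor
#' content 0.30. Variant-level rules: read depth >= 20x in both tumor and
#' normal, VAF strictly > 5%, and at least 3 supporting reads. CNV calls
#' need a log-likelihood strictly > 100.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(
    tumor_cov_min = 60, normal_cov_min = 20,
    snp_correlation_min = 0.80, gnomad_fraction_max = 0.70,
    tumor_content_min = 0.30,
    variant_depth_min = 20, vaf_min = 0.05, alt_reads_min = 3,
    cnv_loglikelihood_min = 100
  )
}

#' Sample-level quality control
#'
#' Applies the five sample-level rules to a metrics table and reports every
#' failed rule (not just the first). All five metrics must be present and
#' non-missing; a missing metric is a configuration error, never a default
#' pass. Mean coverages and the SNP correlation are consumed as upstream
#' pipeline metrics, not recomputed from reads.
#'
#' @param metrics A data frame with columns `sample_id`, `tumor_cov`,
#'   `normal_cov`, `snp_correlation`, `gnomad_fraction`, `tumor_content`.
#' @param thresholds Threshold list, see [qc_thresholds()].
#' @return The metrics tibble plus `passed` (logical) and `reasons`
#'   (list-column of failed rule names; empty iff passed).
#' @export
sample_qc <- function(metrics, thresholds = qc_thresholds()) {
  cols <- c("sample_id", "tumor_cov", "normal_cov", "snp_correlation",
            "gnomad_fraction", "tumor_content")
  require_columns(metrics, cols, "QC metrics table")
  metrics <- as_tibble(metrics)
  vals <- metrics[, setdiff(cols, "sample_id")]
  if (any(!is.finite(as.matrix(vals)))) {
    abort_config("sample_qc requires all five metrics to be present and non-missing")
  }
  reasons <- pmap(metrics[, cols], function(sample_id, tumor_cov, normal_cov,
                                            snp_correlation, gnomad_fraction,
                                            tumor_content) {
    r <- character()
    if (tumor_cov < thresholds$tumor_cov_min) r <- c(r, "tumor_coverage")
    if (normal_cov < thresholds$normal_cov_min) r <- c(r, "normal_coverage")
    if (snp_correlation < thresholds$snp_correlation_min) r <- c(r, "snp_correlation")
    if (gnomad_fraction > thresholds$gnomad_fraction_max) r <- c(r, "gnomad_contamination")
    if (tumor_content < thresholds$tumor_content_min) r <- c(r, "tumor_content")
    r
  })
  metrics$passed <- lengths(reasons) == 0
  metrics$reasons <- reasons
  metrics
}

#' Variant-level quality control
#'
#' Keeps a somatic call iff tumor and normal depth are both >= 20x, VAF is
#' strictly greater than 5%, and at least 3 distinct reads support the
#' alternate allele. The filter is total: no errors, only removal.
#'
#' @param variants A validated variant tibble.
#' @param thresholds Threshold list, see [qc_thresholds()].
#' @return The filtered tibble.
#' @export
variant_qc <- function(variants, thresholds = qc_thresholds()) {
  require_columns(variants, c("tumor_depth", "normal_depth", "vaf", "alt_reads"),
                  "variant table")
  filter(
    as_tibble(variants),
    tumor_depth >= thresholds$variant_depth_min,
    normal_depth >= thresholds$variant_depth_min,
    vaf > thresholds$vaf_min,
    alt_reads >= thresholds$alt_reads_min
  )
}

#' CNV call quality control
#'
#' Keeps calls with log-likelihood strictly greater than 100.
#'
#' @param cnvs A CNV call tibble with a `loglikelihood` column.
#' @param thresholds Threshold list, see [qc_thresholds()].
#' @return The filtered tibble.
#' @export
cnv_qc <- function(cnvs, thresholds = qc_thresholds()) {
  require_columns(cnvs, "loglikelihood", "CNV table")
  filter(as_tibble(cnvs), loglikelihood > thresholds$cnv_loglikelihood_min)
}

#' Estimate tumor content from variant allele frequencies
#'
#' Used when no CNV-based purity estimate is available: takes the median
#' of the 15 highest VAFs (all VAFs if fewer than 15 variants) and doubles
#' it, since a heterozygous clonal variant in a diploid tumor has a VAF of
#' about half the purity; the result is capped at 1. With zero variants
#' the content is undefined: the function returns `NA` and signals a
#' `motiscore_review` warning flagging the sample for manual review
#' (it is not auto-failed).
#'
#' @param variants A variant tibble (QC-filtered), or a numeric vector of
#'   VAFs.
#' @param top_n Number of top VAFs considered (default 15).
#' @param multiplier VAF-to-purity multiplier (default 2, diploid
#'   heterozygous assumption).
#' @return Estimated tumor content in \[0, 1\], or `NA` with a warning.
#' @export
estimate_tumor_content <- function(variants, top_n = 15, multiplier = 2) {
  vafs <- if (is.data.frame(variants)) {
    require_columns(variants, "vaf", "variant table")
    variants$vaf
  } else {
    as.numeric(variants)
  }
  vafs <- vafs[is.finite(vafs)]
  if (length(vafs) == 0) {
    warn("no somatic variants: tumor content undefined, sample flagged for manual review",
         class = "motiscore_review")
    return(NA_real_)
  }
  top <- sort(vafs, decreasing = TRUE)[seq_len(min(top_n, length(vafs)))]
  min(1, multiplier * median(top))
}

#' Study-specific target region
#'
#' A base belongs to the study target region if it is covered at >= 20x in
#' at least half of the study's normal samples (real-valued comparison:
#' 2 of 4 passes, 1 of 3 fails), intersected with exon coordinates padded
#' by 2 bases on each side.
#'
#' @param coverage_tracks List of `interval_set`s, one per normal sample,
#'   each marking the bases covered at >= 20x.
#' @param exons `interval_set` of exon coordinates.
#' @param min_fraction Minimum fraction of samples covering a base
#'   (default 0.5).
#' @param exon_pad Padding in bases applied to each exon side (default 2).
#' @return The study target `interval_set`.
#' @export
study_target_region <- function(coverage_tracks, exons, min_fraction = 0.5,
                                exon_pad = 2) {
  if (!is.list(coverage_tracks) || length(coverage_tracks) == 0 ||
      is.data.frame(coverage_tracks)) {
    abort_config("`coverage_tracks` must be a non-empty list of interval sets")
  }
  exons <- as_interval_set(exons)
  if (nrow(exons) == 0) {
    warn("empty exon set: study target region is empty")
    return(interval_set())
  }
  n <- length(coverage_tracks)
  quorum <- ceiling(n * min_fraction)  # counts are integer, so >= n/2 <=> >= ceiling(n/2)
  all_gr <- do.call(c, lapply(coverage_tracks, function(t) iv_to_gr(as_interval_set(t))))
  cov <- GenomicRanges::coverage(all_gr)
  covered <- GenomicRanges::GRanges(IRanges::slice(cov, lower = quorum, rangesOnly = TRUE))
  covered_iv <- restore_iv(gr_to_iv(covered))
  intersect_intervals(covered_iv, pad_intervals(exons, exon_pad))
}
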