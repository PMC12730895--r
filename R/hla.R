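#' Detect HLA class-I allele loss
#'
#' An allele at a locus is considered lost if either
#' * an overlapping CNV call deletes one allele with clonality of at
#'   least 25% (`hla_cnvs` rows carry the locus, the deleted allele and
#'   the call's clonality -- phasing a deletion to an allele is upstream
#'   annotation), or
#' * the tumor/normal assigned-read-count ratios of the two alleles
#'   deviate by more than 40%: with per-allele ratios r1, r2 (tumor reads
#'   over normal reads), loss is flagged when
#'   `|r1 - r2| / max(r1, r2) > 0.40`, the allele with the smaller ratio
#'   being the lost one.
#'
#' @param genotype HLA genotype tibble from [hla_genotype()].
#' @param hla_cnvs Optional tibble with columns `locus`, `deleted_allele`,
#'   `clonality`.
#' @param read_ratios Optional tibble with columns `locus`, `allele`,
#'   `tumor_reads`, `normal_reads` (two rows per locus, positive counts).
#' @param clonality_min CNV clonality threshold (default 0.25, `>=`).
#' @param deviation_max Read-ratio deviation threshold (default 0.40,
#'   strict `>`).
#' @return The genotype with `loss` and `lost_allele` updated.
#' @export
detect_allele_loss <- function(genotype, hla_cnvs = NULL, read_ratios = NULL,
                               clonality_min = 0.25, deviation_max = 0.40) {
  require_columns(genotype, c("locus", "allele1", "allele2"), "HLA genotype")
  genotype$loss <- genotype$loss %||% FALSE
  genotype$lost_allele <- genotype$lost_allele %||% NA_character_
  if (!is.null(hla_cnvs) && nrow(hla_cnvs) > 0) {
    require_columns(hla_cnvs, c("locus", "deleted_allele", "clonality"), "HLA CNV table")
    hits <- filter(hla_cnvs, clonality >= clonality_min)
    for (i in seq_len(nrow(hits))) {
      j <- which(genotype$locus == hits$locus[i])
      if (length(j) == 1) {
        genotype$loss[j] <- TRUE
        genotype$lost_allele[j] <- normalize_hla_allele(hits$deleted_allele[i])
      }
    }
  }
  if (!is.null(read_ratios) && nrow(read_ratios) > 0) {
    require_columns(read_ratios, c("locus", "allele", "tumor_reads", "normal_reads"),
                    "read-ratio table")
    if (any(read_ratios$tumor_reads <= 0 | read_ratios$normal_reads <= 0)) {
      abort_data("assigned read counts must be positive")
    }
    rr <- mutate(read_ratios, ratio = tumor_reads / normal_reads)
    for (j in seq_len(nrow(genotype))) {
      rows <- filter(rr, locus == genotype$locus[j])
      if (nrow(rows) != 2) next
      r <- rows$ratio
      dev <- abs(r[1] - r[2]) / max(r)
      if (dev > deviation_max) {
        genotype$loss[j] <- TRUE
        genotype$lost_allele[j] <-
          normalize_hla_allele(rows$allele[which.min(r)])
      }
    }
  }
  genotype
}

#' HLA evolutionary divergence (HED)
#'
#' Per class-I locus, the mean Grantham distance per aligned position
#' between the binding-groove sequences of the two alleles. A homozygous
#' locus, or a locus with a detected allele loss, scores 0 -- one
#' functional allele means no divergence. The sample-level HED is the mean
#' of the three locus values (per-locus values are always reported).
#'
#' @param genotype HLA genotype tibble (with `loss` flags set).
#' @param matrix Amino-acid distance matrix, default [grantham_matrix()].
#' @return A list with `per_locus` (tibble of `locus`, `hed`) and
#'   `mean_hed`.
#' @export
hed <- function(genotype, matrix = grantham_matrix()) {
  require_columns(genotype, c("locus", "allele1", "allele2", "groove1",
                              "groove2", "loss"), "HLA genotype")
  per <- map_dbl(seq_len(nrow(genotype)), function(i) {
    if (isTRUE(genotype$loss[i])) return(0)
    if (genotype$allele1[i] == genotype$allele2[i]) return(0)
    grantham_distance(genotype$groove1[i], genotype$groove2[i], matrix)
  })
  list(
    per_locus = tibble(locus = genotype$locus, hed = per),
    mean_hed = mean(per)
  )
}
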