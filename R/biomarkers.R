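#' Candidate biomarkers of the immunogenicity panel
#'
#' The eight candidate biomarkers: tumor mutation burden, neoantigen
#' burden, TCR repertoire entropy, ICI-resistance flag, ICI-response flag,
#' HLA evolutionary divergence, and PDL1/B2M expression. The combined
#' C-X-C chemokine marker is available as an additional panel column but is
#' not a fit candidate by default.
#'
#' @return A tibble with columns `biomarker` and `type`
#'   (`continuous`/`categorical`).
#' @export
panel_biomarkers <- function() {
  tibble(
    biomarker = c("tmb", "neoantigen_burden", "tcr_entropy",
                  "resistance_flag", "response_flag", "hed",
                  "pdl1_cpm", "b2m_cpm"),
    type = c("continuous", "continuous", "continuous", "categorical",
             "categorical", "continuous", "continuous", "continuous")
  )
}

#' Genes of the ICI-resistance mechanism set
#'
#' B2M plus the antigen processing machinery genes. The literature's
#' "CALX" label is read as CANX (calnexin); both aliases are accepted on
#' input via [normalize_gene()].
#'
#' @return Character vector of 7 HGNC symbols.
#' @export
resistance_genes <- function() {
  c("B2M", "TAP1", "TAP2", "TAPBP", "CIITA", "CALR", "CANX")
}

#' Gene of the ICI-response mechanism
#' @return `"LRP1B"`.
#' @export
response_gene <- function() "LRP1B"

#' Normalize gene symbols
#'
#' Upper-cases and resolves the aliases used by this package: CALX -> CANX
#' and PDL1 -> CD274.
#'
#' @param x Character vector of gene symbols.
#' @return Normalized symbols.
#' @export
normalize_gene <- function(x) {
  x <- toupper(as.character(x))
  x[x == "CALX"] <- "CANX"
  x[x == "PDL1"] <- "CD274"
  x
}

#' Tumor mutation burden
#'
#' Number of nonsynonymous somatic variants (impact strictly above
#' protein-altering, i.e. `moderate` or `high`) falling inside the target
#' region, normalized by the region size in megabases.
#'
#' @param variants QC-passed variant tibble.
#' @param region Target `interval_set`; must be non-empty.
#' @return Mutations per megabase.
#' @export
compute_tmb <- function(variants, region) {
  region <- as_interval_set(region)
  mb <- interval_total_bases(region) / 1e6
  if (mb <= 0) {
    abort_data("TMB is undefined on an empty target region")
  }
  if (nrow(variants) == 0) return(0)
  require_columns(variants, c("chrom", "pos", "impact"), "variant table")
  keep <- is_nonsynonymous(variants$impact) &
    in_intervals(variants$chrom, variants$pos, region)
  sum(keep) / mb
}

#' Neoantigen burden
#'
#' Counts predicted neoantigen candidates with median binding affinity
#' strictly below 500 nM that are supported by at least one RNA-Seq read.
#' If an HLA allele loss was detected at a locus, only candidates
#' restricted to the retained allele are counted.
#'
#' @param candidates Neoantigen candidate tibble
#'   (see [read_neoantigens()]).
#' @param genotype HLA genotype tibble (see [hla_genotype()]), with loss
#'   flags e.g. from [detect_allele_loss()].
#' @param affinity_max Affinity threshold in nM (default 500, strict `<`).
#' @param min_rna_reads Minimum RNA read support (default 1).
#' @return Integer candidate count.
#' @export
neoantigen_burden <- function(candidates, genotype, affinity_max = 500,
                              min_rna_reads = 1) {
  if (nrow(candidates) == 0) return(0L)
  require_columns(candidates, c("hla_allele", "median_affinity_nm", "rna_reads"),
                  "neoantigen table")
  require_columns(genotype, c("locus", "allele1", "allele2", "loss", "lost_allele"),
                  "HLA genotype")
  allele <- normalize_hla_allele(candidates$hla_allele)
  locus <- substr(allele, 1, 1)
  gt <- genotype[match(locus, genotype$locus), ]
  known <- !is.na(gt$locus) & (allele == gt$allele1 | allele == gt$allele2)
  if (any(!known)) {
    abort_data(sprintf(
      "neoantigen candidate allele(s) absent from the sample genotype: %s",
      paste(unique(allele[!known]), collapse = ", ")
    ))
  }
  retained_ok <- !gt$loss | (allele != gt$lost_allele)
  keep <- candidates$median_affinity_nm < affinity_max &
    candidates$rna_reads >= min_rna_reads &
    retained_ok
  sum(keep)
}

#' TCR repertoire Shannon entropy
#'
#' Restricts the clonotype table to alpha-chain clones detected at least
#' twice, then computes the Shannon entropy (natural log) of the clone
#' frequency distribution: H = -sum(p_i * ln p_i) with p_i the relative
#' frequency of clone i among the retained clones. Zero or one retained
#' clone gives H = 0.
#'
#' @param clones Clonotype tibble with columns `chain`, `count`.
#' @param chain_used Chain restricted to (default `"alpha"`).
#' @param min_count Minimum clone count (default 2).
#' @return Entropy in nats (>= 0; at most ln of the retained clone count).
#' @export
tcr_entropy <- function(clones, chain_used = "alpha", min_count = 2) {
  if (nrow(clones) == 0) return(0)
  require_columns(clones, c("chain", "count"), "clonotype table")
  kept <- clones$count[clones$chain == chain_used & clones$count >= min_count]
  if (length(kept) <= 1) return(0)
  p <- kept / sum(kept)
  -sum(p * log(p))
}

cnv_gene_hits <- function(cnvs, genes) {
  if (is.null(cnvs) || nrow(cnvs) == 0 || !"genes" %in% names(cnvs)) {
    return(tibble(copy_number = numeric(0), clonality = numeric(0)))
  }
  gene_lists <- strsplit(normalize_gene(cnvs$genes), "\\s*,\\s*")
  hit <- map_lgl(gene_lists, ~ any(.x %in% genes))
  cnvs[hit, , drop = FALSE]
}

#' ICI-resistance flag
#'
#' Set to -1 if a deleterious main-clone alteration hits any of the seven
#' resistance genes (B2M plus the antigen processing machinery,
#' [resistance_genes()]), else 0. Deleterious SNVs/indels have high impact
#' or a COSMIC Cancer Mutation Census annotation, and must affect the main
#' clone: VAF of at least 80% of the tumor clonality. Deleterious CNVs are
#' homozygous deletions (copy number 0) whose own clonality reaches the
#' same 80%-of-tumor-clonality bar. The negative coding reflects that a
#' defective resistance mechanism lowers immunogenicity.
#'
#' @param variants QC-passed variant tibble (may be empty).
#' @param cnvs QC-passed CNV tibble with `copy_number`, `clonality` and a
#'   `genes` column of comma-separated overlapped symbols (may be `NULL`).
#' @param tumor_clonality Tumor clonality in (0, 1\].
#' @param clonal_fraction Main-clone VAF threshold as a fraction of tumor
#'   clonality (default 0.8).
#' @return `-1L` or `0L`.
#' @export
resistance_flag <- function(variants, cnvs = NULL, tumor_clonality,
                            clonal_fraction = 0.8) {
  if (!is.finite(tumor_clonality) || tumor_clonality <= 0 || tumor_clonality > 1) {
    abort_data("tumor_clonality must be in (0, 1]")
  }
  genes <- resistance_genes()
  snv_hit <- FALSE
  if (!is.null(variants) && nrow(variants) > 0) {
    require_columns(variants, c("gene", "impact", "vaf", "cmc_annotated"),
                    "variant table")
    v <- filter(variants,
                normalize_gene(gene) %in% genes,
                as.character(impact) == "high" | cmc_annotated,
                vaf >= clonal_fraction * tumor_clonality)
    snv_hit <- nrow(v) > 0
  }
  cnv_hit <- FALSE
  hits <- cnv_gene_hits(cnvs, genes)
  if (nrow(hits) > 0) {
    cnv_hit <- any(hits$copy_number == 0 &
                     hits$clonality >= clonal_fraction * tumor_clonality)
  }
  if (snv_hit || cnv_hit) -1L else 0L
}

#' ICI-response flag
#'
#' Set to 1 if LRP1B carries a somatic SNV/indel with high impact *and* a
#' COSMIC Cancer Mutation Census annotation, or any homozygous deletion --
#' regardless of clonality. Variants of unclear significance (lower impact
#' or missing CMC annotation) are excluded.
#'
#' @param variants QC-passed variant tibble (may be empty).
#' @param cnvs QC-passed CNV tibble with `copy_number` and `genes` (may be
#'   `NULL`).
#' @return `1L` or `0L`.
#' @export
response_flag <- function(variants, cnvs = NULL) {
  gene_target <- response_gene()
  snv_hit <- FALSE
  if (!is.null(variants) && nrow(variants) > 0) {
    require_columns(variants, c("gene", "impact", "cmc_annotated"), "variant table")
    v <- filter(variants,
                normalize_gene(gene) == gene_target,
                as.character(impact) == "high",
                cmc_annotated)
    snv_hit <- nrow(v) > 0
  }
  hits <- cnv_gene_hits(cnvs, gene_target)
  cnv_hit <- nrow(hits) > 0 && any(hits$copy_number == 0)
  if (snv_hit || cnv_hit) 1L else 0L
}

#' Counts-per-million normalization
#'
#' @param counts A counts tibble (`gene` column plus one column per
#'   sample).
#' @return The same shape with every sample column scaled to counts per
#'   million (columns sum to 1e6). A zero library is an error.
#' @export
cpm <- function(counts) {
  require_columns(counts, "gene", "counts table")
  out <- as_tibble(counts)
  for (col in setdiff(names(out), "gene")) {
    total <- sum(out[[col]])
    if (!is.finite(total) || total <= 0) {
      abort_data(sprintf("sample `%s` has zero library size", col))
    }
    out[[col]] <- 1e6 * out[[col]] / total
  }
  out
}

#' PDL1 and B2M expression markers
#'
#' Library-size-normalized expression (counts per million) of CD274 (PDL1)
#' and B2M for one sample.
#'
#' @param counts A counts tibble (see [read_counts()]); gene identifiers
#'   are resolved through [normalize_gene()].
#' @param sample Sample column name.
#' @return A one-row tibble with `pdl1_cpm` and `b2m_cpm`.
#' @export
expression_markers <- function(counts, sample) {
  require_columns(counts, c("gene", sample), "counts table")
  x <- cpm(counts[, c("gene", sample)])
  g <- normalize_gene(x$gene)
  pick <- function(sym) {
    i <- which(g == sym)
    if (length(i) == 0) {
      abort_data(sprintf("gene `%s` absent from counts table", sym))
    }
    sum(x[[sample]][i])
  }
  tibble(pdl1_cpm = pick("CD274"), b2m_cpm = pick("B2M"))
}

#' Combined C-X-C chemokine expression marker
#'
#' Merges CXCL9, CXCL10 and CXCL11 into one marker: for each gene, the
#' log2 fold change of the sample's CPM against the cohort median CPM of
#' that gene (pseudocount added to numerator and denominator), averaged
#' over the three genes.
#'
#' @param counts Cohort counts tibble (`gene` plus all cohort samples).
#' @param sample Sample column name.
#' @param genes The chemokine genes (default CXCL9/10/11).
#' @param pseudocount Added to both sides of the fold change (default 1).
#' @return Mean log2 fold change (0 for a sample at the cohort median).
#' @export
cxcl_combined <- function(counts, sample,
                          genes = c("CXCL9", "CXCL10", "CXCL11"),
                          pseudocount = 1) {
  require_columns(counts, c("gene", sample), "counts table")
  x <- cpm(counts)
  g <- normalize_gene(x$gene)
  lfc <- map_dbl(genes, function(sym) {
    i <- which(g == normalize_gene(sym))
    if (length(i) == 0) {
      abort_data(sprintf("gene `%s` absent from counts table", sym))
    }
    row <- as.numeric(x[i[1], setdiff(names(x), "gene")])
    ref <- median(row)
    log2((x[[sample]][i[1]] + pseudocount) / (ref + pseudocount))
  })
  mean(lfc)
}

#' Assemble the per-sample biomarker panel
#'
#' Computes every biomarker whose inputs are provided and marks the rest
#' as missing (`NA`), never silently zero. RNA-derived markers (entropy,
#' expression) need `clones`/`counts`; DNA-derived markers need
#' `variants`/`cnvs`/`region`; HED needs a `genotype` (with loss flags
#' already set, e.g. via [detect_allele_loss()]).
#'
#' @param sample_id Sample identifier.
#' @param variants,cnvs QC-passed variant and CNV tibbles (or `NULL`).
#' @param region Target `interval_set` (or `NULL`).
#' @param clones Clonotype tibble (or `NULL`).
#' @param candidates Neoantigen candidate tibble (or `NULL`).
#' @param genotype HLA genotype tibble (or `NULL`).
#' @param counts Cohort counts tibble (or `NULL`).
#' @param tumor_clonality Tumor clonality for the resistance main-clone
#'   filter (or `NA`).
#' @param with_cxcl Also compute the combined chemokine marker
#'   (default `TRUE` when counts are given).
#' @return A one-row panel tibble.
#' @export
build_panel <- function(sample_id, variants = NULL, cnvs = NULL, region = NULL,
                        clones = NULL, candidates = NULL, genotype = NULL,
                        counts = NULL, tumor_clonality = NA_real_,
                        with_cxcl = TRUE) {
  has <- function(x) !is.null(x)
  panel <- tibble(
    sample_id = sample_id,
    tmb = if (has(variants) && has(region)) compute_tmb(variants, region) else NA_real_,
    neoantigen_burden = if (has(candidates) && has(genotype)) {
      as.numeric(neoantigen_burden(candidates, genotype))
    } else NA_real_,
    tcr_entropy = if (has(clones)) tcr_entropy(clones) else NA_real_,
    resistance_flag = if (has(variants) && is.finite(tumor_clonality)) {
      as.numeric(resistance_flag(variants, cnvs, tumor_clonality))
    } else NA_real_,
    response_flag = if (has(variants)) {
      as.numeric(response_flag(variants, cnvs))
    } else NA_real_,
    hed = if (has(genotype)) hed(genotype)$mean_hed else NA_real_,
    pdl1_cpm = NA_real_, b2m_cpm = NA_real_, cxcl_combined = NA_real_
  )
  if (has(counts)) {
    em <- expression_markers(counts, sample_id)
    panel$pdl1_cpm <- em$pdl1_cpm
    panel$b2m_cpm <- em$b2m_cpm
    if (with_cxcl && ncol(counts) > 2) {
      panel$cxcl_combined <- cxcl_combined(counts, sample_id)
    }
  }
  panel
}
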