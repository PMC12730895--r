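test_that("TMB counts nonsynonymous in-region variants per megabase", {
  region10 <- interval_set("chr1", 0, 10e6)
  v30 <- make_variants(30, pos = sample(1:10e6, 30), impact = "moderate")
  expect_equal(compute_tmb(v30, region10), 3.0)

  region1 <- interval_set("chr1", 0, 1e6)
  v5 <- make_variants(5, pos = c(10, 20, 30, 2e6, 3e6), impact = "high")
  expect_equal(compute_tmb(v5, region1), 3.0)

  # classification against the packaged impact table
  vmix <- make_variants(12, pos = seq(100, by = 100, length.out = 12),
                        impact = c(rep("high", 4), rep("missense_variant", 3),
                                   rep("synonymous_variant", 5)))
  expect_equal(compute_tmb(vmix, region1), 7.0)

  expect_error(compute_tmb(v5, interval_set()), class = "motiscore_data_error")
})

test_that("TMB is permutation invariant and additive over disjoint partitions", {
  set.seed(5)
  v <- make_variants(40, pos = sample(1:2e6, 40),
                     impact = sample(impact_levels(), 40, replace = TRUE))
  whole <- interval_set("chr1", 0, 2e6)
  left <- interval_set("chr1", 0, 1e6)
  right <- interval_set("chr1", 1e6, 2e6)
  perm <- v[sample(nrow(v)), ]
  expect_equal(compute_tmb(v, whole), compute_tmb(perm, whole))
  # counts (TMB * Mb) add over the disjoint partition
  expect_equal(compute_tmb(v, whole) * 2,
               compute_tmb(v, left) * 1 + compute_tmb(v, right) * 1)
})

test_that("neoantigen burden applies affinity, expression and allele-loss filters", {
  gt <- hla_genotype(c("A", "B", "C"),
                     c("A*01:01", "B*07:02", "C*04:01"),
                     c("A*02:01", "B*08:01", "C*07:01"))
  cand <- tibble(
    peptide = sprintf("PEP%d", 1:4),
    hla_allele = "A*01:01",
    median_affinity_nm = c(100, 499, 500, 1000),
    rna_reads = 5
  )
  expect_equal(neoantigen_burden(cand, gt), 2)  # strict < 500 nM
  expect_equal(neoantigen_burden(mutate(cand, rna_reads = 0), gt), 0)

  # allele loss at locus A: candidates on the lost allele are excluded
  lost <- gt
  lost$loss[lost$locus == "A"] <- TRUE
  lost$lost_allele[lost$locus == "A"] <- "A*01:01"
  two <- tibble(peptide = c("P1", "P2"),
                hla_allele = c("A*01:01", "A*02:01"),
                median_affinity_nm = 100, rna_reads = 3)
  expect_equal(neoantigen_burden(two, gt), 2)
  expect_equal(neoantigen_burden(two, lost), 1)

  # loss never increases the burden (random fixtures)
  set.seed(9)
  for (i in 1:10) {
    cc <- tibble(peptide = sprintf("P%d", 1:8),
                 hla_allele = sample(c(gt$allele1, gt$allele2), 8, replace = TRUE),
                 median_affinity_nm = runif(8, 50, 900),
                 rna_reads = sample(0:5, 8, replace = TRUE))
    expect_lte(neoantigen_burden(cc, lost), neoantigen_burden(cc, gt))
  }

  stranger <- tibble(peptide = "P", hla_allele = "A*68:01",
                     median_affinity_nm = 10, rna_reads = 1)
  expect_error(neoantigen_burden(stranger, gt), class = "motiscore_data_error")
})

test_that("TCR entropy follows the Shannon formula on alpha clones seen twice", {
  uniform <- tibble(chain = "alpha", cdr3 = letters[1:4], count = 2)
  expect_equal(tcr_entropy(uniform), log(4), tolerance = 1e-12)

  single <- tibble(chain = "alpha", cdr3 = "a", count = 10)
  expect_equal(tcr_entropy(single), 0)

  mixed <- tibble(chain = "alpha", cdr3 = letters[1:3], count = c(5, 3, 2))
  expect_equal(tcr_entropy(mixed),
               -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)),
               tolerance = 1e-12)

  # singletons are dropped before the formula
  with_singletons <- tibble(chain = "alpha", cdr3 = letters[1:3], count = c(1, 1, 7))
  expect_equal(tcr_entropy(with_singletons), 0)

  # beta clones never contribute
  both <- bind_rows(uniform, tibble(chain = "beta", cdr3 = "x", count = 50))
  expect_equal(tcr_entropy(both), log(4))
})

test_that("entropy is bounded by ln(retained clones) with equality at uniform", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    cl <- tibble(chain = "alpha", cdr3 = as.character(seq_len(n)),
                 count = sample(2:40, n, replace = TRUE))
    h <- tcr_entropy(cl)
    expect_gte(h, 0)
    expect_lte(h, log(n) + 1e-12)
  }
})

test_that("resistance flag needs a deleterious main-clone hit in the 7-gene set", {
  b2m_clonal <- make_variants(1, gene = "B2M", impact = "high", vaf = 0.45)
  expect_equal(resistance_flag(b2m_clonal, NULL, tumor_clonality = 0.5), -1L)

  b2m_subclonal <- make_variants(1, gene = "B2M", impact = "high", vaf = 0.30)
  expect_equal(resistance_flag(b2m_subclonal, NULL, tumor_clonality = 0.5), 0L)

  # CMC annotation qualifies even at moderate impact; CALX alias resolves
  calx <- make_variants(1, gene = "CALX", impact = "moderate",
                        cmc_annotated = TRUE, vaf = 0.45)
  expect_equal(resistance_flag(calx, NULL, tumor_clonality = 0.5), -1L)

  other_gene <- make_variants(1, gene = "KRAS", impact = "high", vaf = 0.45)
  expect_equal(resistance_flag(other_gene, NULL, tumor_clonality = 0.5), 0L)

  # homozygous deletion route with main-clone CNV clonality
  dele <- tibble(chrom = "chr15", start = 0, end = 1e5, copy_number = 0,
                 clonality = 0.45, loglikelihood = 200, genes = "B2M,OTHER")
  expect_equal(resistance_flag(make_variants(0), dele, tumor_clonality = 0.5), -1L)
  subclonal_del <- mutate(dele, clonality = 0.30)
  expect_equal(resistance_flag(make_variants(0), subclonal_del,
                               tumor_clonality = 0.5), 0L)

  expect_error(resistance_flag(b2m_clonal, NULL, tumor_clonality = 0),
               class = "motiscore_data_error")
})

test_that("response flag requires high impact plus CMC, at any clonality", {
  hit <- make_variants(1, gene = "LRP1B", impact = "high",
                       cmc_annotated = TRUE, vaf = 0.06, tumor_depth = 100)
  expect_equal(response_flag(hit, NULL), 1L)

  unclear <- make_variants(1, gene = "LRP1B", impact = "moderate",
                           cmc_annotated = FALSE)
  expect_equal(response_flag(unclear, NULL), 0L)
  no_cmc <- make_variants(1, gene = "LRP1B", impact = "high", cmc_annotated = FALSE)
  expect_equal(response_flag(no_cmc, NULL), 0L)
  expect_equal(response_flag(make_variants(0), NULL), 0L)

  homdel <- tibble(chrom = "chr2", start = 0, end = 1e5, copy_number = 0,
                   clonality = 0.05, loglikelihood = 150, genes = "LRP1B")
  expect_equal(response_flag(make_variants(0), homdel), 1L)
})

test_that("CPM normalization and the expression markers are exact arithmetic", {
  counts <- tibble(gene = c("CD274", "B2M", "OTHER"),
                   S1 = c(500, 250000, 749500))
  x <- cpm(counts)
  expect_equal(sum(x$S1), 1e6)
  em <- expression_markers(counts, "S1")
  expect_equal(em$pdl1_cpm, 500)
  expect_equal(em$b2m_cpm, 250000)

  zero <- tibble(gene = "CD274", S1 = 0)
  expect_error(expression_markers(zero, "S1"), class = "motiscore_data_error")

  counts0 <- tibble(gene = c("CD274", "B2M"), S1 = c(0, 100))
  expect_equal(expression_markers(counts0, "S1")$pdl1_cpm, 0)
})

test_that("combined chemokine marker is the mean log2 FC against cohort medians", {
  base <- c(CXCL9 = 4000, CXCL10 = 8000, CXCL11 = 2000, FILLER = 986000)
  mk <- function(mult) {
    v <- base
    v[1:3] <- v[1:3] * mult
    v["FILLER"] <- 1e6 - sum(v[1:3])
    v
  }
  counts <- tibble(gene = names(base),
                   S1 = mk(1), S2 = mk(1), S3 = mk(1), S4 = mk(1), S5 = mk(2))
  expect_equal(cxcl_combined(counts, "S1"), 0, tolerance = 1e-6)
  expect_equal(cxcl_combined(counts, "S5"), 1, tolerance = 0.01)

  # genes at {4x, 1x, 1x} the median -> about 2/3
  v6 <- base
  v6["CXCL9"] <- v6["CXCL9"] * 4
  v6["FILLER"] <- 1e6 - sum(v6[1:3])
  counts$S6 <- v6
  expect_equal(cxcl_combined(counts, "S6"), 2 / 3, tolerance = 0.01)

  expect_error(cxcl_combined(tibble(gene = "CXCL9", S1 = 10), "S1"),
               class = "motiscore_data_error")
})

test_that("panel assembly matches individually computed biomarkers and marks gaps", {
  raw <- simulate_raw_sample(seed = 31, plant_resistance = TRUE)
  v <- variant_qc(raw$variants)
  panel <- build_panel(
    sample_id = "S001", variants = v, cnvs = raw$cnvs, region = raw$region,
    clones = raw$clones, candidates = raw$neoantigens, genotype = raw$genotype,
    counts = raw$counts, tumor_clonality = raw$tumor_clonality
  )
  expect_equal(panel$tmb, compute_tmb(v, raw$region))
  expect_equal(panel$tcr_entropy, tcr_entropy(raw$clones))
  expect_equal(panel$neoantigen_burden,
               as.numeric(neoantigen_burden(raw$neoantigens, raw$genotype)))
  expect_equal(panel$resistance_flag, -1)
  expect_equal(panel$hed, hed(raw$genotype)$mean_hed)
  expect_equal(panel$pdl1_cpm, expression_markers(raw$counts, "S001")$pdl1_cpm)

  # no RNA inputs: RNA-derived fields are NA, not zero
  dna_only <- build_panel("S001", variants = v, cnvs = raw$cnvs,
                          region = raw$region,
                          tumor_clonality = raw$tumor_clonality)
  expect_true(is.na(dna_only$tcr_entropy))
  expect_true(is.na(dna_only$pdl1_cpm))
  expect_true(is.na(dna_only$b2m_cpm))
  expect_false(is.na(dna_only$tmb))
})
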