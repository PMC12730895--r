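#' Default per-biomarker simulation specification
#'
#' Marginal families and planted responder/non-responder effects for the
#' eight candidate biomarkers. Defaults emulate an ICI melanoma discovery
#' cohort: skewed (log-normal) TMB, neoantigen burden and expression
#' markers, roughly Gaussian entropy and HED; moderate planted shifts (in
#' latent SD units) for TMB, neoantigen burden, TCR entropy and PDL1;
#' a response-flag prevalence difference; rare, outcome-neutral resistance
#' alterations; null HED and B2M.
#'
#' @return A tibble with columns `biomarker`, `family`
#'   (`lognormal`/`normal`/`binary`), `mean`/`sd` (latent scale: meanlog
#'   and sdlog for log-normal), `shift` (responder shift in latent SD
#'   units), `prev_responder`/`prev_nonresponder` (binary families), and
#'   `flag_value` (the panel coding of a present binary flag).
#' @export
sim_biomarker_spec <- function() {
  tibble(
    biomarker = c("tmb", "neoantigen_burden", "tcr_entropy", "hed",
                  "pdl1_cpm", "b2m_cpm", "resistance_flag", "response_flag"),
    family = c("lognormal", "lognormal", "normal", "normal",
               "lognormal", "lognormal", "binary", "binary"),
    mean = c(1.6, 3.7, 4.0, 6.0, 2.0, 6.9, NA, NA),
    sd = c(1.0, 1.0, 1.5, 2.0, 1.0, 0.7, NA, NA),
    shift = c(0.6, 0.55, 0.7, 0, 0.45, 0, NA, NA),
    prev_responder = c(NA, NA, NA, NA, NA, NA, 0.01, 0.25),
    prev_nonresponder = c(NA, NA, NA, NA, NA, NA, 0.01, 0.08),
    flag_value = c(NA, NA, NA, NA, NA, NA, -1, 1)
  )
}

#' Simulation configuration
#'
#' Bundles the cohort design used by the synthetic generators: sample
#' size, responder fraction, per-biomarker effect specification,
#' correlation structure (induced through a Gaussian copula on the latent
#' scale), and the survival model. A seed is mandatory: the same seed and
#' configuration reproduce the data exactly.
#'
#' @param n_samples Cohort size (default 225).
#' @param responder_fraction Fraction of responders (default 98/225).
#' @param biomarkers Effect specification, see [sim_biomarker_spec()].
#' @param correlations Tibble of latent Spearman correlation targets with
#'   columns `a`, `b`, `rho` (default: TMB-neoantigen burden at 0.9).
#' @param survival List with `baseline_hazard` (events/day for the
#'   reference group), `hazard_ratio` (high vs low score group) and
#'   `censoring_rate`.
#' @param seed Integer root seed (mandatory).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 225, responder_fraction = 98 / 225,
                       biomarkers = sim_biomarker_spec(),
                       correlations = tibble(a = "tmb", b = "neoantigen_burden",
                                             rho = 0.9),
                       survival = list(baseline_hazard = 1 / 365,
                                       hazard_ratio = 0.5,
                                       censoring_rate = 0.2),
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort_config("sim_config requires a single integer `seed`")
  }
  if (responder_fraction < 0 || responder_fraction > 1) {
    abort_config("responder_fraction must be in [0, 1]")
  }
  cont <- filter(biomarkers, family != "binary")
  if (any(!is.finite(cont$sd) | cont$sd <= 0)) {
    abort_config("continuous biomarker SDs must be > 0")
  }
  binr <- filter(biomarkers, family == "binary")
  prevs <- c(binr$prev_responder, binr$prev_nonresponder)
  if (any(!is.finite(prevs) | prevs < 0 | prevs > 1)) {
    abort_config("binary biomarker prevalences must be in [0, 1]")
  }
  if (survival$censoring_rate < 0 || survival$censoring_rate > 1) {
    abort_config("censoring_rate must be in [0, 1]")
  }
  structure(
    list(n_samples = n_samples, responder_fraction = responder_fraction,
         biomarkers = biomarkers, correlations = correlations,
         survival = survival, seed = as.integer(seed)),
    class = "sim_config"
  )
}

latent_correlation_matrix <- function(config) {
  cont <- filter(config$biomarkers, family != "binary")$biomarker
  R <- diag(length(cont))
  dimnames(R) <- list(cont, cont)
  cors <- config$correlations
  if (!is.null(cors) && nrow(cors) > 0) {
    for (i in seq_len(nrow(cors))) {
      a <- cors$a[i]; b <- cors$b[i]
      if (a %in% cont && b %in% cont) {
        # Pearson latent correlation matching a Spearman target under the
        # Gaussian copula
        r <- 2 * sin(pi * cors$rho[i] / 6)
        R[a, b] <- R[b, a] <- r
      }
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort_config("correlation specification is not positive semi-definite")
  }
  R
}

#' Simulate a panel-level cohort with planted outcome effects
#'
#' Draws a cohort of biomarker panels: continuous biomarkers come from a
#' latent Gaussian copula (so correlation targets are met on the Spearman
#' scale) with per-group location shifts, then mapped to their marginal
#' families (log-normal or normal); binary flags are drawn from per-group
#' prevalences. Fully reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return A cohort tibble (`sample_id`, `outcome`, the eight biomarker
#'   columns) with the planted ground truth (group parameters) in the
#'   `truth` attribute.
#' @export
simulate_panels <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  R <- latent_correlation_matrix(config)
  cont <- filter(config$biomarkers, family != "binary")
  binr <- filter(config$biomarkers, family == "binary")
  n <- config$n_samples
  with_seed(derive_seed(config$seed, 1), {
    n_resp <- round(n * config$responder_fraction)
    outcome <- sample(c(rep("responder", n_resp),
                        rep("non_responder", n - n_resp)))
    L <- chol(R)
    z <- matrix(rnorm(n * nrow(cont)), nrow = n) %*% L
    colnames(z) <- cont$biomarker
    panel <- tibble(sample_id = sprintf("S%03d", seq_len(n)), outcome = outcome)
    is_resp <- outcome == "responder"
    for (i in seq_len(nrow(cont))) {
      b <- cont$biomarker[i]
      latent <- cont$mean[i] + cont$sd[i] * (z[, b] + cont$shift[i] * is_resp)
      panel[[b]] <- if (cont$family[i] == "lognormal") exp(latent) else latent
    }
    for (i in seq_len(nrow(binr))) {
      prev <- if_else(is_resp, binr$prev_responder[i], binr$prev_nonresponder[i])
      panel[[binr$biomarker[i]]] <- binr$flag_value[i] * rbinom(n, 1, prev)
    }
    panel <- panel[, c("sample_id", "outcome", config$biomarkers$biomarker)]
    attr(panel, "truth") <- list(
      biomarkers = config$biomarkers,
      correlations = config$correlations,
      n_responder = n_resp
    )
    panel
  })
}

#' Simulate survival outcomes for score groups
#'
#' Event times are exponential with the configured baseline hazard for the
#' `low` group and `baseline_hazard * hazard_ratio` for the `high` group.
#' Censoring is independent uniform on (0, tau), with tau solved
#' numerically so the expected overall censoring fraction matches the
#' configured rate; rate 0 disables censoring and rate 1 censors
#' everything at time 0+.
#'
#' @param config A [sim_config()].
#' @param groups Factor/character vector over `low`/`high`.
#' @return A tibble `group`, `time`, `event`.
#' @export
simulate_survival <- function(config, groups) {
  stopifnot(inherits(config, "sim_config"))
  groups <- as.character(groups)
  if (!all(groups %in% c("low", "high"))) {
    abort_config("groups must be 'low' or 'high'")
  }
  lam0 <- config$survival$baseline_hazard
  hr <- config$survival$hazard_ratio
  rate <- config$survival$censoring_rate
  lam <- if_else(groups == "high", lam0 * hr, lam0)
  with_seed(derive_seed(config$seed, 2), {
    t_event <- rexp(length(groups), rate = lam)
    if (rate <= 0) {
      return(tibble(group = groups, time = t_event, event = TRUE))
    }
    if (rate >= 1) {
      return(tibble(group = groups, time = rep(0, length(groups)),
                    event = FALSE))
    }
    # P(censored) = P(C < T) for C ~ U(0, tau), T ~ Exp(lam) is
    # (1 - exp(-lam*tau)) / (lam*tau); averaged over the group hazards
    cens_frac <- function(tau) mean((1 - exp(-lam * tau)) / (lam * tau))
    lam_bar <- mean(lam)
    tau <- uniroot(function(x) cens_frac(x) - rate,
                   lower = 1e-9 / lam_bar, upper = 1e9 / lam_bar,
                   tol = 1e-12)$root
    t_cens <- runif(length(groups), 0, tau)
    tibble(group = groups,
           time = pmin(t_event, t_cens),
           event = t_event <= t_cens)
  })
}

#' Simulate raw-level molecular inputs for one sample
#'
#' Generates the desk-scale input files for a single tumor sample --
#' somatic variant table, CNV table, TCR clonotype table, neoantigen
#' candidate table, an expression count column and an HLA genotype --
#' together with the planted ground-truth biomarker values they encode.
#' Realism targets the parsers and formulas (coordinates, counts and flags
#' are planted; sequences are random strings), not biology.
#'
#' @param seed Integer seed.
#' @param sample_id Sample name (default `"S001"`).
#' @param dir Optional directory; when given, the tables are written as
#'   TSV/BED plus a `truth.json`, laid out as the readers expect.
#' @param n_nonsyn,n_syn Planted nonsynonymous / synonymous-level variant
#'   counts inside the region (defaults 12 and 5).
#' @param region_mb Target region size in Mb (default 2).
#' @param n_alpha_clones Distinct alpha clones, uniform at `clone_count`
#'   each (defaults 8 and 2), giving entropy `log(n_alpha_clones)`.
#' @param clone_count Count per planted alpha clone.
#' @param n_neoantigens Planted passing neoantigen candidates (default 6).
#' @param plant_resistance Plant a clonal high-impact B2M variant
#'   (default `FALSE`).
#' @param plant_response Plant a high-impact CMC-annotated LRP1B variant
#'   (default `FALSE`).
#' @param tumor_clonality Planted tumor clonality (default 0.6).
#' @return A list with elements `variants`, `cnvs`, `region`, `clones`,
#'   `neoantigens`, `counts`, `genotype`, `tumor_clonality` and `truth`
#'   (planted biomarker values).
#' @export
simulate_raw_sample <- function(seed, sample_id = "S001", dir = NULL,
                                n_nonsyn = 12, n_syn = 5, region_mb = 2,
                                n_alpha_clones = 8, clone_count = 2,
                                n_neoantigens = 6, plant_resistance = FALSE,
                                plant_response = FALSE, tumor_clonality = 0.6) {
  with_seed(derive_seed(seed, 3), {
    region <- interval_set(c("chr1", "chr2"),
                           c(0, 0), c(region_mb * 5e5, region_mb * 5e5))
    rand_gene <- function(n) sprintf("GENE%04d", sample.int(9999, n))
    rand_base <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
    rand_pep <- function(n, len) {
      map_chr(seq_len(n), ~ paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                         len, replace = TRUE), collapse = ""))
    }
    mk_variants <- function(n, impacts, inside = TRUE, gene = NULL,
                            vaf = NULL, cmc = FALSE) {
      if (n == 0) return(NULL)
      chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
      pos <- if (inside) {
        sample.int(region_mb * 5e5 - 1, n) + 1  # 1-based, inside [0, end)
      } else {
        region_mb * 5e5 + sample.int(1e5, n)
      }
      vaf <- vaf %||% runif(n, 0.1, 0.5)
      depth <- sample(40:120, n, replace = TRUE)
      tibble(
        chrom = chrom, pos = pos, ref = rand_base(n), alt = rand_base(n),
        gene = gene %||% rand_gene(n), vaf = vaf,
        alt_reads = round(vaf * depth),
        tumor_depth = depth, normal_depth = sample(30:80, n, replace = TRUE),
        impact = impacts, cmc_annotated = cmc, in_gnomad = FALSE,
        kind = "SNV"
      )
    }
    variants <- bind_rows(
      mk_variants(n_nonsyn, sample(c("moderate", "high"), n_nonsyn, TRUE)),
      mk_variants(n_syn, rep("synonymous_or_lower", n_syn)),
      mk_variants(3, sample(c("moderate", "high"), 3, TRUE), inside = FALSE),
      # flag plants sit outside the target region so the planted TMB stays
      # n_nonsyn / region_mb (the flags themselves ignore the region)
      if (plant_resistance) {
        mk_variants(1, "high", gene = "B2M", inside = FALSE,
                    vaf = min(0.95, tumor_clonality))
      },
      if (plant_response) {
        mk_variants(1, "high", gene = "LRP1B", inside = FALSE, cmc = TRUE)
      }
    )
    variants$impact <- classify_impact(variants$impact)
    cnvs <- tibble(
      chrom = "chr3", start = c(1e6, 5e6), end = c(2e6, 6e6),
      copy_number = c(3, 1), clonality = c(0.5, 0.3),
      loglikelihood = c(250, 180), genes = c("GENEX1", "GENEX2")
    )
    clones <- bind_rows(
      tibble(chain = "alpha",
             cdr3 = rand_pep(n_alpha_clones, 12),
             count = rep(clone_count, n_alpha_clones)),
      tibble(chain = "alpha", cdr3 = rand_pep(2, 12), count = 1),  # singletons
      tibble(chain = "beta", cdr3 = rand_pep(3, 12), count = 4)
    )
    genotype <- hla_genotype(
      locus = c("A", "B", "C"),
      allele1 = c("A*01:01", "B*07:02", "C*04:01"),
      allele2 = c("A*02:01", "B*08:01", "C*07:01")
    )
    neo_alleles <- sample(c(genotype$allele1, genotype$allele2),
                          n_neoantigens + 2, replace = TRUE)
    neoantigens <- tibble(
      peptide = rand_pep(n_neoantigens + 2, 9),
      hla_allele = neo_alleles,
      median_affinity_nm = c(runif(n_neoantigens, 20, 450),
                             runif(2, 600, 5000)),
      rna_reads = c(sample(1:30, n_neoantigens, replace = TRUE), 0, 0)
    )
    genes <- c("CD274", "B2M", "CXCL9", "CXCL10", "CXCL11", rand_gene(20))
    counts <- tibble(gene = genes)
    counts[[sample_id]] <- c(500, 20000, 150, 300, 80,
                             sample(50:5000, 20, replace = TRUE))
    truth <- list(
      tmb = n_nonsyn / region_mb,
      tcr_entropy = log(n_alpha_clones),
      neoantigen_burden = n_neoantigens,
      resistance_flag = if (plant_resistance) -1L else 0L,
      response_flag = if (plant_response) 1L else 0L,
      pdl1_cpm = 1e6 * counts[[sample_id]][1] / sum(counts[[sample_id]]),
      b2m_cpm = 1e6 * counts[[sample_id]][2] / sum(counts[[sample_id]]),
      tumor_clonality = tumor_clonality
    )
    out <- list(variants = variants, cnvs = cnvs, region = region,
                clones = clones, neoantigens = neoantigens, counts = counts,
                genotype = genotype, tumor_clonality = tumor_clonality,
                truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_variants(variants, file.path(dir, "variants.tsv"))
      readr::write_tsv(cnvs, file.path(dir, "cnvs.tsv"))
      write_intervals(region, file.path(dir, "region.bed"))
      readr::write_tsv(clones, file.path(dir, "clones.tsv"))
      readr::write_tsv(neoantigens, file.path(dir, "neoantigens.tsv"))
      readr::write_tsv(counts, file.path(dir, "counts.tsv"))
      readr::write_tsv(select(genotype, locus, allele1, allele2),
                       file.path(dir, "hla.tsv"))
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    out
  })
}
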