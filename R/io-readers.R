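#' Read an annotated somatic variant table
#'
#' Supports two dialects: the tool's TSV dialect (one row per somatic call)
#' and VCF with annotation carried in INFO keys. All records are validated
#' against the variant invariants; malformed rows are reported with their
#' row numbers.
#'
#' The TSV dialect expects columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `gene`, `vaf`, `alt_reads`, `tumor_depth`, `normal_depth`, `impact`
#' (category label or VEP consequence term), `cmc_annotated`, `in_gnomad`,
#' `kind` (`SNV`/`indel`). For VCF the per-record annotations are read from
#' INFO keys named in `mapping` (defaults: `GENE`, `VAF`, `ALT_READS`,
#' `TDP`, `NDP`, `IMPACT`, `CMC`, `GNOMAD`).
#'
#' @param path Path to the variant file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param mapping Named list overriding column / INFO-key names.
#' @return A validated tibble of variant records.
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf"), mapping = list()) {
  dialect <- arg_match(dialect)
  if (dialect == "tsv") {
    # read as character first: allele strings like "T" must never be
    # type-guessed into logicals
    df <- readr::read_tsv(path, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    map <- modifyList(list(
      chrom = "chrom", pos = "pos", ref = "ref", alt = "alt", gene = "gene",
      vaf = "vaf", alt_reads = "alt_reads", tumor_depth = "tumor_depth",
      normal_depth = "normal_depth", impact = "impact",
      cmc_annotated = "cmc_annotated", in_gnomad = "in_gnomad", kind = "kind"
    ), mapping)
    require_columns(df, unlist(map), "variant TSV")
    df <- tibble(
      chrom = as.character(df[[map$chrom]]),
      pos = as.numeric(df[[map$pos]]),
      ref = as.character(df[[map$ref]]),
      alt = as.character(df[[map$alt]]),
      gene = as.character(df[[map$gene]]),
      vaf = as.numeric(df[[map$vaf]]),
      alt_reads = as.numeric(df[[map$alt_reads]]),
      tumor_depth = as.numeric(df[[map$tumor_depth]]),
      normal_depth = as.numeric(df[[map$normal_depth]]),
      impact = as.character(df[[map$impact]]),
      cmc_annotated = as.logical(df[[map$cmc_annotated]]),
      in_gnomad = as.logical(df[[map$in_gnomad]]),
      kind = as.character(df[[map$kind]])
    )
  } else {
    df <- read_variants_vcf(path, mapping)
  }
  validate_variants(df)
}

read_variants_vcf <- function(path, mapping = list()) {
  check_installed("vcfR")
  map <- modifyList(list(
    gene = "GENE", vaf = "VAF", alt_reads = "ALT_READS", tumor_depth = "TDP",
    normal_depth = "NDP", impact = "IMPACT", cmc_annotated = "CMC",
    in_gnomad = "GNOMAD"
  ), mapping)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_raw <- v@fix[, "INFO"]
  info_of <- function(key, numeric = FALSE) {
    x <- vcfR::extract.info(v, element = key)
    if (numeric) suppressWarnings(as.numeric(x)) else x
  }
  flag_of <- function(key) {
    # INFO flags are bare keys (Type=Flag) or KEY=1/KEY=true values
    bare <- grepl(paste0("(^|;)", key, "(;|$)"), info_raw)
    val <- vcfR::extract.info(v, element = key)
    bare | (!is.na(val) & val != "0" & tolower(val) != "false")
  }
  tibble(
    chrom = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_of(map$gene),
    vaf = info_of(map$vaf, numeric = TRUE),
    alt_reads = info_of(map$alt_reads, numeric = TRUE),
    tumor_depth = info_of(map$tumor_depth, numeric = TRUE),
    normal_depth = info_of(map$normal_depth, numeric = TRUE),
    impact = info_of(map$impact),
    cmc_annotated = flag_of(map$cmc_annotated),
    in_gnomad = flag_of(map$in_gnomad),
    kind = if_else(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1, "SNV", "indel")
  )
}

#' Validate a variant table against the record invariants
#'
#' Checks positions (>= 1), VAF range, non-negative read counts, the
#' read-support consistency `vaf * tumor_depth ~ alt_reads` (within one
#' read of rounding), the impact vocabulary and the SNV/indel kind.
#'
#' @param df A variant tibble as returned by [read_variants()].
#' @return The validated tibble with `impact` as an ordered factor.
#' @export
validate_variants <- function(df) {
  require_columns(df, c("chrom", "pos", "vaf", "alt_reads", "tumor_depth",
                        "normal_depth", "impact", "kind"), "variant table")
  problems <- character()
  flag <- function(cond, what) {
    bad <- which(cond)
    if (length(bad) > 0) {
      problems <<- c(problems, sprintf("row %d: %s", head(bad, 5), what))
    }
  }
  flag(!is.finite(df$pos) | df$pos < 1, "pos must be >= 1")
  flag(!is.finite(df$vaf) | df$vaf < 0 | df$vaf > 1, "vaf must be in [0, 1]")
  flag(!is.finite(df$alt_reads) | df$alt_reads < 0, "alt_reads must be >= 0")
  flag(!is.finite(df$tumor_depth) | df$tumor_depth < 0, "tumor_depth must be >= 0")
  flag(!is.finite(df$normal_depth) | df$normal_depth < 0, "normal_depth must be >= 0")
  flag(abs(round(df$vaf * df$tumor_depth) - df$alt_reads) > 1,
       "vaf * tumor_depth inconsistent with alt_reads")
  flag(!df$kind %in% c("SNV", "indel"), "kind must be SNV or indel")
  if (length(problems) > 0) {
    abort_format(paste0("malformed variant record(s):\n",
                        paste(problems, collapse = "\n")))
  }
  df$impact <- classify_impact(df$impact)
  as_tibble(df)
}

#' Write a variant table in the TSV dialect
#'
#' @param df A validated variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(df, path) {
  out <- df
  out$impact <- as.character(out$impact)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a TCR clonotype table
#'
#' Supports AIRR rearrangement TSVs (columns `locus`/`v_call`,
#' `junction_aa`, `duplicate_count`) and TRUST4-style report TSVs
#' (`#count`, `CDR3aa`, `V`). Because clonotype-report column names vary
#' between tools, the mapping is overridable via `mapping` with entries
#' `chain`, `cdr3`, `count`. Chains are normalized to `alpha`/`beta`
#' (TRA/TRB); clones on other chains are dropped.
#'
#' @param path Path to the clonotype TSV.
#' @param dialect `"airr"` or `"trust4"`.
#' @param mapping Named list overriding column names.
#' @return A tibble with columns `chain`, `cdr3`, `count` (count >= 1).
#' @export
read_clones <- function(path, dialect = c("airr", "trust4"), mapping = list()) {
  dialect <- arg_match(dialect)
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  defaults <- if (dialect == "airr") {
    list(chain = "locus", cdr3 = "junction_aa", count = "duplicate_count")
  } else {
    list(chain = "V", cdr3 = "CDR3aa", count = "#count")
  }
  map <- modifyList(defaults, mapping)
  require_columns(df, unlist(map), "clonotype table")
  raw_chain <- toupper(as.character(df[[map$chain]]))
  chain <- case_when(
    grepl("^TRA", raw_chain) | raw_chain == "ALPHA" ~ "alpha",
    grepl("^TRB", raw_chain) | raw_chain == "BETA" ~ "beta",
    TRUE ~ NA_character_
  )
  out <- tibble(
    chain = chain,
    cdr3 = as.character(df[[map$cdr3]]),
    count = as.numeric(df[[map$count]])
  )
  out <- filter(out, !is.na(chain))
  if (any(!is.finite(out$count) | out$count < 1)) {
    abort_format("clone counts must be integers >= 1")
  }
  out
}

#' Read a neoantigen candidate table
#'
#' Reads a pVACseq-like TSV of predicted MHC-I binding peptides. Default
#' column names are the tool's canonical ones (`peptide`, `hla_allele`,
#' `median_affinity_nm`, `rna_reads`); override via `mapping` for other
#' report dialects. HLA allele names must parse to a class-I locus (A, B
#' or C) at 4-digit resolution.
#'
#' @param path Path to the candidate TSV.
#' @param mapping Named list overriding column names.
#' @return A tibble with columns `peptide`, `hla_allele`,
#'   `median_affinity_nm` (> 0, in nM) and `rna_reads` (>= 0).
#' @export
read_neoantigens <- function(path, mapping = list()) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  map <- modifyList(list(
    peptide = "peptide", hla_allele = "hla_allele",
    median_affinity_nm = "median_affinity_nm", rna_reads = "rna_reads"
  ), mapping)
  require_columns(df, unlist(map), "neoantigen table")
  out <- tibble(
    peptide = as.character(df[[map$peptide]]),
    hla_allele = normalize_hla_allele(as.character(df[[map$hla_allele]])),
    median_affinity_nm = as.numeric(df[[map$median_affinity_nm]]),
    rna_reads = as.numeric(df[[map$rna_reads]])
  )
  if (any(!is.finite(out$median_affinity_nm) | out$median_affinity_nm <= 0)) {
    abort_format("median_affinity_nm must be positive")
  }
  if (any(!is.finite(out$rna_reads) | out$rna_reads < 0)) {
    abort_format("rna_reads must be >= 0")
  }
  out
}

normalize_hla_allele <- function(x) {
  x <- sub("^HLA-", "", toupper(x))
  ok <- grepl("^[ABC]\\*[0-9]+:[0-9]+$", x)
  if (any(!ok)) {
    abort_vocab(sprintf(
      "HLA allele name(s) do not parse to a 4-digit class-I allele: %s",
      paste(unique(x[!ok]), collapse = ", ")
    ))
  }
  x
}

hla_locus <- function(allele) substr(normalize_hla_allele(allele), 1, 1)

#' Read a gene-by-sample raw count matrix
#'
#' Expects a TSV whose first column holds gene identifiers and whose
#' remaining columns are one sample each. Negative entries are rejected.
#'
#' @param path Path to the counts TSV.
#' @return A tibble with column `gene` followed by one numeric column per
#'   sample.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(df) < 2) {
    abort_format("counts table needs a gene column plus at least one sample")
  }
  names(df)[1] <- "gene"
  df$gene <- as.character(df$gene)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    abort_integrity("counts matrix must contain non-negative finite numbers")
  }
  if (anyDuplicated(df$gene)) {
    abort_integrity("duplicate gene identifiers in counts table")
  }
  as_tibble(df)
}

#' Read a clinical table
#'
#' Expects one row per sample with columns `sample_id`, a RECIST label
#' (`recist`, values CR/PR/SD/PD; or an `outcome` column already coded
#' `responder`/`non_responder`/`unknown`), and optionally `survival_time`
#' (days), `event` (logical) and `cancer_type`. CR and PR map to
#' `responder`, SD and PD to `non_responder`, anything else to `unknown`.
#'
#' @param path Path to the clinical TSV.
#' @return A tibble with columns `sample_id`, `outcome`, `survival_time`,
#'   `event`, `cancer_type`.
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  require_columns(df, "sample_id", "clinical table")
  if (anyDuplicated(df$sample_id)) {
    abort_integrity(sprintf(
      "duplicate sample_id in clinical table: %s",
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")
    ))
  }
  outcome <- if ("outcome" %in% names(df)) {
    x <- as.character(df$outcome)
    bad <- !x %in% c("responder", "non_responder", "unknown") & !is.na(x)
    if (any(bad)) {
      abort_vocab(sprintf("unknown outcome label(s): %s",
                          paste(unique(x[bad]), collapse = ", ")))
    }
    replace(x, is.na(x), "unknown")
  } else if ("recist" %in% names(df)) {
    recist_outcome(df$recist)
  } else {
    abort_format("clinical table needs a `recist` or `outcome` column")
  }
  tibble(
    sample_id = as.character(df$sample_id),
    outcome = outcome,
    survival_time = if ("survival_time" %in% names(df)) as.numeric(df$survival_time) else NA_real_,
    event = if ("event" %in% names(df)) as.logical(df$event) else NA,
    cancer_type = if ("cancer_type" %in% names(df)) as.character(df$cancer_type) else NA_character_
  )
}

#' Map RECIST labels to binary outcomes
#'
#' Complete and partial responses (CR, PR) are responders; stable and
#' progressive disease (SD, PD) are non-responders; any other label maps
#' to `unknown`.
#'
#' @param x Character vector of RECIST labels.
#' @return Character vector over `responder`/`non_responder`/`unknown`.
#' @export
recist_outcome <- function(x) {
  case_when(
    toupper(x) %in% c("CR", "PR") ~ "responder",
    toupper(x) %in% c("SD", "PD") ~ "non_responder",
    TRUE ~ "unknown"
  )
}

#' Construct an HLA class-I genotype
#'
#' @param locus Character vector over `A`, `B`, `C`.
#' @param allele1,allele2 4-digit allele names (e.g. `"A*02:01"`).
#' @param grooves Optional allele-to-groove-sequence table (columns
#'   `allele`, `groove_seq`); defaults to the packaged synthetic table.
#'   Both groove sequences at a locus must have equal aligned length.
#' @return A tibble with columns `locus`, `allele1`, `allele2`,
#'   `groove1`, `groove2`, `loss` (FALSE), `lost_allele` (NA).
#' @export
hla_genotype <- function(locus, allele1, allele2, grooves = hla_grooves()) {
  locus <- toupper(as.character(locus))
  if (any(!locus %in% c("A", "B", "C")) || anyDuplicated(locus)) {
    abort_data("locus must be distinct values from A, B, C")
  }
  allele1 <- normalize_hla_allele(allele1)
  allele2 <- normalize_hla_allele(allele2)
  if (any(substr(allele1, 1, 1) != locus) || any(substr(allele2, 1, 1) != locus)) {
    abort_data("allele names must belong to their locus")
  }
  seq_of <- function(al) {
    s <- grooves$groove_seq[match(al, grooves$allele)]
    if (any(is.na(s))) {
      abort_data(sprintf("no groove sequence for allele(s): %s",
                         paste(al[is.na(s)], collapse = ", ")))
    }
    s
  }
  g1 <- seq_of(allele1)
  g2 <- seq_of(allele2)
  if (any(nchar(g1) != nchar(g2))) {
    abort_data("groove sequences at a locus must have equal aligned length")
  }
  tibble(locus = locus, allele1 = allele1, allele2 = allele2,
         groove1 = g1, groove2 = g2, loss = FALSE, lost_allele = NA_character_)
}

#' Packaged synthetic HLA binding-groove sequence table
#'
#' Stand-in aligned groove sequences (24 residues) for common class-I
#' alleles, generated for testing; they are not IMGT sequences. Supply a
#' real alignment table to [hla_genotype()] for production use.
#'
#' @return A tibble with columns `allele` and `groove_seq`.
#' @export
hla_grooves <- function() {
  path <- system.file("extdata", "hla_grooves_synthetic.tsv", package = "motiscore")
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}
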