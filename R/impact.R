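#' Variant impact vocabulary
#'
#' Somatic variants are classified on a four-level ordered scale derived
#' from VEP consequence severity: `synonymous_or_lower` <
#' `protein_altering` < `moderate` < `high`. Variants ranked strictly above
#' "protein altering variant" (the `moderate` and `high` levels) count as
#' nonsynonymous for tumor mutation burden.
#'
#' @return Character vector of the four levels, lowest first.
#' @export
impact_levels <- function() {
  c("synonymous_or_lower", "protein_altering", "moderate", "high")
}

#' Packaged VEP consequence-to-impact table
#'
#' @return A tibble with columns `consequence` (VEP term) and `impact`
#'   (one of [impact_levels()]).
#' @export
vep_impact_table <- function() {
  path <- system.file("extdata", "vep_impact.tsv", package = "motiscore")
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Classify impact labels against the packaged vocabulary
#'
#' Accepts either the four category labels directly or VEP consequence
#' terms, which are mapped through [vep_impact_table()]. Unknown labels
#' raise a vocabulary error naming the offending value.
#'
#' @param x Character vector of impact labels or VEP consequence terms.
#' @return An ordered factor over [impact_levels()].
#' @export
classify_impact <- function(x) {
  levels <- impact_levels()
  x <- as.character(x)
  out <- ifelse(x %in% levels, x, NA_character_)
  needs_map <- is.na(out) & !is.na(x)
  if (any(needs_map)) {
    tab <- vep_impact_table()
    mapped <- tab$impact[match(x[needs_map], tab$consequence)]
    out[needs_map] <- mapped
  }
  unknown <- !is.na(x) & is.na(out)
  if (any(unknown)) {
    abort_vocab(sprintf(
      "unknown impact label%s: %s (expected one of %s or a VEP consequence term)",
      if (sum(unknown) > 1) "s" else "",
      paste(unique(x[unknown]), collapse = ", "),
      paste(levels, collapse = ", ")
    ))
  }
  factor(out, levels = levels, ordered = TRUE)
}

#' Is an impact nonsynonymous (higher than protein-altering)?
#'
#' @param impact Vector of impact labels.
#' @return Logical vector; `TRUE` for `moderate` or `high`.
#' @export
is_nonsynonymous <- function(impact) {
  as.character(impact) %in% c("moderate", "high")
}
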