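#' Construct a fitted score model object
#'
#' The model holds everything needed to score a new sample: the ordered
#' selected biomarkers, their selection p-values, the normalized -log10(p)
#' weights, the discovery-cohort standardization constants, and the Youden
#' classification cutoff.
#'
#' @param selected Ordered character vector of selected biomarker names.
#' @param p_value,weight,mean,sd Numeric vectors parallel to `selected`.
#' @param cutoff Youden threshold (may be `NA` if not fitted).
#' @param provenance Named list of fit metadata (n, seed, date, ...).
#' @return An object of class `motiscore_model`.
#' @export
score_model <- function(selected, p_value, weight, mean, sd,
                        cutoff = NA_real_, provenance = list()) {
  m <- structure(
    list(
      schema_version = 1L,
      selected = as.character(selected),
      p_value = setNames(as.numeric(p_value), selected),
      weight = setNames(as.numeric(weight), selected),
      mean = setNames(as.numeric(mean), selected),
      sd = setNames(as.numeric(sd), selected),
      cutoff = as.numeric(cutoff),
      provenance = provenance
    ),
    class = "motiscore_model"
  )
  validate_score_model(m)
}

#' Validate a score model's invariants
#'
#' Weights must be positive and sum to one within 1e-9; every selected
#' biomarker needs a positive standard deviation.
#'
#' @param m A `motiscore_model`.
#' @return `m`, invisibly validated.
#' @export
validate_score_model <- function(m) {
  k <- length(m$selected)
  if (k == 0) abort_integrity("model has no selected biomarkers")
  lens <- lengths(m[c("p_value", "weight", "mean", "sd")])
  if (any(lens != k)) {
    abort_integrity("model fields p_value/weight/mean/sd must match `selected` in length")
  }
  if (any(!is.finite(m$weight)) || any(m$weight <= 0)) {
    abort_integrity("all model weights must be positive")
  }
  if (abs(sum(m$weight) - 1) > 1e-9) {
    abort_integrity(sprintf("model weights must sum to 1 (got %.12f)", sum(m$weight)))
  }
  if (any(!is.finite(m$sd)) || any(m$sd <= 0)) {
    abort_integrity("model standardization sd must be > 0 for every selected biomarker")
  }
  m
}

#' Save a score model as JSON
#'
#' The on-disk format is schema-versioned JSON so fitted models are
#' transparent and diffable, in keeping with the score's interpretability
#' goal.
#'
#' @param model A `motiscore_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  validate_score_model(model)
  jsonlite::write_json(
    list(
      schema_version = model$schema_version,
      selected = model$selected,
      p_value = as.list(model$p_value),
      weight = as.list(model$weight),
      mean = as.list(model$mean),
      sd = as.list(model$sd),
      cutoff = model$cutoff,
      provenance = model$provenance
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Load a score model from JSON
#'
#' The loaded model is re-validated; a tampered file (e.g. weights no
#' longer summing to one, or a non-positive sd) raises an integrity error.
#'
#' @param path Path to a model JSON written by [save_model()].
#' @return A `motiscore_model`.
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  needed <- c("selected", "p_value", "weight", "mean", "sd")
  if (!all(needed %in% names(x))) {
    abort_integrity("model JSON lacks required fields")
  }
  sel <- unlist(x$selected)
  num_field <- function(f) {
    v <- unlist(x[[f]])
    if (is.null(names(v)) || !setequal(names(v), sel)) {
      if (length(v) == length(sel)) names(v) <- sel else {
        abort_integrity(sprintf("model field `%s` does not match selected biomarkers", f))
      }
    }
    as.numeric(v[sel])
  }
  score_model(
    selected = sel,
    p_value = num_field("p_value"),
    weight = num_field("weight"),
    mean = num_field("mean"),
    sd = num_field("sd"),
    cutoff = if (is.null(x$cutoff)) NA_real_ else as.numeric(x$cutoff),
    provenance = if (is.null(x$provenance)) list() else x$provenance
  )
}

#' @export
print.motiscore_model <- function(x, ...) {
  cat("Multi-omics immunogenicity score model\n")
  cat(sprintf("  %d selected biomarker(s); cutoff = %s\n",
              length(x$selected),
              if (is.na(x$cutoff)) "<unset>" else format(x$cutoff, digits = 4)))
  df <- tibble(biomarker = x$selected, weight = unname(x$weight),
               p_value = unname(x$p_value), mean = unname(x$mean),
               sd = unname(x$sd))
  print(df, ...)
  invisible(x)
}
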