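tie_corrected_auc <- function(x, pos) {
  r <- rank(x)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

fitting_cohort <- function(cohort) {
  require_columns(cohort, "outcome", "cohort table")
  cohort <- filter(as_tibble(cohort), outcome %in% c("responder", "non_responder"))
  tab <- table(cohort$outcome)
  if (length(tab) < 2 || any(tab < 2)) {
    abort_data("fitting needs at least 2 samples in each outcome group")
  }
  cohort
}

#' Screen candidate biomarkers for outcome association
#'
#' Tests each candidate biomarker for enrichment in responders versus
#' non-responders: two-sided Fisher's exact test on the 2x2
#' presence-by-outcome table for categorical biomarkers (a flag is
#' "present" when non-zero), two-sided Mann-Whitney U test for continuous
#' ones. Missing values are dropped pairwise per biomarker. A biomarker is
#' selected iff p < `alpha`; a biomarker constant across all samples is
#' auto-rejected (the test is undefined).
#'
#' Effect sizes (used later for correlation pruning) are the absolute
#' rank-biserial correlation `|2*AUC - 1|` for continuous biomarkers and
#' the absolute Yule's Q (odds-ratio based, Haldane-corrected) for
#' categorical ones; both live on \[0, 1\].
#'
#' @param cohort A tibble with an `outcome` column
#'   (`responder`/`non_responder`; unknowns are ignored) and the candidate
#'   biomarker columns.
#' @param alpha Significance level (default 0.05).
#' @param candidates Candidate table as from [panel_biomarkers()].
#' @return A selection tibble: `biomarker`, `type`, `test_used`,
#'   `p_value`, `effect_size`, `selected`, `rejection_reason`
#'   (`none`/`nonsignificant`/`correlated`), `retained_partner`.
#' @export
select_biomarkers <- function(cohort, alpha = 0.05,
                              candidates = panel_biomarkers()) {
  cohort <- fitting_cohort(cohort)
  candidates <- filter(candidates, biomarker %in% names(cohort))
  if (nrow(candidates) == 0) {
    abort_data("no candidate biomarker columns found in the cohort table")
  }
  rows <- pmap(candidates, function(biomarker, type) {
    x <- cohort[[biomarker]]
    ok <- is.finite(x) & !is.na(cohort$outcome)
    x <- x[ok]
    pos <- cohort$outcome[ok] == "responder"
    if (length(unique(x)) < 2 || sum(pos) < 2 || sum(!pos) < 2) {
      return(tibble(biomarker = biomarker, type = type,
                    test_used = NA_character_, p_value = NA_real_,
                    effect_size = NA_real_, selected = FALSE,
                    rejection_reason = "nonsignificant",
                    retained_partner = NA_character_))
    }
    if (type == "categorical") {
      present <- x != 0
      tab <- table(factor(present, c(FALSE, TRUE)), factor(pos, c(FALSE, TRUE)))
      p <- fisher.test(tab)$p.value
      # Haldane-corrected odds ratio -> Yule's Q in [-1, 1]
      or <- ((tab[2, 2] + 0.5) * (tab[1, 1] + 0.5)) /
        ((tab[2, 1] + 0.5) * (tab[1, 2] + 0.5))
      eff <- abs((or - 1) / (or + 1))
      test <- "fisher"
    } else {
      p <- suppressWarnings(wilcox.test(x[pos], x[!pos])$p.value)
      eff <- abs(2 * tie_corrected_auc(x, pos) - 1)
      test <- "mann_whitney"
    }
    tibble(biomarker = biomarker, type = type, test_used = test,
           p_value = p, effect_size = eff, selected = p < alpha,
           rejection_reason = if_else(p < alpha, "none", "nonsignificant"),
           retained_partner = NA_character_)
  })
  out <- bind_rows(rows)
  attr(out, "alpha") <- alpha
  out
}

#' Prune mutually correlated selected biomarkers
#'
#' Among the selected biomarkers, pairs with absolute Spearman correlation
#' above `rho_max` are resolved by rejecting the member with the smaller
#' effect size (rejection reason `correlated`, naming the retained
#' partner). Violating pairs are resolved iteratively in descending |rho|
#' order until none remain.
#'
#' @param selection Selection tibble from [select_biomarkers()].
#' @param cohort The cohort the selection was computed on.
#' @param rho_max Correlation threshold (default 0.5, strict `>`).
#' @return The updated selection tibble.
#' @export
prune_correlated <- function(selection, cohort, rho_max = 0.5) {
  selection <- as_tibble(selection)
  repeat {
    active <- selection$biomarker[selection$selected]
    if (length(active) < 2) break
    cm <- suppressWarnings(
      cor(as.matrix(cohort[, active]), method = "spearman",
          use = "pairwise.complete.obs")
    )
    cm[!upper.tri(cm)] <- NA
    cm[is.na(cm)] <- NA
    worst <- which(abs(cm) == max(abs(cm), na.rm = TRUE), arr.ind = TRUE)
    if (!length(worst) || max(abs(cm), na.rm = TRUE) <= rho_max) break
    a <- active[worst[1, "row"]]
    b <- active[worst[1, "col"]]
    ea <- selection$effect_size[selection$biomarker == a]
    eb <- selection$effect_size[selection$biomarker == b]
    drop <- if (ea < eb) a else b  # tie keeps the earlier candidate
    keep <- if (drop == a) b else a
    i <- selection$biomarker == drop
    selection$selected[i] <- FALSE
    selection$rejection_reason[i] <- "correlated"
    selection$retained_partner[i] <- keep
  }
  selection
}

#' Biomarker weights from selection p-values
#'
#' Weights are the -log10 selection p-values normalized to sum to one, so
#' each selected biomarker contributes in proportion to the strength of
#' its outcome association. P-values are floored at `p_floor` before the
#' log for numerical safety.
#'
#' @param selection Selection tibble (after pruning).
#' @param p_floor Minimum p-value before taking logs (default 1e-300).
#' @return Named numeric vector of weights (positive, summing to 1).
#' @export
fit_weights <- function(selection, p_floor = 1e-300) {
  sel <- filter(as_tibble(selection), selected)
  if (nrow(sel) == 0) {
    abort_data("no biomarkers selected: cannot determine weights")
  }
  if (any(!is.finite(sel$p_value) | sel$p_value < 0 | sel$p_value >= 1)) {
    abort_data("selected biomarkers must have p-values in (0, 1)")
  }
  raw <- -log10(pmax(sel$p_value, p_floor))
  setNames(raw / sum(raw), sel$biomarker)
}

#' Standardization constants from the discovery cohort
#'
#' @param cohort Cohort tibble.
#' @param selected Character vector of selected biomarker names.
#' @return A tibble `biomarker`, `mean`, `sd` (sample sd, n-1
#'   denominator); a constant biomarker (sd = 0) is a fitting error.
#' @export
fit_standardization <- function(cohort, selected) {
  out <- tibble(
    biomarker = selected,
    mean = map_dbl(selected, ~ mean(cohort[[.x]], na.rm = TRUE)),
    sd = map_dbl(selected, ~ sd(cohort[[.x]], na.rm = TRUE))
  )
  if (any(!is.finite(out$sd) | out$sd <= 0)) {
    bad <- out$biomarker[!is.finite(out$sd) | out$sd <= 0]
    abort_data(sprintf("biomarker(s) constant on the discovery cohort: %s",
                       paste(bad, collapse = ", ")))
  }
  out
}

#' Fit the immunogenicity score on a labeled discovery cohort
#'
#' Runs the full fitting pipeline: statistical screening
#' ([select_biomarkers()]), Spearman correlation pruning
#' ([prune_correlated()]), -log10(p) weight normalization
#' ([fit_weights()]), z-score standardization constants
#' ([fit_standardization()]), then scores the discovery cohort and (by
#' default) fixes the high/low classification cutoff by maximizing
#' Youden's index on the discovery ROC curve.
#'
#' @param cohort A tibble with `outcome` plus the candidate biomarker
#'   columns (and optionally `sample_id`).
#' @param alpha Selection significance level (default 0.05).
#' @param rho_max Correlation pruning threshold (default 0.5).
#' @param candidates Candidate table, see [panel_biomarkers()].
#' @param cutoff `"youden"` (default) or `"none"`.
#' @param seed Optional integer recorded in the model provenance.
#' @return An object of class `motiscore_fit` with elements `model`
#'   (a `motiscore_model`), `selection`, `scores` (discovery scores) and
#'   `roc`.
#' @export
fit_motiscore <- function(cohort, alpha = 0.05, rho_max = 0.5,
                          candidates = panel_biomarkers(),
                          cutoff = c("youden", "none"), seed = NULL) {
  cutoff <- arg_match(cutoff)
  cohort <- fitting_cohort(cohort)
  selection <- select_biomarkers(cohort, alpha = alpha, candidates = candidates)
  selection <- prune_correlated(selection, cohort, rho_max = rho_max)
  w <- fit_weights(selection)
  st <- fit_standardization(cohort, names(w))
  model <- score_model(
    selected = names(w),
    p_value = selection$p_value[match(names(w), selection$biomarker)],
    weight = unname(w),
    mean = st$mean,
    sd = st$sd,
    cutoff = NA_real_,
    provenance = list(
      n = nrow(cohort),
      n_responder = sum(cohort$outcome == "responder"),
      alpha = alpha, rho_max = rho_max,
      seed = seed, date = format(Sys.Date())
    )
  )
  scores <- score_samples(cohort, model, classify = FALSE)
  scores$outcome <- cohort$outcome
  roc <- roc_curve(scores, score, outcome == "responder")
  if (cutoff == "youden") {
    model$cutoff <- youden_cutoff(roc)
  }
  structure(
    list(model = model, selection = selection, scores = scores, roc = roc),
    class = "motiscore_fit"
  )
}

#' Score samples with a fitted model
#'
#' The score of a sample is the weighted sum of the z-scores of the
#' selected biomarkers, `sum_b w_b * (x_b - mean_b) / sd_b`, using the
#' discovery-cohort standardization constants. Every selected biomarker
#' must be present and non-missing; there is no imputation by default --
#' set `impute_mean = TRUE` to fall back to the discovery mean (z = 0) for
#' missing values.
#'
#' @param data Panel tibble (one row per sample) containing the selected
#'   biomarker columns and optionally `sample_id`.
#' @param model A `motiscore_model` or `motiscore_fit`.
#' @param classify Add a `score_class` column using the model cutoff
#'   (default `TRUE` when the cutoff is set).
#' @param impute_mean Impute missing selected biomarkers at the discovery
#'   mean (default `FALSE`).
#' @return A tibble with `sample_id` (if present) and `score` (plus
#'   `score_class`).
#' @export
score_samples <- function(data, model, classify = !is.na(model$cutoff),
                          impute_mean = FALSE) {
  if (inherits(model, "motiscore_fit")) model <- model$model
  validate_score_model(model)
  data <- as_tibble(data)
  missing_cols <- setdiff(model$selected, names(data))
  if (length(missing_cols) > 0) {
    abort_scoring(sprintf("selected biomarker(s) missing from panel: %s",
                          paste(missing_cols, collapse = ", ")))
  }
  z <- map(model$selected, function(b) {
    x <- as.numeric(data[[b]])
    if (any(!is.finite(x))) {
      if (impute_mean) {
        x[!is.finite(x)] <- model$mean[[b]]
      } else {
        abort_scoring(sprintf(
          "biomarker `%s` is missing for %d sample(s); no imputation by default",
          b, sum(!is.finite(x))
        ))
      }
    }
    (x - model$mean[[b]]) / model$sd[[b]]
  })
  score <- Reduce(`+`, map2(z, model$weight[model$selected], ~ .x * .y))
  out <- tibble(score = score)
  if ("sample_id" %in% names(data)) {
    out <- tibble(sample_id = data$sample_id, score = score)
  }
  if (isTRUE(classify)) {
    out$score_class <- classify_scores(score, model)
  }
  out
}

#' Classify scores as high or low against the model cutoff
#'
#' High iff score is strictly greater than the cutoff; ties classify low
#' (conservative toward not recommending therapy).
#'
#' @param scores Numeric vector of scores.
#' @param model A `motiscore_model` (or a single numeric cutoff).
#' @return Factor with levels `low`, `high`.
#' @export
classify_scores <- function(scores, model) {
  cutoff <- if (is.numeric(model) && length(model) == 1) model else model$cutoff
  if (is.null(cutoff) || is.na(cutoff)) {
    abort_scoring("model cutoff is unset; fit with cutoff = \"youden\" or set it")
  }
  factor(if_else(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' @export
print.motiscore_fit <- function(x, ...) {
  cat("Immunogenicity score fit\n")
  cat(sprintf("  discovery n = %s (%s responders), AUC = %.3f\n",
              x$model$provenance$n, x$model$provenance$n_responder,
              attr(x$roc, "auc")))
  print(x$model)
  invisible(x)
}

#' Tidy a fitted score model
#'
#' One row per candidate biomarker with its test, p-value, effect size,
#' selection status and (for selected biomarkers) weight and
#' standardization constants.
#'
#' @param x A `motiscore_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy motiscore_fit
#' @export
tidy.motiscore_fit <- function(x, ...) {
  sel <- as_tibble(x$selection)
  sel$weight <- unname(x$model$weight[sel$biomarker])
  sel$mean <- unname(x$model$mean[sel$biomarker])
  sel$sd <- unname(x$model$sd[sel$biomarker])
  sel
}

#' One-row summary of a fitted score model
#'
#' @param x A `motiscore_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_responder`, `n_selected`, `auc`,
#'   `cutoff`, `alpha`, `rho_max`.
#' @method glance motiscore_fit
#' @export
glance.motiscore_fit <- function(x, ...) {
  tibble(
    n = x$model$provenance$n,
    n_responder = x$model$provenance$n_responder,
    n_selected = length(x$model$selected),
    auc = attr(x$roc, "auc"),
    cutoff = x$model$cutoff,
    alpha = x$model$provenance$alpha,
    rho_max = x$model$provenance$rho_max
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
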