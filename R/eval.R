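#' ROC curve and AUC
#'
#' Operating points are computed at every distinct score threshold with
#' the classification rule "positive iff score > threshold"; the AUC is
#' the tie-corrected concordance probability (tied score pairs contribute
#' 1/2), which equals the trapezoidal area under the curve and the
#' Mann-Whitney U statistic normalized by n1*n0.
#'
#' @param data A data frame, or `NULL` when `score`/`truth` are vectors.
#' @param score Column (tidy-eval) or numeric vector of scores.
#' @param truth Column/expression (tidy-eval) or logical vector; `TRUE`
#'   marks the positive class (responder).
#' @return A tibble of class `motiscore_roc` with columns `threshold`
#'   (descending, ending at `-Inf`), `sensitivity`, `specificity`, and
#'   attributes `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(NULL, c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' @export
roc_curve <- function(data, score, truth) {
  if (is.null(data)) {
    s <- score
    y <- truth
  } else {
    s <- eval_tidy(enquo(score), data)
    y <- eval_tidy(enquo(truth), data)
  }
  y <- as.logical(y)
  ok <- is.finite(s) & !is.na(y)
  s <- s[ok]
  y <- y[ok]
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    abort_data("ROC needs both classes present")
  }
  thr <- sort(unique(s), decreasing = TRUE)
  pos_at <- map_dbl(thr, ~ sum(y & s == .x))
  neg_at <- map_dbl(thr, ~ sum(!y & s == .x))
  # classification rule: positive iff score > t, so the operating point at
  # t = thr[k] counts only scores strictly above thr[k]; -Inf calls all
  # samples positive
  out <- tibble(
    threshold = c(thr, -Inf),
    sensitivity = c(0, cumsum(pos_at) / n1),
    specificity = c(1, 1 - cumsum(neg_at) / n0)
  )
  r <- rank(s)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(out, auc = auc, n_pos = n1, n_neg = n0,
            class = c("motiscore_roc", class(out)))
}

#' Area under a ROC curve
#'
#' @param roc A `motiscore_roc` from [roc_curve()].
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  attr(roc, "auc")
}

#' Youden-index cutoff
#'
#' The threshold maximizing J = sensitivity + specificity - 1 over all
#' operating points of the ROC curve. Among tied maxima the smallest
#' threshold is returned (the more sensitive classifier, favoring not
#' missing responders).
#'
#' @param roc A `motiscore_roc` from [roc_curve()].
#' @return The cutoff; scores strictly above it classify high.
#' @export
youden_cutoff <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  min(roc$threshold[best])
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates via [survival::survfit()]; censored subjects
#' leave the risk set after their time.
#'
#' @param data A data frame, or `NULL` for vector inputs.
#' @param time Column/vector of survival times (days, >= 0).
#' @param event Column/vector; `TRUE`/1 marks an observed event.
#' @param group Column/vector of group labels.
#' @return A tibble of class `motiscore_km` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`; the underlying
#'   `survfit` object is kept in the `fit` attribute.
#' @export
kaplan_meier <- function(data, time, event, group) {
  if (is.null(data)) {
    tt <- time; ee <- event; gg <- group
  } else {
    tt <- eval_tidy(enquo(time), data)
    ee <- eval_tidy(enquo(event), data)
    gg <- eval_tidy(enquo(group), data)
  }
  if (any(tt < 0, na.rm = TRUE)) abort_data("survival times must be >= 0")
  df <- tibble(time = tt, event = as.integer(as.logical(ee)), group = gg)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  s <- summary(fit, censored = TRUE)
  strata <- if (is.null(s$strata)) {
    rep(as.character(unique(df$group))[1], length(s$time))
  } else {
    sub("^group=", "", as.character(s$strata))
  }
  out <- tibble(
    group = strata, time = s$time, n_risk = s$n.risk,
    n_event = s$n.event, n_censor = s$n.censor, survival = s$surv
  )
  structure(out, fit = fit, class = c("motiscore_km", class(out)))
}

#' Univariate Cox proportional-hazards comparison of two groups
#'
#' Maximizes the partial likelihood with Breslow tie handling
#' ([survival::coxph()]). The hazard ratio is exp(beta) for the second
#' factor level versus the first, with a Wald 95% confidence interval and
#' Wald p-value. Each group must contribute at least one event; a
#' monotone likelihood (complete separation of event experience) raises a
#' diagnostic error instead of a silent estimate.
#'
#' @param data A data frame, or `NULL` for vector inputs.
#' @param time,event,group Columns/vectors as in [kaplan_meier()];
#'   `group` is coerced to a two-level factor.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `term`, `estimate` (log hazard ratio), `hr`,
#'   `conf_low`, `conf_high`, `p_value`, `n`, `n_event`.
#' @export
cox_univariate <- function(data, time, event, group, conf_level = 0.95) {
  if (is.null(data)) {
    tt <- time; ee <- event; gg <- group
  } else {
    tt <- eval_tidy(enquo(time), data)
    ee <- eval_tidy(enquo(event), data)
    gg <- eval_tidy(enquo(group), data)
  }
  gg_f <- if (is.factor(gg)) gg else if (setequal(unique(gg), c("low", "high"))) {
    factor(gg, levels = c("low", "high"))  # report high vs low, not alphabetical
  } else {
    factor(gg)
  }
  df <- tibble(time = tt, event = as.integer(as.logical(ee)), group = gg_f)
  if (nlevels(df$group) != 2) {
    abort_data("cox_univariate compares exactly two groups")
  }
  ev <- tapply(df$event, df$group, sum)
  if (any(is.na(ev)) || any(ev < 1)) {
    abort(sprintf(
      "each group needs at least one event (events per group: %s)",
      paste(ev, collapse = ", ")
    ), class = c("motiscore_cox_error", "motiscore_data_error", "motiscore_error"))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = df,
                         ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 1e3) {
    abort("monotone partial likelihood: the hazard ratio is not identifiable",
          class = c("motiscore_cox_error", "motiscore_data_error", "motiscore_error"))
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    term = paste0("group", levels(df$group)[2]),
    estimate = beta,
    hr = exp(beta),
    conf_low = exp(beta - zq * se),
    conf_high = exp(beta + zq * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    n = nrow(df),
    n_event = sum(df$event)
  )
}

#' Response rates stratified by TMB and TCR repertoire
#'
#' Stratifies a cohort into four groups by high/low TMB and high/low TCR
#' entropy and tabulates responders, non-responders and the response rate
#' per stratum. Cutoff defaults: TMB 10 mutations/Mb (the FDA-approved
#' high-TMB threshold); TCR entropy at the cohort median. An empty stratum
#' reports an undefined (`NA`) rate, not 0.
#'
#' @param data A tibble with columns `tmb`, `tcr_entropy`, `outcome`.
#' @param tmb_cutoff High-TMB threshold (strict `>`, default 10).
#' @param tcr_cutoff High-entropy threshold (strict `>`); default is the
#'   cohort median entropy.
#' @return A tibble with one row per stratum: `tcr_level`, `tmb_level`
#'   (factors low/high), `non_responders`, `responders`, `response_rate`
#'   (fraction, `NA` when the stratum is empty).
#' @export
stratified_response_table <- function(data, tmb_cutoff = 10, tcr_cutoff = NULL) {
  require_columns(data, c("tmb", "tcr_entropy", "outcome"), "cohort table")
  data <- filter(as_tibble(data), outcome %in% c("responder", "non_responder"))
  if (is.null(tcr_cutoff)) tcr_cutoff <- median(data$tcr_entropy, na.rm = TRUE)
  lv <- c("low", "high")
  data <- mutate(
    data,
    tcr_level = factor(if_else(tcr_entropy > tcr_cutoff, "high", "low"), lv),
    tmb_level = factor(if_else(tmb > tmb_cutoff, "high", "low"), lv)
  )
  counts <- count(data, tcr_level, tmb_level, outcome, .drop = FALSE)
  wide <- tidyr::pivot_wider(counts, names_from = outcome, values_from = n,
                             values_fill = 0)
  for (col in c("responder", "non_responder")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  out <- transmute_strata(wide)
  attr(out, "tmb_cutoff") <- tmb_cutoff
  attr(out, "tcr_cutoff") <- tcr_cutoff
  out
}

transmute_strata <- function(wide) {
  mutate(
    select(wide, tcr_level, tmb_level,
           non_responders = "non_responder", responders = "responder"),
    response_rate = if_else(
      responders + non_responders > 0,
      responders / (responders + non_responders),
      NA_real_
    )
  )
}

#' Compare AUCs of several score vectors on the same samples
#'
#' @param scores Named list of numeric score vectors, all aligned to
#'   `truth`.
#' @param truth Logical vector; `TRUE` marks the positive class.
#' @return A tibble `model`, `auc`, `n_pos`, `n_neg`, with the individual
#'   ROC curves in the `curves` attribute (for overlay plotting).
#' @export
auc_compare <- function(scores, truth) {
  if (!is.list(scores) || is.null(names(scores)) || any(names(scores) == "")) {
    abort_config("`scores` must be a named list of score vectors")
  }
  curves <- map(scores, ~ roc_curve(NULL, .x, truth))
  out <- tibble(
    model = names(scores),
    auc = unname(map_dbl(curves, roc_auc)),
    n_pos = unname(map_dbl(curves, ~ attr(.x, "n_pos"))),
    n_neg = unname(map_dbl(curves, ~ attr(.x, "n_neg")))
  )
  attr(out, "curves") <- curves
  out
}
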