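test_that("AUC matches brute-force pair concordance on random fixtures", {
  set.seed(301)
  for (i in 1:50) {
    scores <- round(rnorm(20), 1)  # rounding forces ties
    labels <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    roc <- roc_curve(NULL, scores, labels)
    expect_equal(roc_auc(roc), brute_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC endpoints, tie handling, and symmetry behave", {
  perfect <- roc_curve(NULL, c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(roc_auc(perfect), 1)

  ties <- roc_curve(NULL, rep(5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(roc_auc(ties), 0.5)

  set.seed(17)
  s <- rnorm(30)
  y <- runif(30) < 0.4
  y[1:2] <- c(TRUE, FALSE)
  expect_equal(roc_auc(roc_curve(NULL, s, y)) +
                 roc_auc(roc_curve(NULL, -s, y)), 1, tolerance = 1e-12)

  # curve is monotone: sensitivity non-increasing as the threshold rises
  roc <- roc_curve(NULL, s, y)
  expect_true(all(diff(roc$sensitivity) >= 0))  # rows are descending thresholds
  expect_true(all(diff(roc$specificity) <= 0))

  expect_error(roc_curve(NULL, s, rep(TRUE, 30)), class = "motiscore_data_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(41)
  for (i in 1:10) {
    s <- round(rnorm(40), 1)
    y <- runif(40) < 0.5
    y[1:2] <- c(TRUE, FALSE)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, direction = "<",
      levels = c(FALSE, TRUE), quiet = TRUE
    )))
    expect_equal(roc_auc(roc_curve(NULL, s, y)), ref, tolerance = 1e-12)
  }
})

test_that("Youden cutoff equals the exhaustive threshold scan", {
  # perfect separation across the (0.4, 0.6) gap
  s <- c(0.1, 0.4, 0.6, 0.9)
  y <- c(FALSE, FALSE, TRUE, TRUE)
  roc <- roc_curve(NULL, s, y)
  expect_equal(youden_cutoff(roc), brute_youden(s, y))
  expect_equal(youden_cutoff(roc), 0.4)  # smallest maximizing threshold

  # anti-informative scores: max J = 0 at an extreme threshold
  s2 <- c(3, 4, 1, 2)
  y2 <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(youden_cutoff(roc_curve(NULL, s2, y2)), brute_youden(s2, y2))

  set.seed(59)
  for (i in 1:20) {
    s3 <- round(rnorm(10), 1)
    y3 <- runif(10) < 0.5
    y3[1:2] <- c(TRUE, FALSE)
    expect_equal(youden_cutoff(roc_curve(NULL, s3, y3)), brute_youden(s3, y3))
  }
})

test_that("Kaplan-Meier matches closed forms and hand-computed tables", {
  none <- kaplan_meier(NULL, c(5, 10, 15), c(FALSE, FALSE, FALSE), rep("g", 3))
  expect_true(all(none$survival == 1))

  three <- kaplan_meier(NULL, c(1, 2, 3), c(TRUE, TRUE, TRUE), rep("g", 3))
  expect_equal(three$survival, c(2 / 3, 1 / 3, 0))

  # mixed censoring, hand-computed product-limit:
  # n=6; death@1 -> 5/6; censor@2; death@3 (risk 4) -> 5/8; death@4 (risk 3)
  # -> 5/12; censor@5; death@6 (risk 1) -> 0
  mixed <- kaplan_meier(NULL, 1:6, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                        rep("g", 6))
  deaths <- filter(mixed, n_event > 0)
  expect_equal(deaths$survival, c(5 / 6, 5 / 8, 5 / 12, 0), tolerance = 1e-12)

  # with no censoring KM equals the empirical survival function
  set.seed(8)
  t <- sample(1:50, 20)
  km <- kaplan_meier(NULL, t, rep(TRUE, 20), rep("g", 20))
  expect_equal(km$survival, sapply(sort(t), function(u) mean(t > u)))
})

test_that("Cox HR matches the Breslow partial-likelihood grid oracle", {
  set.seed(91)
  n <- 30
  x <- rep(c(0, 1), each = n / 2)
  t <- round(rexp(n, rate = ifelse(x == 1, 0.5, 1)), 1) + 0.1  # ties via rounding
  e <- runif(n) < 0.8
  if (sum(e[x == 0]) == 0) e[1] <- TRUE
  if (sum(e[x == 1]) == 0) e[n] <- TRUE
  cx <- cox_univariate(NULL, t, e, factor(ifelse(x == 1, "B", "A")))
  expect_equal(cx$estimate, grid_cox_beta(t, e, x), tolerance = 1e-3)

  # reversing the reference level inverts the hazard ratio
  cx_flip <- cox_univariate(NULL, t, e, factor(ifelse(x == 1, "B", "A"),
                                               levels = c("B", "A")))
  expect_equal(cx_flip$estimate, -cx$estimate, tolerance = 1e-9)
  expect_equal(cx_flip$hr, 1 / cx$hr, tolerance = 1e-9)

  # identical event patterns in both groups give HR ~ 1
  t2 <- rep(c(1, 2, 3, 4, 5), 2)
  e2 <- rep(TRUE, 10)
  g2 <- rep(c("A", "B"), each = 5)
  cx2 <- cox_univariate(NULL, t2, e2, g2)
  expect_equal(cx2$hr, 1, tolerance = 1e-6)

  expect_error(
    cox_univariate(NULL, t2, c(rep(TRUE, 5), rep(FALSE, 5)), g2),
    class = "motiscore_cox_error"
  )
})

test_that("Cox beta is centered at zero under label permutation", {
  set.seed(100)
  t <- rexp(60, 0.01)
  e <- runif(60) < 0.8
  betas <- replicate(200, {
    g <- sample(rep(c("low", "high"), each = 30))
    cox_univariate(NULL, t, e, g)$estimate
  })
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(200))
})

test_that("stratified response table reproduces printed counts and handles edges", {
  cohort <- strata_cohort(list(c(55, 19), c(35, 25), c(18, 20), c(17, 36)))
  tab <- stratified_response_table(cohort, tmb_cutoff = 10, tcr_cutoff = 1)
  tab <- arrange(tab, tcr_level, tmb_level)
  expect_equal(tab$non_responders, c(55, 18, 35, 17))
  expect_equal(tab$responders, c(19, 20, 25, 36))
  expect_equal(round(100 * tab$response_rate, 1), c(25.7, 52.6, 41.7, 67.9))

  all_resp <- tibble(tmb = c(5, 15), tcr_entropy = c(0.5, 1.5),
                     outcome = "responder")
  t2 <- stratified_response_table(all_resp, tmb_cutoff = 10, tcr_cutoff = 1)
  expect_true(all(t2$response_rate[!is.na(t2$response_rate)] == 1))

  # cutoffs beyond the data range: one occupied stratum, three undefined
  t3 <- stratified_response_table(all_resp, tmb_cutoff = 100, tcr_cutoff = 100)
  expect_equal(sum(is.na(t3$response_rate)), 3)
  expect_equal(sum(!is.na(t3$response_rate)), 1)
})

test_that("AUC comparison is consistent under duplication and negation", {
  set.seed(71)
  s <- rnorm(40)
  y <- runif(40) < 0.5
  y[1:2] <- c(TRUE, FALSE)
  cmp <- auc_compare(list(one = s, two = s, neg = -s), y)
  expect_equal(cmp$auc[1], cmp$auc[2])
  expect_equal(cmp$auc[1] + cmp$auc[3], 1, tolerance = 1e-12)
})

test_that("the combined score beats TMB alone when several biomarkers carry signal", {
  spec <- null_biomarker_spec() %>%
    mutate(shift = case_when(biomarker == "tmb" ~ 0.6,
                             biomarker == "tcr_entropy" ~ 0.7,
                             biomarker == "pdl1_cpm" ~ 0.45,
                             TRUE ~ shift))
  wins <- 0
  nrep <- 200
  for (r in seq_len(nrep)) {
    cfg <- sim_config(n_samples = 100, responder_fraction = 0.5,
                      biomarkers = spec, correlations = NULL, seed = 7000 + r)
    coh <- simulate_panels(cfg)
    fit <- try(fit_motiscore(coh, cutoff = "none"), silent = TRUE)
    if (inherits(fit, "try-error")) next
    y <- coh$outcome == "responder"
    auc_model <- roc_auc(roc_curve(NULL, fit$scores$score, y))
    auc_tmb <- roc_auc(roc_curve(NULL, coh$tmb, y))
    wins <- wins + (auc_model >= auc_tmb)
  }
  expect_gte(wins / nrep, 0.95)
})
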