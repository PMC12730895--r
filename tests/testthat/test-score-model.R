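test_that("selection picks planted effects and rejects constants", {
  set.seed(21)
  n <- 50
  cohort <- tibble(
    outcome = rep(c("responder", "non_responder"), each = n),
    shifted = c(rnorm(n, 2), rnorm(n, 0)),       # +2 pooled-SD shift
    noise = rnorm(2 * n),
    flat = rep(1, 2 * n),
    flag = c(rbinom(n, 1, 0.4), rbinom(n, 1, 0.04))
  )
  cand <- tibble(biomarker = c("shifted", "noise", "flat", "flag"),
                 type = c("continuous", "continuous", "continuous", "categorical"))
  sel <- select_biomarkers(cohort, candidates = cand)
  expect_true(sel$selected[sel$biomarker == "shifted"])
  expect_false(sel$selected[sel$biomarker == "flat"])
  expect_equal(sel$rejection_reason[sel$biomarker == "flat"], "nonsignificant")
  expect_true(is.na(sel$p_value[sel$biomarker == "flat"]))
})

test_that("Fisher branch matches the two-sided hypergeometric sum", {
  cohort <- tibble(
    outcome = rep(c("responder", "non_responder"), each = 50),
    flag = c(rep(1, 20), rep(0, 30), rep(1, 2), rep(0, 48))
  )
  sel <- select_biomarkers(cohort, candidates = tibble(biomarker = "flag",
                                                       type = "categorical"))
  # oracle: sum of hypergeometric probabilities <= that of the observed table
  probs <- dhyper(0:22, 50, 50, 22)
  p_oracle <- sum(probs[probs <= dhyper(20, 50, 50, 22) * (1 + 1e-7)])
  expect_equal(sel$p_value, p_oracle, tolerance = 1e-9)
  expect_true(sel$selected)
  expect_lt(sel$p_value, 1e-4)
})

test_that("correlation pruning drops the weaker member of correlated pairs", {
  set.seed(22)
  n <- 60
  base <- c(rnorm(n, 1.2), rnorm(n, 0))
  cohort <- tibble(
    outcome = rep(c("responder", "non_responder"), each = n),
    strong = base,
    clone = base + rnorm(2 * n, sd = 0.05),  # rho ~ 1, weaker effect by noise
    independent = c(rnorm(n, 0.8), rnorm(n, 0))
  )
  cand <- tibble(biomarker = c("strong", "clone", "independent"),
                 type = "continuous")
  sel <- select_biomarkers(cohort, candidates = cand)
  pruned <- prune_correlated(sel, cohort)
  expect_true(pruned$selected[pruned$biomarker == "strong"] ||
                pruned$selected[pruned$biomarker == "clone"])
  expect_false(all(pruned$selected[pruned$biomarker %in% c("strong", "clone")]))
  dropped <- filter(pruned, rejection_reason == "correlated")
  expect_equal(nrow(dropped), 1)
  expect_true(dropped$retained_partner %in% c("strong", "clone"))
  # the retained member has the larger effect size
  kept <- filter(pruned, biomarker %in% c("strong", "clone"), selected)
  expect_gte(kept$effect_size, dropped$effect_size)
  expect_true(pruned$selected[pruned$biomarker == "independent"])

  # below-threshold correlation leaves both retained
  cohort2 <- tibble(
    outcome = rep(c("responder", "non_responder"), each = n),
    a = base, b = 0.25 * scale(base)[, 1] + rnorm(2 * n, sd = 1) +
      rep(c(0.8, 0), each = n)
  )
  sel2 <- select_biomarkers(cohort2, candidates = tibble(
    biomarker = c("a", "b"), type = "continuous"
  ))
  rho <- cor(cohort2$a, cohort2$b, method = "spearman")
  expect_lt(abs(rho), 0.5)
  pruned2 <- prune_correlated(sel2, cohort2)
  expect_equal(sum(pruned2$rejection_reason == "correlated"), 0)
})

test_that("weights are normalized -log10 p-values", {
  sel <- tibble(biomarker = c("a", "b"), selected = TRUE,
                p_value = c(1e-4, 1e-2))
  expect_equal(unname(fit_weights(sel)), c(2 / 3, 1 / 3), tolerance = 1e-12)

  one <- tibble(biomarker = "a", selected = TRUE, p_value = 0.03)
  expect_equal(unname(fit_weights(one)), 1)

  equal <- tibble(biomarker = letters[1:4], selected = TRUE, p_value = 0.01)
  expect_equal(unname(fit_weights(equal)), rep(0.25, 4))

  floored <- tibble(biomarker = c("a", "b"), selected = TRUE,
                    p_value = c(0, 1e-2))
  w <- fit_weights(floored)
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))
})

test_that("standardization uses the discovery mean and n-1 sd", {
  cohort <- tibble(x = c(1, 2, 3))
  st <- fit_standardization(cohort, "x")
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)

  # binary flag -1/0 at 10% prevalence
  n <- 200
  flag <- c(rep(-1, 20), rep(0, 180))
  stf <- fit_standardization(tibble(f = flag), "f")
  expect_equal(stf$mean, -0.1)
  expect_equal(stf$sd, sqrt(0.09 * n / (n - 1)), tolerance = 1e-12)

  expect_error(fit_standardization(tibble(x = rep(5, 10)), "x"),
               class = "motiscore_data_error")
})

test_that("scoring is the weighted z-score sum, with strict missing handling", {
  m <- score_model(
    selected = c("a", "b", "c", "d"),
    p_value = c(1e-4, 1e-3, 1e-2, 0.04),
    weight = local({ r <- -log10(c(1e-4, 1e-3, 1e-2, 0.04)); r / sum(r) }),
    mean = c(10, 0, -0.1, 100), sd = c(4, 1.5, 0.3, 50)
  )
  at_mean <- tibble(a = 10, b = 0, c = -0.1, d = 100)
  expect_equal(score_samples(at_mean, m)$score, 0)

  one_up <- mutate(at_mean, b = 1.5)  # +1 sd on b
  expect_equal(score_samples(one_up, m)$score, unname(m$weight["b"]),
               tolerance = 1e-12)

  hand <- tibble(a = 14, b = -3, c = 0.2, d = 25)
  manual <- sum(m$weight * c((14 - 10) / 4, (-3 - 0) / 1.5,
                             (0.2 + 0.1) / 0.3, (25 - 100) / 50))
  expect_equal(score_samples(hand, m)$score, manual, tolerance = 1e-12)

  expect_error(score_samples(select(at_mean, -b), m),
               class = "motiscore_scoring_error")
  err <- expect_error(score_samples(mutate(at_mean, b = NA), m),
                      class = "motiscore_scoring_error")
  expect_match(conditionMessage(err), "`b`")
  imputed <- score_samples(mutate(at_mean, b = NA), m, impute_mean = TRUE)
  expect_equal(imputed$score, 0)
})

test_that("classification is strict with ties going low", {
  m <- score_model("a", p_value = 0.01, weight = 1, mean = 0, sd = 1,
                   cutoff = 0.540)
  expect_equal(as.character(classify_scores(c(0.541, 0.540, -1), m)),
               c("high", "low", "low"))
  unset <- score_model("a", p_value = 0.01, weight = 1, mean = 0, sd = 1)
  expect_error(classify_scores(0.5, unset), class = "motiscore_scoring_error")
})

test_that("full fit yields positive weights summing to one and tidy/glance views", {
  cohort <- simulate_panels(sim_config(seed = 42))
  fit <- fit_motiscore(cohort, seed = 42)
  w <- fit$model$weight
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  g <- glance(fit)
  expect_equal(g$n, 225)
  expect_equal(g$n_selected, length(fit$model$selected))
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_equal(sum(!is.na(td$weight)), g$n_selected)
  expect_false(is.na(fit$model$cutoff))
  # scoring the discovery cohort at its own means gives the stored scores
  rescored <- score_samples(cohort, fit$model, classify = FALSE)
  expect_equal(rescored$score, fit$scores$score)
})

test_that("scores are invariant to affine rescaling of a raw biomarker", {
  cohort <- simulate_panels(sim_config(seed = 77))
  fit1 <- fit_motiscore(cohort, cutoff = "none")
  rescaled <- mutate(cohort, tmb = tmb * 1000, pdl1_cpm = pdl1_cpm / 50)
  fit2 <- fit_motiscore(rescaled, cutoff = "none")
  expect_equal(fit2$model$selected, fit1$model$selected)
  expect_equal(fit2$model$weight, fit1$model$weight, tolerance = 1e-9)
  expect_equal(fit2$scores$score, fit1$scores$score, tolerance = 1e-9)
})

test_that("weights are equivariant under biomarker column permutation", {
  cohort <- simulate_panels(sim_config(seed = 55))
  fit1 <- fit_motiscore(cohort, cutoff = "none")
  perm <- panel_biomarkers()[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  fit2 <- fit_motiscore(cohort, cutoff = "none", candidates = perm)
  expect_setequal(fit2$model$selected, fit1$model$selected)
  expect_equal(fit2$model$weight[fit1$model$selected], fit1$model$weight,
               tolerance = 1e-12)
})
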