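test_that("primary effect is the paired contrast with t-based inference", {
  # two participants with condition-mean differences 3 and 1
  tab <- make_score_table(
    list(pattern_a, pattern_b),
    list(flat_scores(pattern_a, 7, 4), flat_scores(pattern_b, 6, 5)))
  est <- primary_effect(tab)
  expect_equal(est$beta_hat, 2)
  expect_equal(est$se, 1)          # sd({3,1})/sqrt(2) = sqrt(2)/sqrt(2)
  expect_equal(est$df, 1)
  expect_equal(est$n_participants, 2)

  # reference paired t-test on the participant condition means
  cm <- condition_means(tab)$per_participant
  tt <- t.test(cm$mean_tool, cm$mean_control, paired = TRUE)
  expect_equal(est$beta_hat, unname(tt$estimate))
  expect_equal(est$p_value, tt$p.value)
  expect_equal(c(est$ci_low, est$ci_high), as.numeric(tt$conf.int))
})

test_that("primary effect is location invariant and flags degenerate data", {
  tr <- generate_trial(simulation_config(n_participants = 15, seed = 31))
  est <- primary_effect(tr$scores)
  shifted <- tr$scores
  shifted$score <- shifted$score + 11.5
  est2 <- primary_effect(shifted)
  expect_equal(est2$beta_hat, est$beta_hat)
  expect_equal(est2$se, est$se)
  expect_equal(est2$p_value, est$p_value)

  # tool scores identical to control scores per participant: no variance
  degen <- make_score_table(
    list(pattern_a, pattern_b),
    list(flat_scores(pattern_a, 5, 5), flat_scores(pattern_b, 3, 3)))
  expect_error(primary_effect(degen), "zero variance")
  one <- make_score_table(list(pattern_a), list(flat_scores(pattern_a, 7, 5)))
  expect_error(primary_effect(one), "at least 2 participants")
})

test_that("paired contrast equals the REML mixed-model fit on balanced data", {
  skip_if_not_installed("lme4")
  set.seed(88)
  for (i in 1:20) {
    tr <- generate_trial(simulation_config(
      n_participants = sample(8:20, 1), beta = runif(1, -2, 3)))
    est <- primary_effect(tr$scores)
    fit <- lme4::lmer(
      score ~ condition + (1 | participant_id) +
        (1 | participant_id:condition),
      data = tr$scores, REML = TRUE,
      control = lme4::lmerControl(optimizer = "bobyqa",
                                  optCtrl = list(rhobeg = 0.2, rhoend = 2e-9),
                                  check.conv.singular = "ignore"))
    # the closed-form/GLS identity holds for interior REML fits; a boundary
    # (singular) fit re-estimates sigma2_c from the between-participant
    # stratum too and is not comparable
    if (lme4::isSingular(fit)) next
    beta_ref <- unname(lme4::fixef(fit)["conditiontool"])
    se_ref <- sqrt(as.numeric(vcov(fit)["conditiontool", "conditiontool"]))
    expect_equal(est$beta_hat, beta_ref, tolerance = 1e-6)
    expect_equal(est$se, se_ref, tolerance = 1e-6)
  }
})

test_that("variance components recover the generating values and degenerate cases", {
  tr <- generate_trial(simulation_config(n_participants = 2000, seed = 99))
  vc <- fit_variance_components(tr$scores)
  # generating components forced by sigma=4, rho=0.8, rho'=0.4
  expect_lt(abs(vc$sigma2_b - 6.4) / 6.4, 0.10)
  expect_lt(abs(vc$sigma2_c - 6.4) / 6.4, 0.10)
  expect_lt(abs(vc$sigma2_e - 3.2) / 3.2, 0.10)
  expect_false(vc$truncated)
  expect_true(vc$rho_prime <= vc$rho && vc$rho <= 1)

  # zero within-participant variation: sigma2_c = sigma2_e = 0
  flat <- make_score_table(
    list(pattern_a, pattern_b, pattern_a),
    list(flat_scores(pattern_a, 4, 4), flat_scores(pattern_b, 7, 7),
         flat_scores(pattern_a, 5, 5)))
  vc0 <- fit_variance_components(flat)
  expect_equal(vc0$sigma2_c, 0)
  expect_equal(vc0$sigma2_e, 0)
  expect_gt(vc0$sigma2_b, 0)

  # negative moment solutions are truncated and flagged: equal cell means
  # per participant (no interaction) but residual spread within cells
  spread <- make_score_table(
    list(pattern_a, pattern_b, pattern_a),
    list(flat_scores(pattern_a, 0, 0), flat_scores(pattern_b, 0, 0),
         flat_scores(pattern_a, 0, 0)))
  spread$score <- rep(c(4, 5, 6, 4, 5, 6), 3)  # cell means all equal
  vct <- fit_variance_components(as_score_table(spread))
  expect_true(vct$truncated)
  expect_equal(vct$sigma2_c, 0)
})

test_that("per-domain comparisons are classical two-sample Student t-tests", {
  # blinding: tool {8, 6} vs control {4, 2}
  tab <- make_score_table(
    list(pattern_a, pattern_a, pattern_b, pattern_b),
    list(flat_scores(pattern_a, 8, 1), flat_scores(pattern_a, 6, 2),
         flat_scores(pattern_b, 1, 4), flat_scores(pattern_b, 2, 2)))
  res <- per_domain_ttest(tab, "blinding")
  expect_equal(res$mean_difference, 4)
  expect_equal(res$mean_tool, 7)
  expect_equal(res$mean_control, 3)

  # hand-computed equal-variance t as the oracle
  tool <- c(8, 6); ctrl <- c(4, 2)
  sp2 <- (var(tool) + var(ctrl)) / 2
  tstat <- (mean(tool) - mean(ctrl)) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 2))

  # identical groups: difference 0, p = 1
  same <- make_score_table(
    list(pattern_a, pattern_a, pattern_b, pattern_b),
    list(flat_scores(pattern_a, 8, 5), flat_scores(pattern_a, 6, 5),
         flat_scores(pattern_b, 5, 8), flat_scores(pattern_b, 5, 6)))
  null_res <- per_domain_ttest(same, "trial_design")
  expect_equal(null_res$mean_difference, 0)
  expect_equal(null_res$p_value, 1)

  # swapping condition labels negates the difference, preserves p
  swapped <- tab
  swapped$condition <- ifelse(tab$condition == "tool", "control", "tool")
  res_sw <- per_domain_ttest(as_score_table(swapped), "blinding")
  expect_equal(res_sw$mean_difference, -res$mean_difference)
  expect_equal(res_sw$p_value, res$p_value)

  expect_error(per_domain_ttest(make_score_table(
    list(pattern_a, pattern_b),
    list(flat_scores(pattern_a, 8, 1), flat_scores(pattern_b, 1, 4))),
    "blinding"), "at least 2 observations")
  expect_equal(nrow(all_domain_ttests(tab)), 6)
})

test_that("no multiplicity adjustment is applied to per-domain tests", {
  tr <- generate_trial(simulation_config(n_participants = 20, seed = 6))
  res <- all_domain_ttests(tr$scores)
  raw <- vapply(trial_domains(), function(d) {
    sub <- tr$scores[tr$scores$domain == d, ]
    t.test(sub$score[sub$condition == "tool"],
           sub$score[sub$condition == "control"], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_equal(res$p_value, unname(raw))  # raw, unadjusted p-values
})

test_that("ancillary comparison pairs participants with publications by protocol", {
  tab <- make_score_table(
    list(pattern_a, pattern_b),
    list(flat_scores(pattern_a, 7, 4), flat_scores(pattern_b, 6, 5)))
  # published identical to participant scores: mean difference 0
  pub_same <- data.frame(protocol_id = tab$protocol_id, domain = tab$domain,
                         score = tab$score)
  res0 <- ancillary_comparison(tab, pub_same, "tool")
  expect_equal(res0$mean_paired_difference, 0)

  # protocol-mean differences {1, 3} -> mean 2
  pub <- pub_same
  pub$score <- tab$score - ifelse(tab$protocol_id == "P01", 1, 3)
  res <- ancillary_comparison(tab, pub, "tool")
  expect_equal(res$mean_paired_difference, 2)
  expect_equal(res$n_protocols, 2)
  expect_equal(res$df, 1)
  expect_equal(res$n_pairs, 6)

  # single protocol: no between-protocol variance, SE undefined
  one <- make_score_table(list(pattern_a), list(flat_scores(pattern_a, 7, 4)))
  expect_error(ancillary_comparison(one, pub_same, "tool"),
               "at least 2 protocols")
  # missing published pair is named
  expect_error(
    ancillary_comparison(tab, pub[pub$domain != "trial_design", ], "tool"),
    "trial_design")
})
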