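test_that("ICC parametrization maps to variance components and back", {
  vc <- variance_components_from_icc(4, 0.8, 0.4)
  expect_equal(vc$sigma2_b, 6.4)
  expect_equal(vc$sigma2_c, 6.4)
  expect_equal(vc$sigma2_e, 3.2)
  expect_equal(vc$sigma2_total, 16)
  # boundaries
  expect_equal(variance_components_from_icc(4, 0.5, 0.5)$sigma2_c, 0)
  expect_equal(variance_components_from_icc(4, 1, 0.3)$sigma2_e, 0)
  expect_error(variance_components_from_icc(4, 0.4, 0.8), "rho_prime")
  expect_error(variance_components_from_icc(0, 0.8, 0.4))
})

test_that("generated trials reproduce the configured moments at scale", {
  cfg <- simulation_config(n_participants = 2000, mu_control = 5.0,
                           beta = 2.1, sigma_total = 4, rho = 0.8,
                           rho_prime = 0.4, seed = 2718)
  tr <- generate_trial(cfg)
  expect_s3_class(tr$scores, "score_table")
  expect_equal(nrow(tr$scores), 12000)

  cm <- condition_means(tr$scores)
  diff <- cm$overall[["tool"]] - cm$overall[["control"]]
  expect_lt(abs(diff - 2.1), 0.15)   # SE of the difference ~ 0.086

  vc <- fit_variance_components(tr$scores)
  expect_lt(abs(vc$rho - 0.8), 0.03)
  expect_lt(abs(vc$rho_prime - 0.4), 0.05)
  expect_lt(abs(vc$sigma2_total - 16) / 16, 0.10)
})

test_that("generation is seed-reproducible and honors degenerate sigma", {
  cfg <- simulation_config(n_participants = 12, seed = 55)
  expect_identical(generate_trial(cfg)$scores$score,
                   generate_trial(cfg)$scores$score)
  cfg2 <- simulation_config(n_participants = 12, seed = 56)
  expect_false(identical(generate_trial(cfg)$scores$score,
                         generate_trial(cfg2)$scores$score))

  det <- generate_trial(simulation_config(n_participants = 6, beta = 2.1,
                                          sigma_total = 0, seed = 1))
  cm <- condition_means(det$scores)
  expect_equal(cm$overall[["tool"]] - cm$overall[["control"]], 2.1)
  expect_true(all(det$scores$score %in% c(5.0, 7.1)))
})

test_that("domain offsets and clipping behave as configured", {
  de <- c(trial_design = 3, randomization = -3, blinding = 1,
          participants = -1, interventions = 2, outcomes = -2)
  cfg <- simulation_config(n_participants = 400, domain_effects = de,
                           sigma_total = 0.5, seed = 10)
  tr <- generate_trial(cfg)
  per_dom <- tapply(tr$scores$score, tr$scores$domain, mean)
  # domain contrasts survive averaging over conditions (beta adds ~ beta/2)
  expect_lt(abs((per_dom[["trial_design"]] - per_dom[["randomization"]]) - 6),
            0.3)
  expect_error(simulation_config(domain_effects = de[1:5]), "length 6")
  expect_error(simulation_config(domain_effects = de + 1), "sum to 0")

  clipped <- generate_trial(simulation_config(n_participants = 200,
                                              clip_mode = "truncate",
                                              seed = 3))
  expect_true(all(clipped$scores$score >= 0 & clipped$scores$score <= 10))
})

test_that("greedy keyword realization hits the target within rubric resolution", {
  rub <- domain_rubric("P1", "outcomes",
                       make_keywords(4, weights = c(4, 3, 2, 1)))
  sel <- realize_keywords(rub, 5)
  expect_identical(sel$present, c(TRUE, FALSE, FALSE, TRUE))  # weights 4 + 1
  expect_equal(attr(sel, "realized"), 5)
  expect_equal(attr(realize_keywords(rub, 10), "realized"), 10)
  expect_true(all(realize_keywords(rub, 10)$present))
  expect_equal(attr(realize_keywords(rub, 0), "realized"), 0)
  expect_false(any(realize_keywords(rub, 0)$present))
  expect_error(realize_keywords(rub, 10.5), "\\[0, 10\\]")
  expect_error(realize_keywords(rub, -1), "\\[0, 10\\]")

  # property: never overshoots; undershoot bounded by 10*w_max/sum(w)
  set.seed(977)
  for (i in 1:1000) {
    r <- random_rubric()
    target <- runif(1, 0, 10)
    realized <- attr(realize_keywords(r, target), "realized")
    expect_lte(realized, target + 1e-9)
    expect_lte(target - realized, 10 * max(r$weight) / sum(r$weight) + 1e-9)
  }
})

test_that("keyword-level realization feeds the scoring pipeline consistently", {
  rub <- make_protocol_rubric("SHARED", k = 6, weights = c(5, 4, 3, 2, 1, 1))
  tr <- generate_trial(simulation_config(n_participants = 4,
                                         clip_mode = "truncate", seed = 21),
                       rubrics = rub)
  expect_false(is.null(tr$ratings))
  # rescoring the realized keywords reproduces each score within the
  # rubric's resolution 10*w_max/sum(w)
  resol <- 10 * 5 / 16
  for (i in seq_len(nrow(tr$scores))) {
    d <- tr$scores$domain[i]
    sub <- tr$ratings[tr$ratings$protocol_id == tr$scores$protocol_id[i] &
                        tr$ratings$domain == d, ]
    s <- domain_score(rekey_rubric_for_test(rub, tr$scores$protocol_id[i])[[d]],
                      sub)
    expect_lte(abs(s - tr$scores$score[i]), resol + 1e-9)
  }
})

test_that("analytic power matches independent normal-CDF computations", {
  p <- design_params()
  # frozen from scipy.stats.norm: Phi(2/(4*sqrt(2*1.4/120)) - 1.95996...)
  expect_equal(analytic_power(p, 120), 0.9054597965354771, tolerance = 1e-12)
  # at the unrounded requirement the power is the nominal 90% by construction
  ss <- required_sample_size(p)
  expect_equal(analytic_power(p, ss$n_inflated), 0.90, tolerance = 1e-3)
  # vanishing effect: one-sided rejection at alpha/2
  tiny <- design_params(delta = 1e-9)
  expect_equal(analytic_power(tiny, 120), 0.025, tolerance = 1e-4)
})

test_that("power simulation respects boundaries, determinism and rep floor", {
  cfg <- simulation_config(n_participants = 8, n_replicates = 120, seed = 5)
  always <- simulate_power(cfg, alpha = 1)
  expect_equal(always$rejection_proportion, 1)
  expect_identical(simulate_power(cfg)$rejection_proportion,
                   simulate_power(cfg)$rejection_proportion)
  expect_error(simulate_power(simulation_config(n_replicates = 10)),
               ">= 100")
})

test_that("null p-values of the primary analysis are uniform", {
  cfg <- simulation_config(n_participants = 10, mu_control = 4, beta = 0,
                           n_replicates = 1, seed = NULL)
  set.seed(4242)
  pvals <- vapply(1:1500, function(i) {
    primary_effect(generate_trial(cfg)$scores)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("weight sensitivity schemes rescore and summarize beta_hat", {
  rub <- make_protocol_rubric("SHARED", k = 4, weights = c(4, 3, 2, 1))
  tr <- generate_trial(simulation_config(n_participants = 6,
                                         clip_mode = "truncate", seed = 14),
                       rubrics = rub)
  cons <- transform(tr$ratings, resolved = FALSE)
  alloc <- tr$allocation
  alloc$participant_id <- sprintf("S%03d", alloc$participant_index)

  # identity scheme: every replicate reproduces the original estimate
  ws0 <- weight_sensitivity(cons, rub, alloc, scheme = "identity",
                            n_replicates = 20, seed = 8)
  expect_true(all(ws0$beta_replicates == ws0$beta_hat))
  expect_equal(unname(ws0$quantiles[["50%"]]), ws0$beta_hat)

  # redrawn weights move the estimate but the summary is seed-stable
  ws1 <- weight_sensitivity(cons, rub, alloc, scheme = "uniform_integer",
                            n_replicates = 50, seed = 9)
  ws2 <- weight_sensitivity(cons, rub, alloc, scheme = "uniform_integer",
                            n_replicates = 50, seed = 9)
  expect_identical(ws1$beta_replicates, ws2$beta_replicates)
  expect_lte(ws1$min, ws1$quantiles[[1]])
  expect_gte(ws1$max, ws1$quantiles[[5]])

  ws3 <- weight_sensitivity(cons, rub, alloc, scheme = "dirichlet",
                            n_replicates = 30, seed = 10)
  expect_length(ws3$beta_replicates, 30)
  expect_error(weight_sensitivity(cons, rub, alloc, scheme = "nope"))

  # one keyword per domain: the score is weight-scale invariant, so every
  # scheme reproduces the original estimate exactly
  rub1 <- make_protocol_rubric("SHARED", k = 1)
  tr1 <- generate_trial(simulation_config(n_participants = 5,
                                          clip_mode = "truncate", seed = 15),
                        rubrics = rub1)
  cons1 <- transform(tr1$ratings, resolved = FALSE)
  alloc1 <- tr1$allocation
  alloc1$participant_id <- sprintf("S%03d", alloc1$participant_index)
  ws_one <- weight_sensitivity(cons1, rub1, alloc1,
                               scheme = "uniform_integer",
                               n_replicates = 25, seed = 11)
  expect_true(all(abs(ws_one$beta_replicates - ws_one$beta_hat) < 1e-12))
})
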