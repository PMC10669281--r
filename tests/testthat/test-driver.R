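# Stage execution, refinement, confirmation and the full two-stage driver.

stage1_config <- function(ex, seed = 1) {
  stage_config(ex$factors, array = "L18", assignment = stage1_assignment(),
               seed = seed)
}

test_that("replaying the screening stage reproduces the full analysis", {
  ex <- cvd_example_stage1()
  st <- run_stage(stage1_config(ex), lookup_objective(ex$plan, ex$results))
  expect_equal(attr(st$summary, "grand_mean"), 0.5999, tolerance = 1e-3)
  expect_setequal(st$retained_mean, c("activation", "optimizer"))
  expect_setequal(st$significant_mean, c("activation", "optimizer"))
  expect_equal(st$best$learning_rate, 0.3)
  expect_equal(st$pred_mean$predicted, 0.7166, tolerance = 1e-3)
  expect_equal(st$pred_sn$predicted, -2.919, tolerance = 0.005 / 2.919)
  expect_equal(st$ci_mean$halfwidth, 0.0933, tolerance = 1e-3)
  expect_equal(st$ci_sn$halfwidth, 1.3481, tolerance = 0.005)
  # every evaluation logged exactly once
  expect_equal(nrow(st$eval_log), 18 * 3)
  expect_false(anyDuplicated(st$eval_log[c("run", "replicate")]) > 0)
})

test_that("a noiseless additive objective is solved exactly by one stage", {
  f <- toy_factors3()
  obj <- synthetic_additive_objective(f, sigma = 0)
  cfg <- stage_config(f, array = "L9",
                      assignment = c(lr = 1, mom = 2, nodes = 3),
                      retain_k = 2)
  st <- run_stage(cfg, obj)
  expect_equal(st$best, attr(obj, "true_best"))
  # additive prediction over ALL factors at the true best hits the true
  # optimum exactly (no interactions by construction)
  pred <- predict_additive(st$rt_mean, st$best)
  expect_equal(pred$predicted, attr(obj, "true_optimum"), tolerance = 1e-12)
})

test_that("single-replicate stages remain valid (zero-width SD column)", {
  f <- toy_factors3()
  obj <- synthetic_additive_objective(f, sigma = 0)
  cfg <- stage_config(f, array = "L9", replicates = 1,
                      assignment = c(lr = 1, mom = 2, nodes = 3))
  st <- run_stage(cfg, obj)
  expect_equal(st$summary$sd, rep(0, 9))
  expect_true(all(is.finite(st$summary$sn)))
  expect_equal(nrow(st$eval_log), 9)
})

test_that("refinement halves level spacing around the stage-1 winner", {
  ex <- cvd_example_stage1()
  st <- run_stage(stage1_config(ex), lookup_objective(ex$plan, ex$results))
  ref <- refine_factors(st)
  # categorical significant factors and the boundary structural factor fixed
  expect_equal(ref$fixed, list(hidden_layers = 4, activation = "tanh",
                               optimizer = "sgd"))
  expect_equal(ref$factors$learning_rate$levels, c(0.25, 0.30, 0.35))
  expect_equal(ref$factors$moment_rate$levels, c(0.85, 0.90, 0.95))
  expect_equal(ref$factors$hidden_nodes$levels, c(6, 8, 10))
  # integer spacing 4 -> step 2
  expect_equal(ref$rule["hidden_nodes", "step"], 2)
})

test_that("refined levels at a hard bound are clipped with a warning", {
  f <- list(factor_spec("rate", c(0.05, 0.15, 0.25), role = "numeric",
                        lower = 0.01),
            factor_spec("other", c(1, 2, 3), role = "numeric"))
  # craft an objective whose optimum is the lowest rate level
  obj <- synthetic_additive_objective(
    f, effects = list(rate = c(0.2, 0.1, 0), other = c(0, 0.05, 0.1)))
  cfg <- stage_config(f, array = "L9", assignment = c(rate = 1, other = 2),
                      retain_k = 1)
  st <- run_stage(cfg, obj)
  expect_equal(st$best$rate, 0.05)
  expect_warning(ref <- refine_factors(st), "clipped")
  expect_equal(ref$factors$rate$levels, c(0.01, 0.05, 0.10))
})

test_that("integer refinement step that rounds to zero is an error", {
  f <- list(factor_spec("n", c(4, 5, 6), role = "integer"),
            factor_spec("other", c(1, 2, 3), role = "numeric"))
  obj <- synthetic_additive_objective(
    f, effects = list(n = c(0, 0.05, 0.1), other = c(0, 0.05, 0.1)))
  cfg <- stage_config(f, array = "L9", assignment = c(n = 1, other = 2),
                      retain_k = 1)
  st <- run_stage(cfg, obj)
  expect_error(refine_factors(st), "rounds to zero")
})

test_that("confirmation replay matches the recorded summaries and intervals", {
  ex <- cvd_example_stage1()
  st <- run_stage(stage1_config(ex), lookup_objective(ex$plan, ex$results))
  conf <- confirm_setting(st$best, replay_objective(ex$confirmation), r = 5,
                          ci_mean = st$ci_mean, ci_sn = st$ci_sn)
  expect_equal(conf$mean, 0.7383, tolerance = 1e-3)
  expect_equal(conf$sn, -2.636, tolerance = 0.005 / 2.636)
  expect_true(conf$pass_mean)
  expect_true(conf$pass_sn)
  ex2 <- cvd_example_stage2()
  conf2 <- confirm_setting(list(), replay_objective(ex2$confirmation), r = 5)
  expect_equal(conf2$mean, 0.7414, tolerance = 1e-3)
  expect_equal(conf2$sn, -2.598, tolerance = 0.005 / 2.598)
  # constructed failure: observation far outside a tight interval
  bad_ci <- structure(list(center = 0.9, halfwidth = 0.01), class = "tsto_ci")
  conf3 <- confirm_setting(list(), replay_objective(rep(0.5, 5)), r = 5,
                           ci_mean = bad_ci)
  expect_false(conf3$pass_mean)
})

test_that("the full two-stage replay reproduces the comparison table", {
  ex1 <- cvd_example_stage1(); ex2 <- cvd_example_stage2()
  rep <- run_tsto(stage1_config(ex1),
                  lookup_objective(ex1$plan, ex1$results),
                  stage2_objective = lookup_objective(ex2$plan, ex2$results),
                  confirm1_objective = replay_objective(ex1$confirmation),
                  confirm2_objective = replay_objective(ex2$confirmation))
  expect_equal(rep$best_setting,
               list(hidden_layers = 4, activation = "tanh", optimizer = "sgd",
                    learning_rate = 0.25, moment_rate = 0.85,
                    hidden_nodes = 10))
  imp <- rep$comparison[rep$comparison$stage == "Improvement", ]
  expect_lt(abs(imp$mean - 0.0032), 1e-3)
  expect_lt(abs(imp$sn - 0.0374), 0.005)
  expect_lt(abs(imp$sd - -0.0002), 1e-3)
  expect_equal(rep$stage2$pred_mean$predicted, 0.7399, tolerance = 1e-3)
  expect_equal(rep$stage2$pred_sn$predicted, -2.616, tolerance = 0.005 / 2.616)
})

test_that("the driver is deterministic: same seed, identical reports", {
  f <- toy_factors6()
  obj <- synthetic_additive_objective(f, sigma = 0.02)
  cfg <- stage_config(f, array = "L18", seed = 11)
  # four numeric factors advance here, so stage 2 falls back to the
  # smallest fitting catalog array with a warning
  expect_warning(r1 <- run_tsto(cfg, obj), "4 refined factor")
  r2 <- suppressWarnings(run_tsto(cfg, obj))
  expect_identical(r1$comparison, r2$comparison)
  expect_identical(r1$stage1$eval_log, r2$stage1$eval_log)
})

test_that("noiseless two-stage run centers on and confirms the true optimum", {
  f <- toy_factors6()
  obj <- synthetic_additive_objective(f, sigma = 0)
  cfg <- stage_config(f, array = "L18", seed = 3)
  rep <- suppressWarnings(run_tsto(cfg, obj))
  tb <- attr(obj, "true_best")
  # stage-1 best equals the construction's optimum
  expect_equal(rep$stage1$best[names(tb)], tb)
  # stage-2 confirmation mean is at least the stage-1 confirmation mean
  expect_gte(rep$confirm2$mean, rep$confirm1$mean)
})

test_that("experiment-budget arithmetic matches the grid-search comparison", {
  ex1 <- cvd_example_stage1()
  b1 <- experiment_budget(ex1$factors, 3, "L18")
  expect_equal(b1$full_factorial, 2187)
  expect_equal(b1$array_experiments, 54)
  expect_equal(b1$reduction, 40.5)
  b2 <- experiment_budget(toy_factors3(), 3, "L9")
  expect_equal(b2$full_factorial, 81)
  expect_equal(b2$array_experiments, 27)
  expect_equal(b2$reduction, 3)
  b3 <- experiment_budget(list(factor_spec("a", c("x", "y"))), 1, "L4")
  expect_equal(b3$full_factorial, 2)
})
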