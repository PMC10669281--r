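# Response tables, pooled ANOVA, F helpers, additive prediction and
# confirmation confidence intervals, validated against the worked example
# and against independent oracles.

stage1_pooled <- c("hidden_layers", "learning_rate", "moment_rate",
                   "hidden_nodes")

stage1_analysis <- function() {
  ex <- cvd_example_stage1()
  s <- summarize_runs(ex$plan, ex$results)
  list(ex = ex, s = s,
       rt_mean = response_table(ex$plan, s, "mean"),
       rt_sn = response_table(ex$plan, s, "sn"),
       a_mean = taguchi_anova(ex$plan, s, pooled = stage1_pooled, kind = "mean"),
       a_sn = taguchi_anova(ex$plan, s, pooled = stage1_pooled, kind = "sn"))
}

test_that("screening response tables reproduce level means, effects, ranks", {
  st <- stage1_analysis()
  lm_act <- st$rt_mean$level_means[["activation"]]
  expect_equal(unname(lm_act), c(0.4968, 0.6587, 0.6443), tolerance = 1e-3)
  expect_equal(st$rt_mean$effects[["activation"]], 0.1619, tolerance = 1e-3)
  expect_equal(unname(st$rt_mean$ranks),
               c(6L, 1L, 2L, 4L, 5L, 3L))  # layers..nodes
  expect_equal(st$rt_sn$effects[["activation"]], 2.3102,
               tolerance = 0.005 / 2.3102)
  # constant response: all effects zero, ranks a stable permutation
  plan9 <- make_plan(toy_factors3(), "L9",
                     assignment = c(lr = 1, mom = 2, nodes = 3))
  rt0 <- response_table(plan9, setNames(rep(0.5, 9), 1:9), "mean")
  expect_equal(unname(rt0$effects), rep(0, 3))
  expect_equal(unname(rt0$ranks), 1:3)
})

test_that("pooled screening ANOVA reproduces MS_error, F, p, R-squared", {
  st <- stage1_analysis()
  a <- st$a_mean
  expect_equal(attr(a, "ve"), 0.003901, tolerance = 1e-3)
  expect_equal(attr(a, "error_df"), 13L)
  f_act <- a$f[a$source == "activation"]
  expect_equal(f_act, 12.35, tolerance = 0.05 / 12.35)
  expect_equal(a$p[a$source == "activation"], 0.001, tolerance = 1)
  expect_lt(abs(a$p[a$source == "activation"] - 0.001), 5e-4)
  expect_equal(attr(a, "r_squared"), 0.7909, tolerance = 1e-3)
  expect_equal(attr(a, "r_squared_adj"), 0.7265, tolerance = 1e-3)
  expect_true(all(is.na(a$f[a$pooled])))  # pooled rows carry no F/p
  expect_equal(attr(st$a_sn, "ve"), 0.815, tolerance = 1e-3)
})

test_that("refinement-stage ANOVA reproduces F and p with one pooled factor", {
  ex <- cvd_example_stage2()
  s <- summarize_runs(ex$plan, ex$results)
  a <- taguchi_anova(ex$plan, s, pooled = "hidden_nodes", kind = "mean")
  expect_equal(attr(a, "error_df"), 4L)
  expect_equal(a$f[a$source == "learning_rate"], 5.94, tolerance = 0.05 / 5.94)
  expect_equal(a$p[a$source == "learning_rate"], 0.06, tolerance = 0.1)
  a_sn <- taguchi_anova(ex$plan, s, pooled = "hidden_nodes", kind = "sn")
  expect_equal(a_sn$f[a_sn$source == "learning_rate"], 6.07,
               tolerance = 0.05 / 6.07)
  expect_equal(attr(a_sn, "ve"), 9.3e-5, tolerance = 0.05)
})

test_that("sum-of-squares decomposition holds exactly on arbitrary designs", {
  set.seed(7)
  plan <- make_plan(toy_factors3(), "L9",
                    assignment = c(lr = 1, mom = 2, nodes = 3))
  for (i in 1:10) {
    y <- setNames(runif(9), 1:9)
    full <- taguchi_anova(plan, y, pooled = character(), kind = "mean")
    sst <- attr(full, "sst")
    ss_all <- sum(full$ss[full$source %in% names(plan$factors)])
    resid <- full$ss[full$source == "Error"]
    expect_equal(ss_all + resid, sst, tolerance = 1e-10)
  }
})

test_that("explicit pooling equals folding pooled-factor SS into error", {
  ex <- cvd_example_stage1()
  s <- summarize_runs(ex$plan, ex$results)
  full <- taguchi_anova(ex$plan, s, pooled = character(), kind = "mean")
  pooledv <- taguchi_anova(ex$plan, s, pooled = stage1_pooled, kind = "mean")
  manual_sse <- full$ss[full$source == "Error"] +
    sum(full$ss[full$source %in% stage1_pooled])
  manual_df <- full$df[full$source == "Error"] +
    sum(full$df[full$source %in% stage1_pooled])
  expect_equal(pooledv$ss[pooledv$source == "Error"], manual_sse)
  expect_equal(pooledv$df[pooledv$source == "Error"], manual_df)
  expect_equal(attr(pooledv, "ve"), manual_sse / manual_df)
})

test_that("response tables are invariant under run-order permutation", {
  ex <- cvd_example_stage2()
  s <- summarize_runs(ex$plan, ex$results)
  rt1 <- response_table(ex$plan, s, "mean")
  shuffled <- ex$results[sample(nrow(ex$results)), ]
  s2 <- summarize_runs(ex$plan, shuffled, sn_type = "ltb")
  rt2 <- response_table(ex$plan, s2, "mean")
  expect_equal(rt1$level_means, rt2$level_means)
  expect_equal(rt1$effects, rt2$effects)
})

test_that("ANOVA guards: empty unpooled set, no error DF, degenerate data", {
  plan <- make_plan(toy_factors3(), "L9",
                    assignment = c(lr = 1, mom = 2, nodes = 3))
  y <- setNames(runif(9), 1:9)
  expect_error(taguchi_anova(plan, y, pooled = c("lr", "mom", "nodes")),
               "unpooled")
  expect_error(taguchi_anova(plan, setNames(rep(1, 9), 1:9),
                             pooled = "nodes"), "degenerate")
  # 4 factors on all 4 L9 columns, nothing pooled -> 0 error DF
  f4 <- c(toy_factors3(), list(factor_spec("extra", c(1, 2, 3), role = "numeric")))
  plan4 <- make_plan(f4, "L9",
                     assignment = c(lr = 1, mom = 2, nodes = 3, extra = 4))
  expect_error(taguchi_anova(plan4, y, pooled = character()),
               "error degrees of freedom")
})

test_that("F quantiles and p-values are accurate and mutually inverse", {
  expect_equal(f_quantile(0.05, 1, 13), 4.6672, tolerance = 5e-4 / 4.6672)
  expect_equal(f_quantile(0.05, 1, 4), 7.7086, tolerance = 5e-4 / 7.7086)
  expect_equal(f_pvalue(12.35, 2, 13), 0.001, tolerance = 1)
  expect_lt(abs(f_pvalue(12.35, 2, 13) - 0.001), 5e-4)
  for (alpha in c(0.01, 0.05, 0.1, 0.5)) {
    expect_equal(f_pvalue(f_quantile(alpha, 2, 13), 2, 13), alpha,
                 tolerance = 1e-6)
  }
  expect_error(f_quantile(0.05, 0, 5))
})

test_that("significant factors are those with p below alpha", {
  st <- stage1_analysis()
  expect_setequal(significant_factors(st$a_mean, 0.1),
                  c("activation", "optimizer"))
  ex2 <- cvd_example_stage2()
  s2 <- summarize_runs(ex2$plan, ex2$results)
  a2 <- taguchi_anova(ex2$plan, s2, pooled = "hidden_nodes", kind = "mean")
  expect_setequal(significant_factors(a2, 0.1),
                  c("learning_rate", "moment_rate"))
  expect_length(significant_factors(st$a_mean, 1e-9), 0)
})

test_that("additive predictions match the worked example and degenerate case", {
  st <- stage1_analysis()
  p <- predict_additive(st$rt_mean, list(activation = "tanh",
                                         optimizer = "sgd"))
  expect_equal(p$predicted, 0.7166, tolerance = 1e-3)
  ps <- predict_additive(st$rt_sn, list(activation = "tanh",
                                        optimizer = "sgd"))
  expect_equal(ps$predicted, -2.919, tolerance = 0.005 / 2.919)
  expect_equal(predict_additive(st$rt_mean)$predicted, st$rt_mean$grand_mean)
  expect_equal(predict_additive(st$rt_mean)$predicted, 0.5999,
               tolerance = 1e-3)
  expect_error(predict_additive(st$rt_mean, list(bogus = 1)), "Unknown factor")
  expect_error(predict_additive(st$rt_mean, list(activation = "swish")),
               "no level")
})

test_that("confirmation CI half-widths match the worked example", {
  st <- stage1_analysis()
  ci <- confidence_halfwidth(st$a_mean, 18, c("activation", "optimizer"),
                             r = 5, center = 0.7166)
  expect_equal(ci$n_eff, 3.6)
  expect_equal(ci$halfwidth, 0.0933, tolerance = 1e-3)
  expect_equal(ci$lower, 0.6233, tolerance = 1e-3)
  expect_equal(ci$upper, 0.8099, tolerance = 1e-3)
  ci_sn <- confidence_halfwidth(st$a_sn, 18, c("activation", "optimizer"),
                                r = 5)
  expect_equal(ci_sn$halfwidth, 1.3481, tolerance = 0.005)
})

test_that("zero pooled variance yields a zero half-width", {
  # build a response that is exactly additive in the unpooled factors so
  # the pooled error variance vanishes
  plan <- make_plan(toy_factors3(), "L9",
                    assignment = c(lr = 1, mom = 2, nodes = 3))
  idx <- plan$array$matrix[, 1]
  y <- setNames(c(0.1, 0.2, 0.3)[idx], 1:9)
  a <- taguchi_anova(plan, y, pooled = c("mom", "nodes"), kind = "mean")
  expect_equal(attr(a, "ve"), 0, tolerance = 1e-15)
  ci <- confidence_halfwidth(a, 9, "lr", r = 5)
  expect_equal(ci$halfwidth, 0, tolerance = 1e-7)
})

test_that("best-level selection follows mean, then SN, then level order", {
  st <- stage1_analysis()
  best <- select_best_levels(st$rt_mean, st$rt_sn)
  expect_equal(best, list(hidden_layers = 4, activation = "tanh",
                          optimizer = "sgd", learning_rate = 0.3,
                          moment_rate = 0.9, hidden_nodes = 8))
  ex2 <- cvd_example_stage2()
  s2 <- summarize_runs(ex2$plan, ex2$results)
  best2 <- select_best_levels(response_table(ex2$plan, s2, "mean"),
                              response_table(ex2$plan, s2, "sn"))
  expect_equal(best2, list(learning_rate = 0.25, moment_rate = 0.85,
                           hidden_nodes = 10))
  # constructed exact tie on the mean; SN favors level 2
  plan <- make_plan(list(factor_spec("a", c(1, 2, 3), role = "numeric")),
                    "L9", assignment = c(a = 1))
  idx <- plan$array$matrix[, 1]
  y_mean <- setNames(c(0.5, 0.5, 0.1)[idx], 1:9)
  y_sn <- setNames(c(-3, -1, -5)[idx], 1:9)
  rm_ <- response_table(plan, y_mean, "mean")
  rs_ <- response_table(plan, y_sn, "sn")
  expect_equal(select_best_levels(rm_, rs_)$a, 2)
})
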