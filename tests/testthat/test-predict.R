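test_that("stratified 3:2 splits use round-half-up per stratum", {
  ann <- balanced_ann(19, 22)  # 19 cases, 22 controls
  sp <- random_split(ann, split_scheme(seed = 3), 1)
  grp <- setNames(ann$group, ann$sample_id)
  expect_equal(sum(grp[sp$train] == "control"), 13)
  expect_equal(sum(grp[sp$train] == "case"), 11)
  expect_equal(sum(grp[sp$validation] == "control"), 9)
  expect_equal(sum(grp[sp$validation] == "case"), 8)
  # disjoint and exhaustive
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ann$sample_id)
  # deterministic given (seed, repetition); different repetitions differ
  sp2 <- random_split(ann, split_scheme(seed = 3), 1)
  expect_identical(sp, sp2)
  expect_false(setequal(sp$train, random_split(ann, split_scheme(seed = 3), 2)$train))
  # degenerate: single class
  expect_error(random_split(toy_ann(paste0("s", 1:5), rep("case", 5)),
                            split_scheme(), 1),
               "stratum|class")
})

test_that("split properties hold across repetitions", {
  ann <- balanced_ann(7, 9)
  sch <- split_scheme(train_fraction = 0.6, seed = 9)
  for (r in 1:25) {
    sp <- random_split(ann, sch, r)
    expect_length(intersect(sp$train, sp$validation), 0)
    expect_setequal(c(sp$train, sp$validation), ann$sample_id)
    expect_length(sp$train, floor(0.6 * 7 + 0.5) + floor(0.6 * 9 + 0.5))
  }
})

test_that("logistic IRLS matches glm and handles separation", {
  set.seed(4)
  x <- rnorm(80)
  y <- rbinom(80, 1, plogis(0.3 + 1.2 * x))
  fit <- fit_logistic_univariate(x, y)
  ref <- glm(y ~ x, family = binomial())
  expect_false(fit$separated)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-6)
  # slope sign follows the group-mean difference
  expect_gt(fit$slope * (mean(x[y == 1]) - mean(x[y == 0])), 0)

  # perfectly informative feature: flagged, but ranking intact (AUC 1)
  ysep <- rep(0:1, each = 10)
  sep_fit <- fit_logistic_univariate(as.numeric(ysep), ysep)
  expect_true(sep_fit$separated)
  expect_equal(roc_auc(predict(sep_fit, as.numeric(ysep)), ysep), 1)

  # single-class training errors; constant feature falls back to intercept
  expect_error(fit_logistic_univariate(rnorm(5), rep(1, 5)), "single class")
  const <- fit_logistic_univariate(rep(2, 10), rep(0:1, 5))
  expect_equal(const$slope, 0)
})

test_that("logistic estimator is consistent", {
  set.seed(6)
  slopes <- replicate(200, {
    x <- rnorm(200)
    y <- rbinom(200, 1, plogis(0 + 1.5 * x))
    fit_logistic_univariate(x, y)$slope
  })
  expect_lt(abs(mean(slopes) - 1.5), 0.15)
})

test_that("roc_auc implements the tie-corrected Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.4, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 8), rep(0:1, 4)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(8)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    expect_equal(roc_auc(s, y), enumerate_auc(s, y), tolerance = 1e-12)
  }
})

test_that("evaluate_split computes confusion-matrix metrics", {
  perfect <- structure(list(intercept = 0, slope = 10), class = "logistic_model")
  x <- c(1, 1, -1, -1); y <- c("case", "case", "control", "control")
  ev <- evaluate_split(perfect, x, y)
  expect_equal(unlist(ev), c(auc = 1, accuracy = 1, sensitivity = 1,
                             specificity = 1))
  # constant classifier at probability 0.6: calls everything a case
  const <- structure(list(intercept = qlogis(0.6), slope = 0),
                     class = "logistic_model")
  ev2 <- evaluate_split(const, x, y)
  expect_equal(unlist(ev2), c(auc = 0.5, accuracy = 0.5, sensitivity = 1,
                              specificity = 0))
  # TP=3 FN=1 TN=4 FP=2 -> sens 0.75, spec 2/3, acc 0.7
  ident <- structure(list(intercept = 0, slope = 1), class = "logistic_model")
  xv <- c(1, 1, 1, -1,  -1, -1, -1, -1, 1, 1)
  yv <- c(rep("case", 4), rep("control", 6))
  ev3 <- evaluate_split(ident, xv, yv)
  expect_equal(ev3$sensitivity, 0.75)
  expect_equal(ev3$specificity, 2 / 3)
  expect_equal(ev3$accuracy, 0.7)
})

test_that("repeated evaluation aggregates and is deterministic", {
  ann <- balanced_ann(12, 12)
  grp <- setNames(ann$group, ann$sample_id)
  # perfect marker: monotone map of the label
  x_perfect <- setNames(ifelse(grp == "case", 2, -2) +
                          seq_along(grp) * 1e-9, names(grp))
  sch <- split_scheme(n_repetitions = 60, seed = 5)
  st <- repeat_evaluation(x_perfect, ann, sch)
  expect_equal(st$auc_mean, 1)
  expect_equal(st$auc_ci_lower, 1)
  expect_equal(st$auc_ci_upper, 1)
  expect_equal(st$n_repetitions_used, 60)
  # bit-identical on re-run
  expect_identical(st, repeat_evaluation(x_perfect, ann, sch))
  # aggregate bounds
  x_noise <- toy_feature(ann, 0.8, 0, seed = 2)
  st2 <- repeat_evaluation(x_noise, ann, sch)
  expect_true(st2$auc_ci_lower <= st2$auc_mean &&
                st2$auc_mean <= st2$auc_ci_upper)
  metrics <- unlist(st2[, c("auc_mean", "accuracy_mean", "sensitivity_mean",
                            "specificity_mean")])
  expect_true(all(metrics >= 0 & metrics <= 1))
})

test_that("per-repetition AUC is invariant to monotone transforms", {
  ann <- balanced_ann(10, 10)
  x <- toy_feature(ann, 2, 0, seed = 3)
  sch <- split_scheme(n_repetitions = 40, seed = 7)
  st_raw <- repeat_evaluation(x, ann, sch)
  st_exp <- repeat_evaluation(exp(x), ann, sch)   # strictly increasing map
  expect_equal(st_raw$auc_mean, st_exp$auc_mean, tolerance = 1e-12)
  expect_equal(st_raw$auc_ci_lower, st_exp$auc_ci_lower, tolerance = 1e-12)
  expect_equal(st_raw$auc_ci_upper, st_exp$auc_ci_upper, tolerance = 1e-12)
})

test_that("flipping the fitted slope maps AUC to its complement", {
  # refitting on a negated feature mirrors the slope and leaves the
  # probabilities (hence AUC) unchanged; the complement appears when the
  # same validation data are scored with the slope sign flipped
  ann <- balanced_ann(10, 10)
  x <- toy_feature(ann, 2, 0, seed = 4)
  grp <- setNames(ann$group, ann$sample_id)
  sch <- split_scheme(n_repetitions = 25, seed = 8)
  for (r in 1:25) {
    sp <- random_split(ann, sch, r)
    fit <- fit_logistic_univariate(x[sp$train], grp[sp$train])
    flipped <- fit
    flipped$slope <- -fit$slope
    a <- evaluate_split(fit, x[sp$validation], grp[sp$validation])$auc
    b <- evaluate_split(flipped, x[sp$validation], grp[sp$validation])$auc
    expect_equal(b, 1 - a, tolerance = 1e-12)
  }
  # refit on the negated feature: identical scores, identical AUC
  st_pos <- repeat_evaluation(x, ann, sch)
  st_neg <- repeat_evaluation(-x, ann, sch)
  expect_equal(st_neg$auc_mean, st_pos$auc_mean, tolerance = 1e-12)
})

test_that("evaluate_predictors scores each requested probe", {
  sim <- simulate_panel(recovery_config(n_probes = 40, n_de = 2,
                                        effect_log2 = c(4, -4),
                                        frac_never_detected = 0, seed = 6))
  x <- delta_normalize(sim$ct, sim$truth$control_probe_ids)
  sch <- split_scheme(n_repetitions = 30, seed = 2)
  tab <- evaluate_predictors(x, sim$annotation, sim$truth$de_probe_ids, sch)
  expect_equal(tab$probe_id, sim$truth$de_probe_ids)
  expect_true(all(tab$auc_mean > 0.8))  # |effect| = 4 vs noise sd ~ 0.7
  expect_error(evaluate_predictors(x, sim$annotation, "absent", sch),
               "not in matrix")
})
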