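test_that("cross-validation partitions cow-days and is seed-deterministic", {
  herd <- small_herd(60, seed = 41)
  preds <- crossvalidate(herd, methods = c("M0", "M3A"), n_folds = 5,
                         n_reps = 2, seed = 9)
  # every cow-session predicted exactly once per model per replicate
  expect_equal(nrow(preds), 2 * 2 * nrow(herd))
  for (r in 1:2) {
    p <- preds[preds$replicate == r & preds$model == "M3A", ]
    expect_equal(sort(paste(p$cow_id, p$session)),
                 sort(paste(herd$cow_id, herd$session)))
    # both sessions of a cow-day share a fold
    fold_by_cow <- tapply(p$fold, p$cow_id, function(f) length(unique(f)))
    expect_true(all(fold_by_cow == 1))
  }
  # the doubling estimator has no parameters: replicate-invariant estimates
  m0 <- preds[preds$model == "M0", ]
  m0key <- paste(m0$cow_id, m0$session)
  expect_equal(m0$y_hat[m0$replicate == 1][order(m0key[m0$replicate == 1])],
               m0$y_hat[m0$replicate == 2][order(m0key[m0$replicate == 2])])

  again <- crossvalidate(herd, methods = c("M0", "M3A"), n_folds = 5,
                         n_reps = 2, seed = 9)
  expect_identical(as.data.frame(preds), as.data.frame(again))
})

test_that("the bias-variance decomposition is exact", {
  preds <- data.frame(
    replicate = c(1, 2, 1, 2), fold = 1,
    cow_id = "a", session = "AM", model = c("mA", "mA", "mB", "mB"),
    y_true = 23, y_hat = c(23, 25, 23, 23))
  dec <- decompose_mse(preds)
  a <- dec$per_animal[dec$per_animal$model == "mA", ]
  expect_equal(a$variance, 1)   # population variance of {23, 25}
  expect_equal(a$bias2, 1)      # mean estimate 24, truth 23
  expect_equal(a$mse, 2)
  b <- dec$per_animal[dec$per_animal$model == "mB", ]
  expect_equal(unlist(b[, c("variance", "bias2", "mse")]),
               c(variance = 0, bias2 = 0, mse = 0))
  expect_equal(dec$per_animal$mse,
               dec$per_animal$variance + dec$per_animal$bias2)

  herd <- small_herd(50, seed = 42)
  cv <- crossvalidate(herd, methods = c("M0", "M1"), n_folds = 5, n_reps = 3,
                      seed = 2)
  dec <- decompose_mse(cv)
  expect_equal(dec$per_animal$mse,
               dec$per_animal$variance + dec$per_animal$bias2,
               tolerance = 1e-9)
  expect_equal(sort(dec$aggregate$model), c("M0", "M1"))
})

test_that("predictive accuracy is 1 for perfect and 0 for mean-level estimates", {
  y <- c(20, 22, 24, 26, 28, 30)
  base <- data.frame(replicate = 1, fold = 1,
                     cow_id = letters[1:6], session = "AM",
                     model = "perfect", y_true = y, y_hat = y)
  two <- rbind(base, transform(base, replicate = 2))
  acc <- r2_accuracy(two)
  expect_equal(acc$per_replicate$r2, c(1, 1))
  expect_equal(acc$per_animal$r2, rep(1, 6))

  flat <- transform(two, model = "mean", y_hat = mean(y))
  acc <- r2_accuracy(flat)
  expect_equal(acc$per_replicate$r2, c(0, 0))
  expect_error(r2_accuracy(transform(two, y_true = 24)), "constant")
})

test_that("actual-on-estimated regression separates bias from correlation", {
  y <- c(20, 22, 24, 26, 28, 30)
  preds <- data.frame(replicate = 1, fold = 1, cow_id = letters[1:6],
                      session = "AM", model = "m", y_true = y, y_hat = y)
  fit <- regress_actual_on_estimated(preds, "m", "AM")
  expect_equal(unname(fit), c(0, 1, 1), tolerance = 1e-12)
  # affine rescaling of the estimates leaves the correlation untouched
  # but moves intercept and slope -- correlation alone cannot see bias
  shifted <- transform(preds, y_hat = 3 + 0.8 * y_hat)
  fit2 <- regress_actual_on_estimated(shifted, "m", "AM")
  expect_equal(fit2["correlation"], c(correlation = 1), tolerance = 1e-12)
  expect_equal(fit2["slope"], c(slope = 1 / 0.8), tolerance = 1e-12)
  expect_false(abs(fit2["intercept"]) < 1e-9)
  expect_error(regress_actual_on_estimated(preds[1:2, ], "m", "AM"), ">= 3")
})

test_that("discretization bias is the exact gap between continuous and table fits", {
  expect_equal(-1.147 * 0.25, -0.28675)
  herd <- small_herd(300, seed = 43)
  sch <- micl_scheme()
  f3a <- fit_daily_yield(herd, "M3A", scheme = sch)
  f3b <- fit_daily_yield(herd, "M3B", scheme = sch)
  db <- discretization_bias(f3a, sch, herd)
  expect_false(db$multiplicative)
  # at the midpoint the bias vanishes
  at_mid <- abs(db$per_record$t - db$per_record$tbar) < 1e-12
  expect_equal(db$per_record$bias[at_mid],
               rep(0, sum(at_mid)))
  # per record: continuous prediction = table prediction + beta (t - tbar)
  gap <- predict(f3a, herd) - predict(f3b, herd)
  expect_equal(gap, db$per_record$bias, tolerance = 1e-9)

  f7a <- fit_daily_yield(herd, "M7A", scheme = sch)
  db7 <- discretization_bias(f7a, sch, herd)
  expect_true(db7$multiplicative)
  expect_equal(db7$per_record$bias,
               exp(f7a$model$beta * (herd$interval_h - db7$per_record$tbar)),
               tolerance = 1e-12)
})

test_that("table contrasts match their closed forms", {
  expect_equal(acf_contrast_closed_form(1.942, 12.05), 0.6989, tolerance = 1e-4)
  expect_equal(acf_contrast_closed_form(1.942, 24.10), 1.3978, tolerance = 1e-4)
  expect_equal(acf_contrast_closed_form(2, 12.05), 0)
  expect_equal(acf_contrast_closed_form(2, 24.10), 0)

  herd <- small_herd(2000, seed = 44)
  sch <- micl_scheme()
  f2b <- fit_daily_yield(herd, "M2B", scheme = sch)
  f3b <- fit_daily_yield(herd, "M3B", scheme = sch)
  ctr <- acf_table_contrast(f3b$table, f2b$table, records = herd)
  # measured mean table difference tracks (2 - b) xbar within a few percent
  expect_equal(ctr$mean_diff, ctr$closed_form_mean_diff,
               tolerance = 0.05)
  # per-mirror-pair sums of the regression table track (2 - b) ybar
  expect_equal(mean(ctr$pair_sums$sum_a), ctr$closed_form_pair_sum,
               tolerance = 0.05)
  # and the b = 2 table sums to ~0 per pair
  expect_lt(max(abs(ctr$pair_sums$sum_b)), 0.5)
  expect_error(
    acf_table_contrast(f3b$table,
                       fit_daily_yield(herd, "M2B",
                                       scheme = micl_scheme(9, 15, 1))$table),
    "scheme")
})

test_that("cross-validation failures are recorded, not fatal", {
  herd <- small_herd(30, seed = 45)
  # a 2-class scheme leaves some test classes unpopulated in tiny folds;
  # those predictions surface as NA with a reason, never as an error
  preds <- crossvalidate(herd, methods = c("M0", "M1"), n_folds = 3,
                         n_reps = 1, seed = 1,
                         scheme = micl_scheme(11.9, 12.1, 0.1))
  expect_true(is.data.frame(attr(preds, "failures")))
  expect_equal(nrow(preds), 2 * nrow(herd))
  rep_inv <- eval_report(preds)
  expect_equal(nrow(rep_inv), 2)
})
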