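test_that("doubling estimator doubles", {
  expect_equal(predict_doubling(11.4), 22.8)
  expect_equal(predict_doubling(0.5), 1.0)
  expect_error(predict_doubling(0), "positive")
})

test_that("empirical ACF are mean paired differences with the zero-sum identity", {
  sch <- micl_scheme(9, 15, 0.5)
  # two cow-days in one complementary class pair: AM in [11.5, 12), PM mirror
  pairs <- make_pairs(t_am = c(11.8, 11.9), x_am = c(13, 12.5),
                      x_pm = c(11, 11.5))
  tab <- fit_acf_empirical(pairs, sch)
  k_am <- assign_micl(11.8, sch)
  d_pm <- tab$factor[tab$session == "PM" & tab$class == micl_mirror(k_am, sch)]
  d_am <- tab$factor[tab$session == "AM" & tab$class == k_am]
  expect_equal(d_pm, 1.5)   # mean(13 - 11, 12.5 - 11.5)
  expect_equal(d_am, -1.5)

  # zero-sum per mirror-class pair on a noisy herd, exactly
  herd <- small_herd(300, seed = 21)
  tab <- fit_acf_empirical(herd, sch)
  am <- tab[tab$session == "AM", ]
  pm <- tab[tab$session == "PM", ]
  mirror <- pm$factor[match(micl_mirror(am$class, sch), pm$class)]
  expect_equal(am$factor + mirror, rep(0, nrow(am)), tolerance = 1e-9)
})

test_that("symmetric noise-free herds need no correction", {
  p <- sim_params(n_cows = 40, seed = 13, partition_noise_sd_kg = 0,
                  interval_sd_h = 1e-12)
  herd <- simulate_herd(p)
  tab <- fit_acf_empirical(herd, micl_scheme())
  expect_equal(tab$factor, rep(0, nrow(tab)), tolerance = 1e-9)
})

test_that("factorial ACF equal class means of y - 2x and the empirical table", {
  sch <- micl_scheme(9, 15, 6)  # single interior class
  # AM milkings (x, y): (10, 21.4), (10.6, 21.4) -> mean(1.4, 0.2) = 0.8
  pairs <- make_pairs(t_am = c(11.5, 12.4), x_am = c(10, 10.6),
                      x_pm = c(11.4, 10.8))
  tab <- fit_acf_factorial(pairs, sch)
  expect_equal(tab$factor[tab$session == "AM" & tab$class == 1], 0.8)

  herd <- small_herd(300, seed = 22)
  sch <- micl_scheme()
  raw <- fit_acf_factorial(herd, sch, smooth = FALSE)
  emp <- fit_acf_empirical(herd, sch)
  expect_equal(raw$factor, emp$factor, tolerance = 1e-12)
  expect_equal(raw$class, emp$class)
})

test_that("smoothed factorial ACF lie on a per-session line in the midpoints", {
  herd <- small_herd(400, seed = 23)
  sch <- micl_scheme()
  tab <- fit_acf_factorial(herd, sch, smooth = TRUE)
  for (s in c("AM", "PM")) {
    a <- tab[tab$session == s & tab$class >= 1 & tab$class <= sch$K, ]
    fit <- lm(factor ~ midpoint_h, data = a)
    expect_equal(unname(residuals(fit)), rep(0, nrow(a)), tolerance = 1e-9)
  }
  # the smooth covers every interior class even if empty
  expect_true(all(seq_len(sch$K) %in% tab$class[tab$session == "AM"]))
})

test_that("linear regression recovers an exact coefficient surface", {
  rec <- linear_surface_records(14.46, 14.48, -1.147, 1.942)
  fit <- fit_lr(rec)
  expect_equal(fit$alpha_am, 14.46, tolerance = 1e-9)
  expect_equal(fit$alpha_pm, 14.48, tolerance = 1e-9)
  expect_equal(fit$beta, -1.147, tolerance = 1e-9)
  expect_equal(fit$b, 1.942, tolerance = 1e-9)
  expect_lt(fit$sigma2, 1e-18)

  # duplicated rows do not change an OLS fit
  fit2 <- fit_lr(rbind(rec, rec))
  expect_equal(coef(fit2$lm_fit), coef(fit$lm_fit), tolerance = 1e-9)

  # collinear design is reported, not silently dropped
  bad <- rec
  bad$interval_h <- 12
  expect_error(fit_lr(bad), "collinear|rank")
})

test_that("the reference herd attenuates b below 2", {
  herd <- small_herd(2000, seed = 24)
  fit <- fit_lr(herd)
  expect_lt(fit$b, 2)
  # brute-force normal equations agree with the lm route
  X <- cbind(am = herd$session == "AM", pm = herd$session == "PM",
             t = herd$interval_h, x = herd$single_yield_kg)
  beta_hat <- solve(crossprod(X), crossprod(X, herd$daily_yield_kg))
  expect_equal(unname(beta_hat[, 1]),
               unname(c(fit$alpha_am, fit$alpha_pm, fit$beta, fit$b)),
               tolerance = 1e-8)
})

test_that("LR-derived ACF evaluate the fitted surface at class midpoints", {
  m <- manual_lr_model(14.46, 14.48, -1.147, b = 1.942)
  sch <- micl_scheme(9, 15, 6)  # single class, midpoint 12
  tab <- acf_from_lr(m, sch)
  expect_equal(tab$factor[tab$session == "AM"], 14.46 - 1.147 * 12)
  expect_equal(tab$factor[tab$session == "AM"], 0.696, tolerance = 1e-9)
  # root of the AM factor line: alpha + beta t = 0 at t = -alpha/beta
  t0 <- -m$alpha_am / m$beta
  expect_equal(m$alpha_am + m$beta * t0, 0)
  expect_equal(t0, 12.6068, tolerance = 1e-4)
})

test_that("per-class factor sums follow the (2 - b) identity", {
  # pairs consistent with the coefficient surface: (2 - b) y = a1 + a2 + 24 b
  a1 <- 14.46; a2 <- 14.48; be <- -1.147; b <- 1.942
  y <- (a1 + a2 + 24 * be) / (2 - b)
  t_am <- seq(9.3, 14.7, by = 0.3)
  x_am <- (y - a1 - be * t_am) / b
  pairs <- make_pairs(t_am, x_am, y - x_am)
  sch <- micl_scheme()
  m <- manual_lr_model(a1, a2, be, b)
  tab <- acf_from_lr(m, sch, records = pairs_records(pairs))
  am <- tab[tab$session == "AM" & tab$class >= 1 & tab$class <= sch$K, ]
  pm <- tab[tab$session == "PM", ]
  sums <- am$factor + pm$factor[match(micl_mirror(am$class, sch), pm$class)]
  cm <- tapply(rep(y, length(t_am)), assign_micl(t_am, sch), mean)
  expect_equal(sums, rep((2 - b) * y, nrow(am)), tolerance = 1e-6)
  expect_equal(as.numeric((2 - b) * cm[as.character(am$class)]), sums,
               tolerance = 1e-6)
})

test_that("forcing b = 2 restores the zero-sum identity", {
  herd <- small_herd(300, seed = 25)
  fit <- fit_lr(herd, fix_b = 2)
  expect_equal(fit$b, 2)
  # residual orthogonality makes the mirror-pair sum vanish identically
  expect_equal(fit$alpha_am + fit$alpha_pm + 24 * fit$beta, 0,
               tolerance = 1e-9)
  tab <- acf_from_lr(fit, micl_scheme())
  am <- tab[tab$session == "AM", ]
  pm <- tab[tab$session == "PM", ]
  sums <- am$factor +
    pm$factor[match(micl_mirror(am$class, micl_scheme()), pm$class)]
  expect_equal(sums, rep(0, length(sums)), tolerance = 1e-9)
})

test_that("additive-table prediction adds the factor to b times the yield", {
  sch <- micl_scheme(9, 15, 6)
  tab <- factor_table(
    data.frame(session = c("AM", "PM"), class = 1L, midpoint_h = 12,
               factor = c(0.7, 0.7), n = 1L),
    kind = "additive", smoothing = "none", model_id = "M1", scheme = sch)
  expect_equal(predict_acf(11, "AM", 12, tab, b = 2), 22.7)
  expect_equal(predict_acf(10, "PM", 12, tab, b = 2) - 0.7, 20)
  tab0 <- factor_table(
    data.frame(session = c("AM", "PM"), class = 1L, midpoint_h = 12,
               factor = 0, n = 1L),
    kind = "additive", smoothing = "none", model_id = "M1", scheme = sch)
  expect_equal(predict_acf(c(7, 9), c("AM", "PM"), c(12, 12), tab0, b = 2),
               c(14, 18))
  # regression-derived factor with the fitted b reproduces the daily mean
  expect_equal(0.696 + 1.942 * 12.05, 24.0971)
  expect_error(predict_acf(10, "AM", 8, tab, b = 2), "class")
  expect_equal(predict_acf(10, "AM", 8, tab, b = 2, strict = FALSE),
               NA_real_)
})
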