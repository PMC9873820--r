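test_that("bulk-ratio factors are ratios of class sums with the reciprocal identity", {
  sch <- micl_scheme(9, 15, 0.5)
  # one complementary class pair, bulk AM 130 kg, bulk PM 110 kg
  pairs <- make_pairs(t_am = c(11.7, 11.8), x_am = c(60, 70), x_pm = c(50, 60))
  tab <- mcf_bulk_ratio(pairs, sch)
  k_am <- assign_micl(11.7, sch)
  f_am <- tab$factor[tab$session == "AM" & tab$class == k_am]
  f_pm <- tab$factor[tab$session == "PM" & tab$class == micl_mirror(k_am, sch)]
  expect_equal(f_am, 240 / 130)
  expect_equal(f_pm, 240 / 110)
  expect_equal(1 / f_am + 1 / f_pm, 1, tolerance = 1e-12)

  # symmetric bulk -> both factors 2
  sym <- make_pairs(t_am = c(11.7, 11.8), x_am = c(60, 50), x_pm = c(50, 60))
  tab <- mcf_bulk_ratio(sym, sch)
  expect_equal(tab$factor, rep(2, nrow(tab)))

  # reciprocal-sum identity across all mirror pairs of a noisy herd
  herd <- small_herd(300, seed = 31)
  tab <- mcf_bulk_ratio(herd, sch)
  am <- tab[tab$session == "AM", ]
  pm <- tab[tab$session == "PM", ]
  mir <- pm$factor[match(micl_mirror(am$class, sch), pm$class)]
  expect_equal(1 / am$factor + 1 / mir, rep(1, nrow(am)), tolerance = 1e-12)
})

test_that("the complement map is an involution with fixed point 2", {
  expect_equal(complement_mcf(240 / 110), 240 / 130, tolerance = 1e-12)
  expect_equal(complement_mcf(2.182), 1.846, tolerance = 5e-4)
  expect_equal(complement_mcf(2), 2)
  expect_equal(complement_mcf(complement_mcf(1.7)), 1.7, tolerance = 1e-12)
  expect_error(complement_mcf(1), "exceed 1")
})

test_that("origin regression and ratio of sums are distinct estimators", {
  sch <- micl_scheme(9, 15, 6)
  # one class holding (x, y) = (10, 21), (12, 25)
  pairs <- make_pairs(t_am = c(11.5, 12.3), x_am = c(10, 12),
                      x_pm = c(11, 13))
  tab_o <- fit_mcf_origin(pairs, sch)
  tab_r <- mcf_bulk_ratio(pairs, sch)
  f_o <- tab_o$factor[tab_o$session == "AM" & tab_o$class == 1]
  f_r <- tab_r$factor[tab_r$session == "AM" & tab_r$class == 1]
  expect_equal(f_o, 510 / 244, tolerance = 1e-12)   # sum(xy)/sum(x^2)
  expect_equal(f_r, 46 / 22, tolerance = 1e-12)     # sum(y)/sum(x)
  expect_gt(abs(f_o - f_r), 1e-4)                   # 2.0902 vs 2.0909

  # exact doubling data: every class factor is exactly 2 for both
  dbl <- make_pairs(t_am = seq(10, 14, by = 0.5), x_am = seq(8, 12, by = 0.5),
                    x_pm = seq(8, 12, by = 0.5))
  expect_equal(fit_mcf_origin(dbl, micl_scheme())$factor,
               rep(2, 18), tolerance = 1e-12)
  expect_equal(mcf_bulk_ratio(dbl, micl_scheme())$factor,
               rep(2, 18), tolerance = 1e-12)
})

test_that("reciprocal smoothing reproduces an exact linear reciprocal surface", {
  # single yields proportional to daily with portion 0.25 + 0.02 t;
  # intervals sit exactly at class midpoints so the raw per-class factors
  # equal the reciprocal line exactly
  t_am <- seq(9.25, 14.75, by = 0.5)
  y <- rep(24, length(t_am))
  x_am <- (0.25 + 0.02 * t_am) * y
  pairs <- make_pairs(t_am, x_am, y - x_am)
  sch <- micl_scheme()
  tab <- fit_mcf_origin(pairs, sch, smooth = TRUE)
  am <- tab[tab$session == "AM" & tab$class >= 1 & tab$class <= sch$K, ]
  expect_equal(am$factor, 1 / (0.25 + 0.02 * am$midpoint_h), tolerance = 1e-9)
  f12 <- 1 / (0.25 + 0.02 * 12)
  expect_equal(f12, 1 / 0.49, tolerance = 1e-12)
  # smoothing covers interior classes without members
  expect_true(all(seq_len(sch$K) %in% am$class))
})

test_that("quadratic portion smoothing recovers an exact quadratic", {
  t_am <- seq(9.2, 14.8, by = 0.4)
  y <- rep(24, length(t_am))
  a <- 0.1; b2 <- 0.025; c2 <- 0.0005
  t_pm <- 24 - t_am
  x_pm <- (a + b2 * t_pm + c2 * t_pm^2) * y
  pairs <- make_pairs(t_am, y - x_pm, x_pm)
  sch <- micl_scheme()
  tab <- smooth_mcf_quadratic(pairs, sch)
  pm <- tab[tab$session == "PM" & tab$class >= 1 & tab$class <= sch$K, ]
  expect_equal(pm$factor, 1 / (a + b2 * pm$midpoint_h + c2 * pm$midpoint_h^2),
               tolerance = 1e-9)
  # AM factors come from the complement of the PM portion at 24 - t
  am <- tab[tab$session == "AM" & tab$class >= 1 & tab$class <= sch$K, ]
  t24 <- 24 - am$midpoint_h
  expect_equal(am$factor, 1 / (1 - (a + b2 * t24 + c2 * t24^2)),
               tolerance = 1e-9)

  # constant portion 0.5 -> every factor 2
  flat <- make_pairs(t_am, y / 2, y / 2)
  tab <- smooth_mcf_quadratic(flat, sch)
  expect_equal(tab$factor, rep(2, nrow(tab)), tolerance = 1e-9)
})

test_that("proportion regression recovers exact surfaces and flags bad domains", {
  rec <- proportion_surface_records(0.208, 0.208, 0.024)
  fit <- fit_proportion_lr(rec)
  expect_equal(fit$alpha_am, 0.208, tolerance = 1e-9)
  expect_equal(fit$alpha_pm, 0.208, tolerance = 1e-9)
  expect_equal(fit$beta, 0.024, tolerance = 1e-9)

  flat <- proportion_surface_records(0.5, 0.5, 0)
  fit2 <- fit_proportion_lr(flat)
  expect_equal(fit2$alpha_am, 0.5, tolerance = 1e-9)
  expect_equal(fit2$beta, 0, tolerance = 1e-9)

  m <- manual_proportion_model(0.208, 0.208, 0.024)
  expect_equal(predict_m6a(m, 12, "AM", 12), 12 / 0.496, tolerance = 1e-12)
  expect_equal(predict_m6a(m, 12, "AM", 12), 24.194, tolerance = 5e-4)
  expect_equal(predict_m6a(manual_proportion_model(0.5, 0.5, 0), 7, "PM", 13),
               14)
  # fitted proportion at/above 1 is rejected
  bad <- manual_proportion_model(0.9, 0.9, 0.01)
  expect_error(predict_m6a(bad, 12, "AM", 12), "outside \\(0, 1\\)")
})

test_that("proportion-derived MCF invert the fitted proportion at midpoints", {
  m <- manual_proportion_model(0.208, 0.208, 0.024)
  sch <- micl_scheme(9, 15, 6)
  tab <- mcf_from_proportion(m, sch)
  expect_equal(tab$factor[tab$session == "AM"], 1 / 0.496, tolerance = 1e-12)
  expect_equal(tab$factor[tab$session == "AM"], 2.016, tolerance = 5e-4)

  # the reciprocal-sum identity holds only up to a1 + a2 + 24 beta, not 1
  sch2 <- micl_scheme()
  tab2 <- mcf_from_proportion(m, sch2)
  am <- tab2[tab2$session == "AM", ]
  pm <- tab2[tab2$session == "PM", ]
  mir <- pm$factor[match(micl_mirror(am$class, sch2), pm$class)]
  expect_equal(1 / am$factor + 1 / mir,
               rep(0.208 + 0.208 + 24 * 0.024, nrow(am)), tolerance = 1e-12)
})

test_that("multiplicative prediction scales by the class factor", {
  sch <- micl_scheme(9, 15, 6)
  tab <- factor_table(
    data.frame(session = c("AM", "PM"), class = 1L, midpoint_h = 12,
               factor = 2.016, n = 1L),
    kind = "multiplicative", smoothing = "none", model_id = "M6B", scheme = sch)
  expect_equal(predict_mcf(12, "AM", 12, tab), 24.192)
  expect_error(predict_mcf(12, "AM", 8, tab), "class")
  # factors not exceeding 1 are rejected at construction
  expect_error(factor_table(
    data.frame(session = "AM", class = 1L, midpoint_h = 12, factor = 1, n = 1L),
    kind = "multiplicative", smoothing = "none", model_id = "x", scheme = sch),
    "exceed 1")
})

test_that("ratio estimators agree to first order and factors fall off with interval", {
  herd <- small_herd(3000, seed = 33, noise = 0.5)
  sch <- micl_scheme()
  k <- assign_micl(herd$interval_h, sch)
  key <- paste(herd$session, k)
  mor <- tapply(herd$daily_yield_kg / herd$single_yield_kg, key, mean)
  rom <- tapply(herd$daily_yield_kg, key, mean) /
    tapply(herd$single_yield_kg, key, mean)
  mid <- tapply(herd$interval_h, key, mean)
  sel <- abs(mid - 12) <= 2
  expect_lt(max(abs(mor[sel] / rom[sel] - 1)), 0.01)

  for (m in c("M4", "M5", "M6B")) {
    tab <- fit_daily_yield(herd, m, scheme = sch)$table
    for (s in c("AM", "PM")) {
      a <- tab[tab$session == s & tab$class >= 1 & tab$class <= sch$K, ]
      a <- a[order(a$midpoint_h), ]
      expect_true(all(diff(a$factor) < 0))
      expect_true(all(a$factor > 1.5 & a$factor < 3))
    }
  }
})
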