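#' Bulk-ratio multiplicative correction factors (M4, raw)
#'
#' The classical ratio factors: within each class, the factor for a session
#' is the bulk (summed) daily yield divided by the bulk yield of that
#' session's milkings, `F_AM = (AMP + PMP)/AMP` and
#' `F_PM = (AMP + PMP)/PMP`, i.e. the ratio-of-sums estimator. Entries are
#' keyed by the interval of the milking being corrected, so the AM factor
#' of a class and the PM factor of its mirror class come from the same
#' cow-days and satisfy `1/F_AM + 1/F_PM = 1` exactly.
#'
#' @inheritParams fit_acf_empirical
#' @return A multiplicative [factor_table()] (`model_id = "M4"`,
#'   smoothing `"none"`).
#' @export
mcf_bulk_ratio <- function(records, scheme) {
  pairs <- as_pairs(records)
  long <- pairs_long(pairs)
  k <- assign_micl(long$t, scheme)
  key <- paste(long$session, k)
  sum_x <- tapply(long$x, key, sum)
  sum_y <- tapply(long$y, key, sum)
  if (any(sum_x <= 0)) {
    stop("mcf_bulk_ratio: a class has zero bulk yield", call. = FALSE)
  }
  agg <- class_aggregate(long$session, long$t, scheme, values = list())
  agg$factor <- as.vector(sum_y[paste(agg$session, agg$class)] /
                            sum_x[paste(agg$session, agg$class)])
  factor_table(agg, kind = "multiplicative", smoothing = "none",
               model_id = "M4", scheme = scheme)
}

#' Quadratic-portion smoothed MCF (M4, smoothed)
#'
#' Fits a quadratic regression of the PM portion of daily yield on the PM
#' milking interval, `x_PM/y = a + b t + c t^2`, evaluates the fitted
#' portion at the class midpoints to get smoothed PM factors
#' `F_PM(k) = 1/portion(tbar)`, and derives the AM factors through the
#' complement identity `F_AM(k) = 1/(1 - portion(24 - tbar_AM(k)))`. The
#' smooth covers classes with no or few records.
#'
#' @inheritParams fit_acf_empirical
#' @param per_session Fit the quadratic separately for each session instead
#'   of deriving AM factors by complement? Default `FALSE`.
#' @return A multiplicative [factor_table()] (`model_id = "M4"`,
#'   smoothing `"quadratic_portion"`).
#' @export
smooth_mcf_quadratic <- function(records, scheme, per_session = FALSE) {
  pairs <- as_pairs(records)
  if (length(unique(pairs$t_pm)) < 3) {
    stop("smooth_mcf_quadratic: need at least 3 distinct PM intervals", call. = FALSE)
  }
  portion_fit <- function(t, p) stats::lm(p ~ t + I(t^2))
  predict_portion <- function(fit, t) {
    unname(stats::predict(fit, newdata = data.frame(t = t)))
  }
  fit_pm <- portion_fit(pairs$t_pm, pairs$x_pm / pairs$y)
  tab <- model_factor_grid(scheme, pairs_to_records(pairs))
  is_pm <- tab$session == "PM"
  p_pm <- predict_portion(fit_pm, tab$midpoint_h[is_pm])
  if (per_session) {
    fit_am <- portion_fit(pairs$t_am, pairs$x_am / pairs$y)
    p_am <- predict_portion(fit_am, tab$midpoint_h[!is_pm])
  } else {
    # complement: AM portion at t equals 1 - PM portion at 24 - t
    p_am <- 1 - predict_portion(fit_pm, 24 - tab$midpoint_h[!is_pm])
  }
  p <- numeric(nrow(tab))
  p[is_pm] <- p_pm
  p[!is_pm] <- p_am
  bad <- p <= 0 | p >= 1
  if (any(bad)) {
    stop(sprintf(
      "smooth_mcf_quadratic: fitted portion outside (0, 1) for session %s class %d",
      tab$session[which(bad)[1]], tab$class[which(bad)[1]]), call. = FALSE)
  }
  tab$factor <- 1 / p
  factor_table(tab, kind = "multiplicative", smoothing = "quadratic_portion",
               model_id = "M4", scheme = scheme)
}

#' Regression-through-origin MCF (M5)
#'
#' Within each (session, class), fits the no-intercept regression
#' `y = F x + e` separately (allowing heterogeneous class means and
#' variances), so each factor is the least-squares-through-origin estimate
#' `F = sum(x y)/sum(x^2)` -- a distinct estimator from the ratio of sums
#' used by [mcf_bulk_ratio()]. With `smooth = TRUE` the reciprocals of the
#' raw class factors are regressed linearly on the class midpoints
#' (count-weighted by default) and the smoothed factors
#' `F = 1/(a + b tbar)` are returned for all classes.
#'
#' @inheritParams fit_acf_empirical
#' @param smooth Apply the linear reciprocal smoothing? Default `FALSE`.
#' @param weighted Weight the reciprocal smoothing by class counts?
#'   Default `TRUE`.
#' @return A multiplicative [factor_table()] (`model_id = "M5"`).
#' @export
fit_mcf_origin <- function(records, scheme, smooth = FALSE, weighted = TRUE) {
  pairs <- as_pairs(records)
  long <- pairs_long(pairs)
  k <- assign_micl(long$t, scheme)
  key <- paste(long$session, k)
  sxy <- tapply(long$x * long$y, key, sum)
  sxx <- tapply(long$x^2, key, sum)
  agg <- class_aggregate(long$session, long$t, scheme, values = list())
  agg$factor <- as.vector(sxy[paste(agg$session, agg$class)] /
                            sxx[paste(agg$session, agg$class)])
  if (!smooth) {
    return(factor_table(agg, kind = "multiplicative", smoothing = "none",
                        model_id = "M5", scheme = scheme))
  }
  out <- list()
  for (s in c("AM", "PM")) {
    a <- agg[agg$session == s, ]
    w <- if (weighted) a$n else rep(1, nrow(a))
    fit <- stats::lm(I(1 / factor) ~ midpoint_h, data = a, weights = w)
    cls <- sort(unique(c(seq_len(scheme$K), a$class)))
    mid <- micl_midpoint(scheme, cls)
    mid[is.na(mid)] <- a$midpoint_h[match(cls[is.na(mid)], a$class)]
    keep <- !is.na(mid)
    recip <- stats::coef(fit)[1] + stats::coef(fit)[2] * mid[keep]
    if (any(recip <= 0 | recip >= 1)) {
      stop("fit_mcf_origin: smoothed reciprocal outside (0, 1); ",
           "factor undefined at some class midpoint", call. = FALSE)
    }
    out[[s]] <- data.frame(
      session = s, class = cls[keep], midpoint_h = mid[keep],
      factor = 1 / recip,
      n = ifelse(is.na(match(cls[keep], a$class)), 0L,
                 a$n[match(cls[keep], a$class)])
    )
  }
  factor_table(do.call(rbind, out), kind = "multiplicative",
               smoothing = "linear_reciprocal", model_id = "M5", scheme = scheme)
}

#' Proportion-regression model (M6)
#'
#' Regresses the single-milking proportion of daily yield on the milking
#' interval, `x/y = alpha_j + beta t + e`, jointly over AM and PM rows with
#' session-specific intercepts and a common slope.
#'
#' @param records A milking-record table.
#' @param per_session_beta Allow a separate slope per session?
#'   Default `FALSE`.
#' @return A list of class `"proportion_model"`: `alpha_am`, `alpha_pm`,
#'   `beta` (and `beta_pm` if per-session), `se`, `sigma2`, `n`, `lm_fit`.
#' @export
fit_proportion_lr <- function(records, per_session_beta = FALSE) {
  records <- as_milking_records(records)
  df <- data.frame(
    p = records$single_yield_kg / records$daily_yield_kg,
    session = records$session, t = records$interval_h
  )
  if (length(unique(df$t)) < 3) {
    stop("fit_proportion_lr: need at least 3 distinct intervals", call. = FALSE)
  }
  fml <- if (per_session_beta) p ~ 0 + session + session:t else p ~ 0 + session + t
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("fit_proportion_lr: rank-deficient design", call. = FALSE)
  sm <- summary(fit)
  out <- list(
    alpha_am = unname(cf["sessionAM"]), alpha_pm = unname(cf["sessionPM"]),
    beta = unname(if (per_session_beta) cf["sessionAM:t"] else cf["t"]),
    beta_pm = if (per_session_beta) unname(cf["sessionPM:t"]) else NA_real_,
    se = sm$coefficients[, "Std. Error"],
    sigma2 = sm$sigma^2, n = nrow(df), lm_fit = fit
  )
  class(out) <- "proportion_model"
  out
}

#' @export
print.proportion_model <- function(x, ...) {
  cat("Proportion model: x/y = alpha_j + beta t\n")
  print(round(c(alpha_am = x$alpha_am, alpha_pm = x$alpha_pm, beta = x$beta), 4))
  invisible(x)
}

# fitted proportion for a session/interval, shared by M6A and M6B
proportion_at <- function(model, session, t) {
  alpha <- ifelse(session == "AM", model$alpha_am, model$alpha_pm)
  beta <- ifelse(session == "PM" & !is.na(model$beta_pm), model$beta_pm, model$beta)
  alpha + beta * t
}

#' Direct prediction from the proportion model (M6A)
#'
#' Daily yield is the single yield divided by its fitted proportion at the
#' observed (continuous) interval: `y-hat = x/(alpha_j + beta t)`.
#'
#' @param model A fitted [fit_proportion_lr()] model.
#' @param x Single-milking yields, kg.
#' @param session `"AM"`/`"PM"` per milking.
#' @param t Milking intervals, hours.
#' @return Estimated daily yields, kg.
#' @export
predict_m6a <- function(model, x, session, t) {
  stopifnot(inherits(model, "proportion_model"))
  p <- proportion_at(model, session, t)
  bad <- p <= 0 | p >= 1
  if (any(bad)) {
    stop(sprintf(
      "predict_m6a: fitted proportion %.3f outside (0, 1) at t = %.2f h",
      p[which(bad)[1]], t[which(bad)[1]]), call. = FALSE)
  }
  x / p
}

#' Class-wise MCF from the proportion model (M6B)
#'
#' Evaluates the fitted proportion at the class midpoints and inverts:
#' `F_j(k) = 1/(alpha_j + beta tbar_j(k))`. Note the complement identity
#' `1/F_AM + 1/F_PM = 1` holds only approximately for proportion-derived
#' factors (the mirror-pair reciprocals sum to
#' `alpha_AM + alpha_PM + 24 beta`, which the fit does not constrain to 1);
#' the residual of that identity is a useful diagnostic.
#'
#' @param model A fitted [fit_proportion_lr()] model.
#' @param scheme A [micl_scheme()].
#' @param records Optional training records (edge-class entries and counts,
#'   as in [acf_from_lr()]).
#' @return A multiplicative [factor_table()] (`model_id = "M6B"`).
#' @export
mcf_from_proportion <- function(model, scheme, records = NULL) {
  stopifnot(inherits(model, "proportion_model"))
  tab <- model_factor_grid(scheme, records)
  p <- proportion_at(model, tab$session, tab$midpoint_h)
  bad <- p <= 0 | p >= 1
  if (any(bad)) {
    stop(sprintf(
      "mcf_from_proportion: fitted proportion outside (0, 1) for session %s class %d",
      tab$session[which(bad)[1]], tab$class[which(bad)[1]]), call. = FALSE)
  }
  tab$factor <- 1 / p
  factor_table(tab, kind = "multiplicative", smoothing = "model_derived",
               model_id = "M6B", scheme = scheme)
}
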