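#' Doubling estimator of daily yield (M0)
#'
#' The original AM-PM plan estimator: daily yield is twice the observed
#' single-milking yield, which is exact only for equal 12-12 h intervals.
#'
#' @param x Single-milking yields, kg (> 0).
#' @return Estimated daily yields, kg.
#' @examples
#' predict_doubling(11.4)  # 22.8
#' @export
predict_doubling <- function(x) {
  if (any(x <= 0)) stop("predict_doubling: yields must be positive", call. = FALSE)
  2 * x
}

#' Empirical paired-difference additive correction factors (M1)
#'
#' The classical ACF estimator: within each milking-interval class, the PM
#' factor is the mean AM-minus-PM yield difference of the cow-days whose PM
#' interval falls in that class, and the AM factor is the sign-flipped mean
#' over cow-days whose AM interval falls in that class. Each table entry is
#' keyed by the interval of the milking being corrected, so the AM factor of
#' a class and the PM factor of its mirror class are computed from the same
#' cow-days and sum to zero exactly.
#'
#' @param records A milking-record table (paired cow-days are extracted with
#'   [validate_pairs()]); alternatively the `pairs` data frame itself.
#' @param scheme A [micl_scheme()].
#' @return An additive [factor_table()] (`model_id = "M1"`, no smoothing).
#'   Classes without records get no entry.
#' @export
fit_acf_empirical <- function(records, scheme) {
  pairs <- as_pairs(records)
  long <- pairs_long(pairs)
  agg <- class_aggregate(long$session, long$t, scheme,
                         values = list(factor = long$diff))
  factor_table(agg, kind = "additive", smoothing = "none",
               model_id = "M1", scheme = scheme)
}

#' Factorial-model additive correction factors (M2A/M2B)
#'
#' Fits the ACF model with the daily yield as response, the coefficient on
#' the single yield fixed at 2, and a session-by-class factorial effect:
#' `y = f(session, class) + 2x + e`. By least squares the class effects are
#' the within-(session, class) means of `y - 2x`, which coincide with the
#' empirical paired-difference factors. With `smooth = TRUE` the class
#' effects are replaced by a count-weighted linear fit on the class
#' midpoints per session (the smoothed table, M2B); the smoothed line also
#' covers interior classes without records.
#'
#' @inheritParams fit_acf_empirical
#' @param smooth Replace raw class effects by the per-session linear
#'   smooth? Default `FALSE` (M2A).
#' @return An additive [factor_table()] (`model_id` `"M2A"` or `"M2B"`).
#' @export
fit_acf_factorial <- function(records, scheme, smooth = FALSE) {
  pairs <- as_pairs(records)
  long <- pairs_long(pairs)
  # least-squares class effects with b fixed at 2: class means of y - 2x
  agg <- class_aggregate(long$session, long$t, scheme,
                         values = list(factor = long$y - 2 * long$x))
  if (!smooth) {
    return(factor_table(agg, kind = "additive", smoothing = "none",
                        model_id = "M2A", scheme = scheme))
  }
  out <- list()
  for (s in c("AM", "PM")) {
    a <- agg[agg$session == s, ]
    if (nrow(a) < 2 || length(unique(a$midpoint_h)) < 2) {
      warning("fit_acf_factorial: all records of session ", s,
              " in one class; smoothing falls back to the class mean")
      line <- c(stats::weighted.mean(a$factor, a$n), 0)
    } else {
      fit <- stats::lm(factor ~ midpoint_h, data = a, weights = a$n)
      line <- stats::coef(fit)
    }
    # interior classes are always covered by the line; edge classes only
    # where members define an empirical midpoint
    cls <- sort(unique(c(seq_len(scheme$K), a$class)))
    mid <- micl_midpoint(scheme, cls)
    mid[is.na(mid)] <- a$midpoint_h[match(cls[is.na(mid)], a$class)]
    out[[s]] <- data.frame(
      session = s, class = cls, midpoint_h = mid,
      factor = line[1] + line[2] * mid,
      n = ifelse(is.na(match(cls, a$class)), 0L, a$n[match(cls, a$class)])
    )
  }
  factor_table(do.call(rbind, out), kind = "additive", smoothing = "linear",
               model_id = "M2B", scheme = scheme)
}

#' Linear regression model for daily yield (M3A)
#'
#' Ordinary least squares for
#' `y = alpha_j + beta * t + gamma * (dim - d0) + b * x + e`, with
#' session-specific intercepts `alpha_AM`, `alpha_PM`, a common
#' milking-interval slope `beta` (kg/h), an optional days-in-milk slope
#' `gamma` (kg/day) and a free coefficient `b` on the single-milking yield.
#'
#' @param records A milking-record table.
#' @param use_dim Include the days-in-milk covariate? Default `FALSE`.
#' @param d0 Reference days in milk (only with `use_dim`). Default 150.
#' @param fix_b Fix the coefficient on the single yield at this value
#'   instead of estimating it (fitted via an offset); `fix_b = 2` collapses
#'   the model to the classical ACF form, restoring the per-class zero-sum
#'   identity of the derived factors. Default `NULL` (free `b`).
#' @return A list of class `"lr_model"`: `alpha_am`, `alpha_pm`, `beta`,
#'   `gamma` (or `NA`), `d0`, `b`, `se` (named SDs of the estimates),
#'   `sigma2` (residual variance), `n`, and the underlying `lm` fit.
#' @export
fit_lr <- function(records, use_dim = FALSE, d0 = 150, fix_b = NULL) {
  records <- as_milking_records(records)
  df <- data.frame(
    y = records$daily_yield_kg, session = records$session,
    t = records$interval_h, x = records$single_yield_kg,
    dimc = records$dim - d0
  )
  if (nrow(unique(df[c("t", "x")])) < 4) {
    stop("fit_lr: need at least 4 distinct (interval, yield) points", call. = FALSE)
  }
  free_b <- is.null(fix_b)
  if (!free_b) df$y <- df$y - fix_b * df$x
  fml <- if (use_dim && free_b) y ~ 0 + session + t + dimc + x
    else if (use_dim) y ~ 0 + session + t + dimc
    else if (free_b) y ~ 0 + session + t + x
    else y ~ 0 + session + t
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("fit_lr: rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  out <- list(
    alpha_am = unname(cf["sessionAM"]), alpha_pm = unname(cf["sessionPM"]),
    beta = unname(cf["t"]),
    gamma = if (use_dim) unname(cf["dimc"]) else NA_real_,
    d0 = d0, b = if (free_b) unname(cf["x"]) else fix_b,
    se = sm$coefficients[, "Std. Error"],
    sigma2 = sm$sigma^2, n = nrow(df), lm_fit = fit
  )
  class(out) <- "lr_model"
  out
}

#' @export
print.lr_model <- function(x, ...) {
  cat("Linear daily-yield model: y = alpha_j + beta t",
      if (!is.na(x$gamma)) "+ gamma (dim - d0)", "+ b x\n")
  print(round(c(alpha_am = x$alpha_am, alpha_pm = x$alpha_pm, beta = x$beta,
                gamma = x$gamma, b = x$b), 4))
  invisible(x)
}

#' Additive correction factors from a fitted linear regression (M3B)
#'
#' Evaluates the fitted regression surface at the class midpoints:
#' `Delta_j(k) = alpha_j + beta * tbar_j(k)`, ignoring the within-class
#' interval deviation (the source of the discretization bias, see
#' [discretization_bias()]). Predictions from the resulting table use
#' `b = b-hat` from the fit, not 2.
#'
#' @param model A fitted [fit_lr()] model.
#' @param scheme A [micl_scheme()].
#' @param records Optional training records; when given, edge classes with
#'   members get entries at their empirical mean intervals, and `n` counts
#'   are filled in. Without records the table covers interior classes only.
#' @return An additive [factor_table()] (`model_id = "M3B"`,
#'   smoothing `"model_derived"`); the fitted `b` is attached as the `"b"`
#'   attribute.
#' @export
acf_from_lr <- function(model, scheme, records = NULL) {
  stopifnot(inherits(model, "lr_model"))
  tab <- model_factor_grid(scheme, records)
  alpha <- ifelse(tab$session == "AM", model$alpha_am, model$alpha_pm)
  tab$factor <- alpha + model$beta * tab$midpoint_h
  out <- factor_table(tab, kind = "additive", smoothing = "model_derived",
                      model_id = "M3B", scheme = scheme)
  attr(out, "b") <- model$b
  out
}

# ---- internal helpers ------------------------------------------------------

# accept either a milking_records table or a ready-made pairs data frame
as_pairs <- function(records) {
  if (is.data.frame(records) && all(c("t_am", "x_am", "y") %in% names(records))) {
    return(records)
  }
  vp <- validate_pairs(records)
  if (nrow(vp$issues)) {
    warning("as_pairs: ", nrow(vp$issues),
            " cow-day issue(s) found; inconsistent cow-days dropped")
  }
  if (!nrow(vp$pairs)) stop("no valid AM/PM pairs in the records", call. = FALSE)
  vp$pairs
}

# one row per milking with the paired-difference response:
# for a PM milking (own interval t_pm) the target difference is x_am - x_pm,
# for an AM milking it is x_pm - x_am; both equal y - 2x of that milking
pairs_long <- function(pairs) {
  data.frame(
    session = rep(c("AM", "PM"), each = nrow(pairs)),
    t = c(pairs$t_am, pairs$t_pm),
    x = c(pairs$x_am, pairs$x_pm),
    y = rep(pairs$y, 2L),
    diff = c(pairs$x_pm - pairs$x_am, pairs$x_am - pairs$x_pm)
  )
}

# grid of (session, class) rows with midpoints for model-derived tables
model_factor_grid <- function(scheme, records = NULL) {
  if (is.null(records)) {
    cls <- seq_len(scheme$K)
    grid <- expand.grid(session = c("AM", "PM"), class = cls,
                        stringsAsFactors = FALSE)
    grid$midpoint_h <- micl_midpoint(scheme, grid$class)
    grid$n <- 0L
    return(grid)
  }
  records <- as_milking_records(records)
  agg <- class_aggregate(records$session, records$interval_h, scheme,
                         values = list())
  # all interior classes plus observed edge classes
  out <- list()
  for (s in c("AM", "PM")) {
    a <- agg[agg$session == s, ]
    cls <- sort(unique(c(seq_len(scheme$K), a$class)))
    mid <- micl_midpoint(scheme, cls)
    mid[is.na(mid)] <- a$midpoint_h[match(cls[is.na(mid)], a$class)]
    keep <- !is.na(mid)
    out[[s]] <- data.frame(
      session = s, class = cls[keep], midpoint_h = mid[keep],
      n = ifelse(is.na(match(cls[keep], a$class)), 0L,
                 a$n[match(cls[keep], a$class)])
    )
  }
  do.call(rbind, out)
}
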