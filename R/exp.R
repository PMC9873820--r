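#' Exponential regression model for daily yield (M7)
#'
#' Fits the log-linear ratio model
#' `log(y) = alpha_j + beta t + b log(x) + e` by ordinary least squares on
#' the log scale, with session-specific intercepts, a common interval slope
#' and a free elasticity `b` of the single-milking yield (the constrained
#' case `b = 1` corresponds to modelling the log daily-to-single yield
#' ratio directly). Exponentiating gives the exponential regression
#' prediction `y-hat = x^b exp(alpha_j + beta t)`.
#'
#' @param records A milking-record table; all yields must be positive.
#' @return A list of class `"exp_model"`: `alpha_am`, `alpha_pm`, `beta`,
#'   `b`, `se`, `sigma2` (residual variance on the log scale), `n`,
#'   `lm_fit`.
#' @export
fit_exp_model <- function(records) {
  records <- as_milking_records(records)
  bad <- which(records$single_yield_kg <= 0 | records$daily_yield_kg <= 0)
  if (length(bad)) {
    stop("fit_exp_model: non-positive yields in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    ly = log(records$daily_yield_kg), session = records$session,
    t = records$interval_h, lx = log(records$single_yield_kg)
  )
  if (nrow(unique(df[c("t", "lx")])) < 4) {
    stop("fit_exp_model: need at least 4 distinct (interval, log yield) points",
         call. = FALSE)
  }
  fit <- stats::lm(ly ~ 0 + session + t + lx, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("fit_exp_model: rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  out <- list(
    alpha_am = unname(cf["sessionAM"]), alpha_pm = unname(cf["sessionPM"]),
    beta = unname(cf["t"]), b = unname(cf["lx"]),
    se = sm$coefficients[, "Std. Error"],
    sigma2 = sm$sigma^2, n = nrow(df), lm_fit = fit
  )
  class(out) <- "exp_model"
  out
}

#' @export
print.exp_model <- function(x, ...) {
  cat("Exponential regression model: log y = alpha_j + beta t + b log x\n")
  print(round(c(alpha_am = x$alpha_am, alpha_pm = x$alpha_pm,
                beta = x$beta, b = x$b), 4))
  invisible(x)
}

#' Direct prediction from the exponential model (M7A)
#'
#' `y-hat = x^b exp(alpha_j + beta t)`, computed on the log scale to guard
#' against overflow.
#'
#' @param model A fitted [fit_exp_model()].
#' @param x Single-milking yields, kg (> 0).
#' @param session `"AM"`/`"PM"` per milking.
#' @param t Milking intervals, hours.
#' @return Estimated daily yields, kg.
#' @export
predict_exp <- function(model, x, session, t) {
  stopifnot(inherits(model, "exp_model"))
  if (any(x <= 0)) stop("predict_exp: yields must be positive", call. = FALSE)
  alpha <- ifelse(session == "AM", model$alpha_am, model$alpha_pm)
  exp(model$b * log(x) + alpha + model$beta * t)
}

#' Class-wise MCF from the exponential model (M7B)
#'
#' Converts the log-scale fit into ratio factors per (session, class) via a
#' second-order Taylor moment correction. With class means `xbar`, `ybar`
#' and variances `V(x)`, `V(y)`, the correction is
#' \deqn{\rho_j(k) = \exp\{\tfrac12 [V(y)/\bar y^2 - b V(x)/\bar x^2]\},}
#' and the factor is
#' `F_j(k) = rho_j(k) * xbar^(b-1) * exp(alpha_j + beta tbar_j(k))`.
#' Classes with a single record cannot estimate the variances and borrow
#' `rho = 1` (no adjustment); classes without records get no entry.
#'
#' @param model A fitted [fit_exp_model()].
#' @param records The training milking-record table supplying the class
#'   moments.
#' @param scheme A [micl_scheme()].
#' @return A multiplicative [factor_table()] (`model_id = "M7B"`) with a
#'   `rho` column.
#' @export
mcf_from_exp <- function(model, records, scheme) {
  stopifnot(inherits(model, "exp_model"))
  records <- as_milking_records(records)
  k <- assign_micl(records$interval_h, scheme)
  key <- paste(records$session, k)
  agg <- class_aggregate(records$session, records$interval_h, scheme,
                         values = list(xbar = records$single_yield_kg,
                                       ybar = records$daily_yield_kg))
  akey <- paste(agg$session, agg$class)
  vx <- as.vector(tapply(records$single_yield_kg, key, stats::var)[akey])
  vy <- as.vector(tapply(records$daily_yield_kg, key, stats::var)[akey])
  # single-record classes: sample variance undefined -> no adjustment
  vx[is.na(vx)] <- 0
  vy[is.na(vy)] <- 0
  agg$rho <- exp(0.5 * (vy / agg$ybar^2 - model$b * vx / agg$xbar^2))
  alpha <- ifelse(agg$session == "AM", model$alpha_am, model$alpha_pm)
  agg$factor <- agg$rho * agg$xbar^(model$b - 1) *
    exp(alpha + model$beta * agg$midpoint_h)
  factor_table(agg[, c("session", "class", "midpoint_h", "factor", "n", "rho")],
               kind = "multiplicative", smoothing = "model_derived",
               model_id = "M7B", scheme = scheme)
}

#' Exponential-growth reparameterization of the exponential model
#'
#' The prediction `y = x^b exp(t*)`, with the time function
#' `t* = alpha_j + beta t`, can be rewritten as the exponential growth form
#' `y = x^b (1 + r)^(t*)` with initial value `x^b` and rate constant
#' `r = e - 1 = 1.718` (to 3 decimals).
#'
#' @param model A fitted [fit_exp_model()].
#' @return A list of class `"exp_growth_form"`: `rate` (`e - 1` rounded to
#'   3 decimals), `rate_exact`, `b`, `alpha_am`, `alpha_pm`, `beta`, and
#'   `tstar(t, session)`, the fitted time function.
#' @examples
#' \dontrun{growth_rate_form(fit)$rate  # 1.718 for any fit}
#' @export
growth_rate_form <- function(model) {
  stopifnot(inherits(model, "exp_model"))
  alpha_am <- model$alpha_am
  alpha_pm <- model$alpha_pm
  beta <- model$beta
  list(
    rate = round(exp(1) - 1, 3),
    rate_exact = exp(1) - 1,
    b = model$b,
    alpha_am = alpha_am, alpha_pm = alpha_pm, beta = beta,
    tstar = function(t, session = "AM") {
      ifelse(session == "AM", alpha_am, alpha_pm) + beta * t
    }
  )
}
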