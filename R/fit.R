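#' Fit a daily-yield estimation model
#'
#' Unified front-end to the whole family of AM-PM daily-yield estimators.
#' Every method consumes the same milking-record table and returns a fitted
#' object with `predict()`, `coef()`, `summary()`, `residuals()` and
#' `plot()` methods, so the methods can be benchmarked interchangeably.
#'
#' Methods:
#' \describe{
#'   \item{M0}{Doubling: `y-hat = 2x`. No parameters.}
#'   \item{M1}{Empirical paired-difference ACF table per interval class.}
#'   \item{M2A}{Factorial ACF model (`b = 2`), raw class effects.}
#'   \item{M2B}{Factorial ACF model, class effects smoothed linearly on the
#'     class midpoints.}
#'   \item{M3A}{Linear regression `y = alpha_j + beta t + b x`, predicting
#'     at the continuous interval.}
#'   \item{M3B}{The M3A fit discretized into an ACF table at class
#'     midpoints; prediction uses `b-hat`.}
#'   \item{M4}{Bulk-ratio MCF, smoothed by the quadratic PM-portion
#'     regression (set `smooth = FALSE` for the raw ratio-of-sums table).}
#'   \item{M5}{Per-class regression-through-origin MCF with linear
#'     reciprocal smoothing (`smooth = FALSE` for raw factors).}
#'   \item{M6A}{Proportion regression `x/y = alpha_j + beta t`, predicting
#'     `x/p(t)` at the continuous interval.}
#'   \item{M6B}{The M6A fit discretized into an MCF table at class
#'     midpoints.}
#'   \item{M7A}{Exponential regression `log y = alpha_j + beta t + b log x`,
#'     predicting at the continuous interval.}
#'   \item{M7B}{The M7A fit converted to class-wise MCF with the
#'     second-order Taylor moment correction.}
#' }
#'
#' @param records A milking-record table (see [as_milking_records()]).
#' @param method One of `"M0"`, `"M1"`, `"M2A"`, `"M2B"`, `"M3A"`, `"M3B"`,
#'   `"M4"`, `"M5"`, `"M6A"`, `"M6B"`, `"M7A"`, `"M7B"`.
#' @param scheme A [micl_scheme()]; used by the table-based methods.
#' @param smooth For M4/M5: use the smoothed factor table (default `TRUE`,
#'   matching the cited methods; the raw tables are available with
#'   `FALSE`).
#' @param use_dim For M3A/M3B: include the days-in-milk covariate.
#' @param ... Passed to the underlying fitting function.
#' @return An object of class `c("ampm_fit_<kind>", "ampm_fit")` with
#'   elements `method`, `scheme`, `model` (the coefficient model, if any),
#'   `table` (the factor table, if any), `b` (coefficient applied to the
#'   single yield at prediction time, where applicable), `n`, `call`.
#' @examples
#' herd <- simulate_herd(sim_params(n_cows = 200, seed = 1))
#' fit <- fit_daily_yield(herd, "M3A")
#' coef(fit)
#' head(predict(fit, herd))
#' @export
fit_daily_yield <- function(records, method = "M3A", scheme = micl_scheme(),
                            smooth = TRUE, use_dim = FALSE, ...) {
  method <- match.arg(method, c("M0", "M1", "M2A", "M2B", "M3A", "M3B",
                                "M4", "M5", "M6A", "M6B", "M7A", "M7B"))
  records <- as_milking_records(records)
  obj <- list(method = method, scheme = scheme, model = NULL, table = NULL,
              b = NULL, n = nrow(records), call = match.call())
  kind <- switch(method,
    M0 = "doubling",
    M1 = , M2A = , M2B = "acf_table",
    M3A = "lr", M3B = "lr_table",
    M4 = , M5 = "mcf_table",
    M6A = "proportion", M6B = "proportion_table",
    M7A = "exp", M7B = "exp_table")
  if (method == "M1") {
    obj$table <- fit_acf_empirical(records, scheme)
    obj$b <- 2
  } else if (method %in% c("M2A", "M2B")) {
    obj$table <- fit_acf_factorial(records, scheme, smooth = method == "M2B")
    obj$b <- 2
  } else if (method %in% c("M3A", "M3B")) {
    obj$model <- fit_lr(records, use_dim = use_dim, ...)
    obj$b <- obj$model$b
    if (method == "M3B") obj$table <- acf_from_lr(obj$model, scheme, records)
  } else if (method == "M4") {
    obj$table <- if (smooth) smooth_mcf_quadratic(records, scheme, ...) else
      mcf_bulk_ratio(records, scheme)
  } else if (method == "M5") {
    obj$table <- fit_mcf_origin(records, scheme, smooth = smooth, ...)
  } else if (method %in% c("M6A", "M6B")) {
    obj$model <- fit_proportion_lr(records, ...)
    if (method == "M6B") obj$table <- mcf_from_proportion(obj$model, scheme, records)
  } else if (method %in% c("M7A", "M7B")) {
    obj$model <- fit_exp_model(records)
    obj$b <- obj$model$b
    if (method == "M7B") obj$table <- mcf_from_exp(obj$model, records, scheme)
  }
  class(obj) <- c(paste0("ampm_fit_", kind), "ampm_fit")
  obj
}

#' Predict daily yield from a fitted model
#'
#' @param object An [fit_daily_yield()] object.
#' @param newdata A milking-record table (the `daily_yield_kg` column may be
#'   a placeholder equal to `single_yield_kg`; it is not used).
#' @param strict For table-based methods: error on a milking whose interval
#'   class has no table entry (default), or return `NA` for it.
#' @param ... Unused.
#' @return Numeric vector of estimated daily yields, kg, one per row of
#'   `newdata`.
#' @export
predict.ampm_fit <- function(object, newdata, strict = TRUE, ...) {
  nd <- as_milking_records(newdata)
  x <- nd$single_yield_kg
  s <- as.character(nd$session)
  t <- nd$interval_h
  switch(object$method,
    M0 = predict_doubling(x),
    M1 = , M2A = , M2B = predict_acf(x, s, t, object$table, b = 2,
                                     strict = strict),
    M3A = {
      m <- object$model
      alpha <- ifelse(s == "AM", m$alpha_am, m$alpha_pm)
      dimterm <- if (!is.na(m$gamma)) m$gamma * (nd$dim - m$d0) else 0
      alpha + m$beta * t + dimterm + m$b * x
    },
    M3B = predict_acf(x, s, t, object$table, b = object$b, strict = strict),
    M4 = , M5 = predict_mcf(x, s, t, object$table, strict = strict),
    M6A = predict_m6a(object$model, x, s, t),
    M6B = predict_mcf(x, s, t, object$table, strict = strict),
    M7A = predict_exp(object$model, x, s, t),
    M7B = predict_mcf(x, s, t, object$table, strict = strict)
  )
}

#' @export
coef.ampm_fit <- function(object, ...) {
  m <- object$model
  if (is.null(m)) return(NULL)
  if (inherits(m, "lr_model")) {
    c(alpha_am = m$alpha_am, alpha_pm = m$alpha_pm, beta = m$beta,
      gamma = m$gamma, b = m$b)
  } else if (inherits(m, "proportion_model")) {
    c(alpha_am = m$alpha_am, alpha_pm = m$alpha_pm, beta = m$beta)
  } else {
    c(alpha_am = m$alpha_am, alpha_pm = m$alpha_pm, beta = m$beta, b = m$b)
  }
}

#' @export
print.ampm_fit <- function(x, ...) {
  desc <- switch(x$method,
    M0 = "doubling estimator",
    M1 = "empirical paired-difference ACF",
    M2A = "factorial ACF (raw class effects)",
    M2B = "factorial ACF (smoothed class effects)",
    M3A = "linear regression (continuous interval)",
    M3B = "linear regression, discretized ACF table",
    M4 = "bulk-ratio MCF",
    M5 = "regression-through-origin MCF",
    M6A = "proportion regression (continuous interval)",
    M6B = "proportion regression, discretized MCF table",
    M7A = "exponential regression (continuous interval)",
    M7B = "exponential regression, discretized MCF table")
  cat(sprintf("Daily-yield model %s: %s (n = %d milkings)\n",
              x$method, desc, x$n))
  cf <- coef(x)
  if (!is.null(cf)) print(round(cf[!is.na(cf)], 4))
  if (!is.null(x$table)) {
    cat(sprintf("Factor table: %d entries (%s, smoothing %s)\n",
                nrow(x$table), x$table$kind[1], x$table$smoothing[1]))
  }
  invisible(x)
}

#' @export
summary.ampm_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$model) && !is.null(object$model$se)) {
    cat("Coefficient SDs:\n")
    print(round(object$model$se, 4))
  }
  if (!is.null(object$table)) print(object$table)
  invisible(object)
}

#' @export
residuals.ampm_fit <- function(object, records, ...) {
  if (missing(records)) {
    stop("residuals.ampm_fit: supply the records to evaluate against",
         call. = FALSE)
  }
  nd <- as_milking_records(records)
  nd$daily_yield_kg - predict(object, nd)
}

#' Plot factor curves of a fitted model
#'
#' Draws factor versus class midpoint per session for a table-based fit
#' (the style of correction-factor comparison plots).
#'
#' @param x An [fit_daily_yield()] object with a factor table.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ampm_fit <- function(x, ...) {
  if (is.null(x$table)) {
    stop("plot.ampm_fit: method ", x$method, " has no factor table", call. = FALSE)
  }
  tab <- x$table
  am <- tab[tab$session == "AM", ]
  pm <- tab[tab$session == "PM", ]
  ylab <- if (tab$kind[1] == "additive") "ACF (kg)" else "MCF"
  graphics::plot(am$midpoint_h, am$factor, type = "b", pch = 16,
                 xlim = range(tab$midpoint_h), ylim = range(tab$factor),
                 xlab = "class midpoint (h)", ylab = ylab,
                 main = paste("Correction factors,", x$method), ...)
  graphics::lines(pm$midpoint_h, pm$factor, type = "b", pch = 1, lty = 2)
  graphics::legend("topright", legend = c("AM", "PM"), pch = c(16, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Serialize a fitted coefficient model to a flat key-value file
#'
#' Coefficient-based fits (M3A/M6A/M7A and the models behind their table
#' variants) round-trip through a plain `key = value` text file at full
#' precision.
#'
#' @param object An [fit_daily_yield()] object with a coefficient model.
#' @param path File path.
#' @return `write_ampm_model()` returns `path` invisibly;
#'   `read_ampm_model()` returns a named numeric vector of coefficients
#'   with the method id as attribute.
#' @export
write_ampm_model <- function(object, path) {
  stopifnot(inherits(object, "ampm_fit"))
  cf <- coef(object)
  if (is.null(cf)) {
    stop("write_ampm_model: method ", object$method,
         " has no coefficient model; write its factor table instead",
         call. = FALSE)
  }
  lines <- c(
    paste("method =", object$method),
    paste("n =", object$n),
    sprintf("%s = %.17g", names(cf)[!is.na(cf)], cf[!is.na(cf)])
  )
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_ampm_model
#' @export
read_ampm_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  num <- suppressWarnings(as.numeric(vals))
  cf <- num[!is.na(num) & keys != "n"]
  names(cf) <- keys[!is.na(num) & keys != "n"]
  attr(cf, "method") <- vals[keys == "method"]
  attr(cf, "n") <- as.integer(num[keys == "n"])
  cf
}
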