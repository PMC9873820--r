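#' Repeated k-fold cross-validation of daily-yield models
#'
#' Partitions cow-days (both session rows of a cow-day stay together, so no
#' daily yield leaks between training and test) into `n_folds` folds,
#' refits every requested method on the training folds, and predicts the
#' held-out milkings from their single yields -- both the AM-based and the
#' PM-based estimate of each cow-day. The fold assignment is re-randomized
#' in each of the `n_reps` replicates; everything is deterministic given
#' `seed`.
#'
#' @param records A milking-record table.
#' @param methods Character vector of method ids (see [fit_daily_yield()]).
#' @param scheme A [micl_scheme()].
#' @param n_folds Number of folds, >= 2. Default 10.
#' @param n_reps Number of replicates. Default 30.
#' @param seed Integer seed. Default 1.
#' @param smooth Passed to [fit_daily_yield()] for M4/M5.
#' @return A data frame of class `"prediction_set"`: `replicate`, `fold`,
#'   `cow_id`, `session`, `model`, `y_true`, `y_hat`. A model that fails to
#'   fit on a training split, or a test milking without a factor-table
#'   entry, yields `NA` in `y_hat`; the attribute `"failures"` records the
#'   reasons.
#' @export
crossvalidate <- function(records, methods = c("M0", "M1", "M2A", "M2B",
                                               "M3A", "M3B", "M4", "M5",
                                               "M6A", "M6B", "M7A", "M7B"),
                          scheme = micl_scheme(), n_folds = 10, n_reps = 30,
                          seed = 1, smooth = TRUE) {
  stopifnot(n_folds >= 2, n_reps >= 1)
  records <- as_milking_records(records)
  cows <- unique(records$cow_id)
  n_cows <- length(cows)
  if (n_cows < n_folds) stop("crossvalidate: fewer cow-days than folds", call. = FALSE)
  set.seed(as.integer(seed))
  row_cow <- match(records$cow_id, cows)
  out <- vector("list", n_reps * n_folds * length(methods))
  failures <- list()
  pos <- 0L
  for (r in seq_len(n_reps)) {
    fold_of_cow <- sample(rep_len(seq_len(n_folds), n_cows))
    fold_of_row <- fold_of_cow[row_cow]
    for (f in seq_len(n_folds)) {
      train <- records[fold_of_row != f, ]
      test <- records[fold_of_row == f, ]
      for (m in methods) {
        pos <- pos + 1L
        y_hat <- rep(NA_real_, nrow(test))
        fit <- tryCatch(
          fit_daily_yield(train, m, scheme = scheme, smooth = smooth),
          error = function(e) e)
        if (inherits(fit, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            replicate = r, fold = f, model = m,
            reason = conditionMessage(fit))
        } else {
          y_hat <- tryCatch(
            predict(fit, test, strict = FALSE),
            error = function(e) {
              failures[[length(failures) + 1L]] <<- data.frame(
                replicate = r, fold = f, model = m,
                reason = conditionMessage(e))
              rep(NA_real_, nrow(test))
            })
        }
        out[[pos]] <- data.frame(
          replicate = r, fold = f,
          cow_id = test$cow_id, session = as.character(test$session),
          model = m, y_true = test$daily_yield_kg, y_hat = y_hat
        )
      }
    }
  }
  preds <- do.call(rbind, out)
  rownames(preds) <- NULL
  attr(preds, "failures") <- if (length(failures)) do.call(rbind, failures) else
    data.frame(replicate = integer(), fold = integer(), model = character(),
               reason = character())
  attr(preds, "n_folds") <- n_folds
  attr(preds, "n_reps") <- n_reps
  class(preds) <- c("prediction_set", class(preds))
  preds
}

#' Bias-variance decomposition of cross-validated estimates
#'
#' For each animal-session and model, across replicates: the bias is the
#' mean estimation error `mean(y_hat - y)`, the variance is the
#' (population) variance of `y_hat` over replicates, and the mean squared
#' error is their sum `variance + bias^2` -- an exact decomposition because
#' an animal's true daily yield is constant across replicates. Aggregates
#' are means over animal-sessions.
#'
#' @param preds A [crossvalidate()] prediction set.
#' @return A list with `per_animal` (model, cow_id, session, variance,
#'   bias2, mse, n_reps) and `aggregate` (model, variance, bias2, mse).
#' @export
decompose_mse <- function(preds) {
  p <- preds[!is.na(preds$y_hat), ]
  if (max(p$replicate) < 2) {
    warning("decompose_mse: single replicate; variances reported as 0")
  }
  key <- paste(p$model, p$cow_id, p$session, sep = "\r")
  idx <- !duplicated(key)
  mean_hat <- tapply(p$y_hat, key, mean)
  mean_sq <- tapply(p$y_hat^2, key, mean)
  kk <- key[idx]
  per <- data.frame(
    model = p$model[idx], cow_id = p$cow_id[idx],
    session = p$session[idx],
    variance = pmax(as.vector(mean_sq[kk] - mean_hat[kk]^2), 0),
    bias = as.vector(mean_hat[kk]) - p$y_true[idx],
    n_reps = as.vector(table(key)[kk])
  )
  per$bias2 <- per$bias^2
  per$mse <- per$variance + per$bias2
  agg_by <- function(v) as.vector(tapply(v, per$model, mean))
  aggregate <- data.frame(
    model = sort(unique(per$model)),
    variance = agg_by(per$variance),
    bias2 = agg_by(per$bias2),
    mse = agg_by(per$mse)
  )
  list(per_animal = per[order(per$model, per$cow_id, per$session),
                        c("model", "cow_id", "session", "variance",
                          "bias2", "mse", "n_reps")],
       aggregate = aggregate)
}

#' Predictive R-squared accuracy of cross-validated estimates
#'
#' Per replicate: `R^2 = 1 - SSE/SST` over the replicate's held-out
#' predictions, with `SST` about the replicate's mean true yield. Per
#' animal-session: `R^2_i = 1 - mean_r((y_hat - y_i)^2) / Var(y)`, with the
#' population variance of the true daily yields as denominator (an
#' animal's own yield is constant across replicates, so a within-animal
#' total sum of squares does not exist). Means and min-max ranges of both
#' are reported per model.
#'
#' @param preds A [crossvalidate()] prediction set.
#' @return A list with `per_replicate` (model, replicate, r2), `per_animal`
#'   (model, cow_id, session, r2) and `summary` (model, mean/min/max of
#'   both accuracies).
#' @export
r2_accuracy <- function(preds) {
  p <- preds[!is.na(preds$y_hat), ]
  if (stats::var(p$y_true) == 0) {
    stop("r2_accuracy: true daily yields are constant", call. = FALSE)
  }
  err2 <- (p$y_true - p$y_hat)^2
  keyr <- paste(p$model, p$replicate, sep = "\r")
  sse <- tapply(err2, keyr, sum)
  sst <- tapply(p$y_true, keyr, function(y) sum((y - mean(y))^2))
  idr <- !duplicated(keyr)
  per_rep <- data.frame(
    model = p$model[idr], replicate = p$replicate[idr],
    r2 = as.vector(1 - sse[keyr[idr]] / sst[keyr[idr]])
  )
  # population variance of true daily yield over animals (one value per cow)
  first <- !duplicated(p$cow_id)
  vy <- stats::var(p$y_true[first]) * (sum(first) - 1) / sum(first)
  keya <- paste(p$model, p$cow_id, p$session, sep = "\r")
  msea <- tapply(err2, keya, mean)
  ida <- !duplicated(keya)
  per_animal <- data.frame(
    model = p$model[ida], cow_id = p$cow_id[ida], session = p$session[ida],
    r2 = as.vector(1 - msea[keya[ida]] / vy)
  )
  models <- sort(unique(p$model))
  sm <- data.frame(
    model = models,
    acc_rep_mean = as.vector(tapply(per_rep$r2, per_rep$model, mean)[models]),
    acc_rep_min = as.vector(tapply(per_rep$r2, per_rep$model, min)[models]),
    acc_rep_max = as.vector(tapply(per_rep$r2, per_rep$model, max)[models]),
    acc_animal_mean = as.vector(tapply(per_animal$r2, per_animal$model, mean)[models]),
    acc_animal_min = as.vector(tapply(per_animal$r2, per_animal$model, min)[models]),
    acc_animal_max = as.vector(tapply(per_animal$r2, per_animal$model, max)[models])
  )
  list(per_replicate = per_rep, per_animal = per_animal, summary = sm)
}

#' Benchmark report of cross-validated models
#'
#' Combines [decompose_mse()] and [r2_accuracy()] into one row per model:
#' variance, squared bias and MSE (averages over animal-sessions), and the
#' mean and range of the per-replicate and per-animal predictive
#' accuracies.
#'
#' @param preds A [crossvalidate()] prediction set.
#' @return A data frame with one row per model.
#' @export
eval_report <- function(preds) {
  dec <- decompose_mse(preds)$aggregate
  acc <- r2_accuracy(preds)$summary
  merge(dec, acc, by = "model")
}

#' Actual-on-estimated regression
#'
#' Regresses the true daily yield on the estimated daily yield per session
#' and reports intercept, slope and the correlation coefficient. An
#' unbiased estimator gives intercept 0 and slope 1; the correlation is
#' invariant to affine rescaling of the estimates and therefore blind to
#' bias, which is why it is not by itself an accuracy measure.
#'
#' @param preds A [crossvalidate()] prediction set (or any data frame with
#'   `model`, `session`, `y_true`, `y_hat`).
#' @param model Model id to evaluate.
#' @param session `"AM"` or `"PM"`.
#' @return A named numeric vector `intercept`, `slope`, `correlation`.
#' @export
regress_actual_on_estimated <- function(preds, model, session = "AM") {
  p <- preds[preds$model == model & preds$session == session &
               !is.na(preds$y_hat), ]
  if (nrow(p) < 3) stop("regress_actual_on_estimated: need >= 3 predictions",
                        call. = FALSE)
  if (stats::var(p$y_hat) == 0) {
    stop("regress_actual_on_estimated: degenerate estimates", call. = FALSE)
  }
  fit <- stats::lm(y_true ~ y_hat, data = p)
  c(intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    correlation = stats::cor(p$y_true, p$y_hat))
}

#' Discretization bias of class-midpoint factor tables
#'
#' A continuous regression evaluated at class midpoints ignores the
#' within-class interval deviation. For the linear model the ignored term
#' is additive, `beta (t - tbar_class)`; for the exponential model it is
#' the multiplicative factor `exp(beta (t - tbar_class))`. Per record this
#' is exactly the difference (or ratio) between the continuous prediction
#' and its discretized counterpart.
#'
#' @param model A fitted [fit_lr()] or [fit_exp_model()] (or an
#'   [fit_daily_yield()] object wrapping one).
#' @param scheme The [micl_scheme()] of the discretized counterpart.
#' @param records Milking records to evaluate at (also supply the edge-class
#'   empirical midpoints).
#' @return A list with `per_record` (session, class, t, tbar, bias -- the
#'   additive term, or the multiplicative factor for the exponential model)
#'   and `per_class` (session, class, mean absolute additive bias or mean
#'   absolute log of the multiplicative bias).
#' @export
discretization_bias <- function(model, scheme, records) {
  if (inherits(model, "ampm_fit")) model <- model$model
  stopifnot(inherits(model, "lr_model") || inherits(model, "exp_model"))
  records <- as_milking_records(records)
  t <- records$interval_h
  k <- assign_micl(t, scheme)
  tbar <- micl_midpoint(scheme, k)
  # edge-class midpoints are per-session empirical means, matching the
  # midpoints the factor-table builders use
  for (s in c("AM", "PM")) {
    for (kk in c(0L, scheme$K + 1L)) {
      sel <- records$session == s & k == kk
      if (any(sel)) tbar[sel] <- mean(t[sel])
    }
  }
  dev <- model$beta * (t - tbar)
  multiplicative <- inherits(model, "exp_model")
  per_record <- data.frame(
    session = as.character(records$session), class = k, t = t, tbar = tbar,
    bias = if (multiplicative) exp(dev) else dev
  )
  absdev <- abs(dev)
  key <- paste(per_record$session, k)
  idx <- !duplicated(key)
  per_class <- data.frame(
    session = per_record$session[idx], class = k[idx],
    mean_abs_bias = as.vector(tapply(absdev, key, mean)[key[idx]])
  )
  list(per_record = per_record,
       per_class = per_class[order(per_class$session, per_class$class), ],
       multiplicative = multiplicative)
}

#' Contrast two additive correction-factor tables
#'
#' Averages the per-class factor difference `Delta_a - Delta_b` over
#' sessions and interior classes, reports the per-class AM+PM factor sums
#' of each table, and (when records and a fitted `b` are supplied)
#' evaluates the closed-form counterparts: the mean difference between a
#' free-`b` regression table and a `b = 2` table is approximately
#' `(2 - b) * xbar` and the per-class factor sum of the regression table is
#' `(2 - b) * ybar(k)`, with `xbar`/`ybar` the grand means of the class
#' means of single and daily yield.
#'
#' @param table_a,table_b Additive [factor_table()]s on the same scheme
#'   (e.g. M3B and M2B).
#' @param records Optional milking records for the closed forms.
#' @param b Optional fitted regression coefficient on the single yield
#'   (defaults to the `"b"` attribute of `table_a` if present).
#' @return A list: `mean_diff` (mean of `Delta_a - Delta_b` over sessions
#'   and interior classes), `per_class` (session, class, midpoint,
#'   `factor_a`, `factor_b`, `diff`), `pair_sums` (per mirror-class pair:
#'   `sum_a`, `sum_b` of AM + PM factors), and with records/b:
#'   `closed_form_mean_diff` (`(2 - b) xbar`) and `closed_form_pair_sum`
#'   (`(2 - b) ybar`).
#' @export
acf_table_contrast <- function(table_a, table_b, records = NULL, b = NULL) {
  stopifnot(inherits(table_a, "factor_table"), inherits(table_b, "factor_table"),
            table_a$kind[1] == "additive", table_b$kind[1] == "additive")
  sa <- attr(table_a, "scheme")
  sb <- attr(table_b, "scheme")
  if (!isTRUE(all.equal(sa[c("lo", "hi", "width")], sb[c("lo", "hi", "width")]))) {
    stop("acf_table_contrast: tables use different MICL schemes", call. = FALSE)
  }
  if (is.null(b)) b <- attr(table_a, "b")
  interior_a <- table_a[table_a$class >= 1 & table_a$class <= sa$K, ]
  interior_b <- table_b[table_b$class >= 1 & table_b$class <= sa$K, ]
  m <- merge(interior_a[, c("session", "class", "midpoint_h", "factor")],
             interior_b[, c("session", "class", "factor")],
             by = c("session", "class"), suffixes = c("_a", "_b"))
  m$diff <- m$factor_a - m$factor_b
  names(m)[names(m) == "factor_a"] <- "factor_a"
  pair_sum <- function(tab) {
    am <- tab[tab$session == "AM", ]
    pm <- tab[tab$session == "PM", ]
    pm_mirror <- pm$factor[match(micl_mirror(am$class, sa), pm$class)]
    data.frame(class_am = am$class, sum = am$factor + pm_mirror)
  }
  ps_a <- pair_sum(interior_a)
  ps_b <- pair_sum(interior_b)
  out <- list(
    mean_diff = mean(m$diff),
    per_class = m[order(m$session, m$class), ],
    pair_sums = data.frame(class_am = ps_a$class_am, sum_a = ps_a$sum,
                           sum_b = ps_b$sum[match(ps_a$class_am, ps_b$class_am)])
  )
  if (!is.null(records) && !is.null(b)) {
    records <- as_milking_records(records)
    cm <- class_aggregate(records$session, records$interval_h, sa,
                          values = list(x = records$single_yield_kg,
                                        y = records$daily_yield_kg))
    cm <- cm[cm$class >= 1 & cm$class <= sa$K, ]
    out$xbar_classes <- mean(cm$x)
    out$ybar_classes <- mean(cm$y)
    out$closed_form_mean_diff <- (2 - b) * out$xbar_classes
    out$closed_form_pair_sum <- (2 - b) * out$ybar_classes
    out$b <- b
  }
  out
}

#' Closed-form ACF contrast
#'
#' The analytic counterpart of [acf_table_contrast()]: with a fitted
#' coefficient `b` on the single-milking yield and a grand mean `m` of the
#' class means (of single yield for the mean table difference, of daily
#' yield for the per-class AM+PM factor sum), the contrast is
#' `(2 - b) * m`.
#'
#' @param b Fitted regression coefficient on the single yield.
#' @param m Grand mean yield, kg.
#' @return `(2 - b) * m`, kg.
#' @examples
#' acf_contrast_closed_form(1.942, 12.05)  # ~0.699
#' acf_contrast_closed_form(1.942, 24.10)  # ~1.398
#' @export
acf_contrast_closed_form <- function(b, m) {
  (2 - b) * m
}
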