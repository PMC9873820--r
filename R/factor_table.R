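#' Correction-factor tables
#'
#' A factor table holds one additive (`Delta`, kg) or multiplicative
#' (`F`, dimensionless, > 1) correction factor per (session, MICL class),
#' together with the class record count, the class midpoint used, the
#' smoothing that produced it and the model id. Tables are plain data frames
#' of class `"factor_table"` with columns `kind`, `session`, `class`,
#' `class_lo`, `class_hi`, `midpoint_h`, `factor`, `n`, `smoothing`,
#' `model_id` (plus `rho` for tables carrying the Taylor moment correction).
#'
#' @param df Data frame with at least `session`, `class`, `midpoint_h`,
#'   `factor`, `n`.
#' @param kind `"additive"` or `"multiplicative"`.
#' @param smoothing One of `"none"`, `"linear"`, `"linear_reciprocal"`,
#'   `"quadratic_portion"`, `"model_derived"`.
#' @param model_id Identifier of the producing model (e.g. `"M1"`).
#' @param scheme The [micl_scheme()] the classes refer to.
#' @return A `factor_table` data frame; the scheme is attached as the
#'   `"scheme"` attribute.
#' @export
factor_table <- function(df, kind, smoothing, model_id, scheme) {
  kind <- match.arg(kind, c("additive", "multiplicative"))
  smoothing <- match.arg(
    smoothing,
    c("none", "linear", "linear_reciprocal", "quadratic_portion", "model_derived"))
  stopifnot(all(c("session", "class", "midpoint_h", "factor", "n") %in% names(df)))
  if (kind == "multiplicative" && any(df$factor <= 1)) {
    stop("factor_table: multiplicative factors must exceed 1 ",
         "(daily yield exceeds any single milking)", call. = FALSE)
  }
  b <- micl_bounds(scheme, df$class)
  out <- data.frame(
    kind = kind,
    session = as.character(df$session),
    class = as.integer(df$class),
    class_lo = b[, "lo"],
    class_hi = b[, "hi"],
    midpoint_h = df$midpoint_h,
    factor = df$factor,
    n = as.integer(df$n),
    smoothing = smoothing,
    model_id = model_id
  )
  if ("rho" %in% names(df)) out$rho <- df$rho
  out <- out[order(out$session, out$class), ]
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  class(out) <- c("factor_table", class(out))
  out
}

#' @export
print.factor_table <- function(x, ...) {
  cat(sprintf("%s correction-factor table (%s, smoothing: %s)\n",
              x$kind[1], x$model_id[1], x$smoothing[1]))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Look up factors for new milkings
#'
#' @param table A [factor_table()].
#' @param session Character vector, `"AM"`/`"PM"`.
#' @param t Milking intervals, hours.
#' @param strict If `TRUE` (default), a milking whose (session, class) has
#'   no table entry raises an error naming it; if `FALSE`, its factor is
#'   `NA` (used by cross-validation to record missing predictions).
#' @return Numeric vector of factors.
#' @keywords internal
lookup_factor <- function(table, session, t, strict = TRUE) {
  scheme <- attr(table, "scheme")
  k <- assign_micl(t, scheme)
  idx <- match(paste(session, k), paste(table$session, table$class))
  if (strict && anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop(sprintf(
      "no factor-table entry for session %s, class %d (interval %.2f h)",
      session[miss], k[miss], t[miss]), call. = FALSE)
  }
  table$factor[idx]
}

#' Predict daily yield with an additive correction factor table
#'
#' Daily yield is estimated as `Delta_j(k) + b * x`: the class factor plus
#' `b` times the single-milking yield (`b = 2` for the classical ACF
#' methods, `b = b-hat` for regression-derived tables).
#'
#' @param x Single-milking yields, kg.
#' @param session `"AM"`/`"PM"` per milking.
#' @param t Milking intervals, hours.
#' @param table An additive [factor_table()].
#' @param b Regression coefficient on the single yield. Default 2.
#' @param strict See [lookup_factor()].
#' @return Estimated daily yields, kg.
#' @export
predict_acf <- function(x, session, t, table, b = 2, strict = TRUE) {
  stopifnot(inherits(table, "factor_table"), table$kind[1] == "additive")
  lookup_factor(table, session, t, strict = strict) + b * x
}

#' Predict daily yield with a multiplicative correction-factor table
#'
#' Daily yield is estimated as `F_j(k) * x`.
#'
#' @inheritParams predict_acf
#' @param table A multiplicative [factor_table()].
#' @return Estimated daily yields, kg.
#' @export
predict_mcf <- function(x, session, t, table, strict = TRUE) {
  stopifnot(inherits(table, "factor_table"), table$kind[1] == "multiplicative")
  lookup_factor(table, session, t, strict = strict) * x
}

#' Complement of a multiplicative correction factor
#'
#' Because the AM and PM proportions of a daily yield sum to one, the bulk
#' AM and PM factors of a class pair satisfy `1/F_AM + 1/F_PM = 1`, so one
#' factor determines the other: `F -> F / (F - 1)`. The map is an involution
#' on (1, Inf) with fixed point 2.
#'
#' @param F Multiplicative factor(s), each > 1.
#' @return The complementary factor(s).
#' @examples
#' complement_mcf(2.182)               # 1.846...
#' complement_mcf(complement_mcf(1.7)) # 1.7
#' @export
complement_mcf <- function(F) {
  if (any(F <= 1)) {
    stop("complement_mcf: factors must exceed 1", call. = FALSE)
  }
  F / (F - 1)
}

#' Read and write factor tables
#'
#' CSV schema: `kind`, `session`, `class`, `class_lo`, `class_hi`,
#' `midpoint_h`, `factor`, `n`, `smoothing`, `model_id` (optional `rho`).
#' Reads validate the schema and reject non-positive multiplicative factors;
#' writes are atomic. The MICL scheme is reconstructed from the interior
#' class bounds.
#'
#' @param path File path.
#' @param table A [factor_table()].
#' @return `read_factor_table()` returns a `factor_table`;
#'   `write_factor_table()` returns `path` invisibly.
#' @export
read_factor_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("kind", "session", "class", "class_lo", "class_hi",
                "midpoint_h", "factor", "n", "smoothing", "model_id")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("factor table file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (x$kind[1] == "multiplicative" && any(x$factor <= 1)) {
    stop("factor table file: multiplicative factors must exceed 1", call. = FALSE)
  }
  interior <- x[x$class_lo > 0 & x$class_hi < 24, ]
  if (!nrow(interior)) stop("factor table file: no interior classes", call. = FALSE)
  width <- stats::median(interior$class_hi - interior$class_lo)
  # any interior row pins the scheme origin: class_lo = lo + (class - 1) * width
  lo <- interior$class_lo[1] - (interior$class[1] - 1) * width
  K <- max(c(interior$class, round((max(interior$class_hi) - lo) / width)))
  scheme <- micl_scheme(lo, lo + K * width, width)
  factor_table(x, kind = x$kind[1], smoothing = x$smoothing[1],
               model_id = x$model_id[1], scheme = scheme)
}

#' @rdname read_factor_table
#' @export
write_factor_table <- function(table, path) {
  stopifnot(inherits(table, "factor_table"))
  atomic_write_csv(as.data.frame(table), path)
  invisible(path)
}

# per (session, class) aggregation helper used by the table builders:
# returns a data frame with one row per observed (session, class)
class_aggregate <- function(session, t, scheme, values) {
  k <- assign_micl(t, scheme)
  key <- paste(session, k)
  ukey <- !duplicated(key)
  out <- data.frame(session = as.character(session)[ukey], class = k[ukey],
                    key = key[ukey])
  out$n <- as.integer(table(key)[out$key])
  out$midpoint_h <- micl_midpoint(scheme, out$class, t = t)
  # edge midpoints must be per-session empirical means of members
  for (s in c("AM", "PM")) {
    for (kk in c(0L, scheme$K + 1L)) {
      sel <- out$session == s & out$class == kk
      if (any(sel)) out$midpoint_h[sel] <- mean(t[session == s & k == kk])
    }
  }
  for (nm in names(values)) {
    out[[nm]] <- as.vector(tapply(values[[nm]], key, mean)[out$key])
  }
  out$key <- NULL
  out[order(out$session, out$class), ]
}
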