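#' Milking records
#'
#' A milking-record table has one row per cow x milking session:
#' `cow_id` (identifier), `session` (`"AM"` or `"PM"`), `interval_h` (hours
#' since the previous milking), `single_yield_kg` (yield of that milking),
#' `daily_yield_kg` (total test-day yield, stored redundantly on both session
#' rows of a cow-day), and optionally `dim` (days in milk).
#'
#' `as_milking_records()` validates a data frame against this schema and the
#' domain invariants (intervals in (0, 24), positive single yields, daily
#' yield at least the single yield).
#'
#' @param x A data frame with the columns above (`dim` optional).
#' @return `x`, with `session` normalized to a factor with levels AM, PM and
#'   class `"milking_records"` prepended.
#' @examples
#' rec <- data.frame(
#'   cow_id = c(1, 1), session = c("AM", "PM"),
#'   interval_h = c(11, 13), single_yield_kg = c(10, 12),
#'   daily_yield_kg = c(22, 22)
#' )
#' as_milking_records(rec)
#' @export
as_milking_records <- function(x) {
  required <- c("cow_id", "session", "interval_h", "single_yield_kg",
                "daily_yield_kg")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("milking records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x)
  if (!all(as.character(x$session) %in% c("AM", "PM"))) {
    stop("milking records: 'session' must be \"AM\" or \"PM\"", call. = FALSE)
  }
  x$session <- factor(as.character(x$session), levels = c("AM", "PM"))
  for (col in c("interval_h", "single_yield_kg", "daily_yield_kg")) {
    if (!is.numeric(x[[col]])) {
      stop("milking records: column '", col, "' must be numeric", call. = FALSE)
    }
  }
  bad <- which(!is.finite(x$interval_h) | x$interval_h <= 0 | x$interval_h >= 24)
  if (length(bad)) {
    stop("milking records: interval_h outside (0, 24) in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(x$single_yield_kg) | x$single_yield_kg <= 0)
  if (length(bad)) {
    stop("milking records: non-positive single_yield_kg in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(x$daily_yield_kg < x$single_yield_kg - 1e-9)
  if (length(bad)) {
    stop("milking records: daily_yield_kg below single_yield_kg in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!"dim" %in% names(x)) x$dim <- rep(NA_real_, nrow(x))
  if (!inherits(x, "milking_records")) {
    class(x) <- c("milking_records", class(x))
  }
  x
}

#' Pair AM and PM records of a cow-day and flag inconsistencies
#'
#' Joint analyses of AM and PM records, and all factor tables built from
#' pairs, require each cow-day to contribute exactly one AM and one PM row
#' whose single yields add up to the daily yield and whose intervals add up
#' to 24 h. `validate_pairs()` builds the paired cow-day table and lists
#' every violation; violations are reported, not fatal, because real
#' recording data can break the interval identity.
#'
#' @param records A milking-record table (see [as_milking_records()]).
#' @param tol_yield Absolute tolerance on `x_AM + x_PM = y`, kg. Default 1e-6.
#' @param tol_interval Absolute tolerance on `t_AM + t_PM = 24`, hours.
#'   Default 1e-9.
#' @return A list with `pairs` (one row per valid cow-day: `cow_id`, `t_am`,
#'   `t_pm`, `x_am`, `x_pm`, `y`, `dim`) and `issues` (data frame of
#'   `cow_id`, `issue` for orphan sessions, duplicated sessions, additivity
#'   and interval violations).
#' @export
validate_pairs <- function(records, tol_yield = 1e-6, tol_interval = 1e-9) {
  records <- as_milking_records(records)
  if (nrow(records) == 0) {
    warning("validate_pairs: empty record table")
    return(list(
      pairs = data.frame(cow_id = character(), t_am = numeric(),
                         t_pm = numeric(), x_am = numeric(), x_pm = numeric(),
                         y = numeric(), dim = numeric()),
      issues = data.frame(cow_id = character(), issue = character())
    ))
  }
  am <- records[records$session == "AM", ]
  pm <- records[records$session == "PM", ]
  issues <- list()
  dup_am <- unique(am$cow_id[duplicated(am$cow_id)])
  dup_pm <- unique(pm$cow_id[duplicated(pm$cow_id)])
  for (id in union(dup_am, dup_pm)) {
    issues[[length(issues) + 1L]] <- data.frame(
      cow_id = id, issue = "duplicated session rows for cow-day")
  }
  dup <- union(dup_am, dup_pm)
  am <- am[!am$cow_id %in% dup, ]
  pm <- pm[!pm$cow_id %in% dup, ]
  orphan <- c(setdiff(am$cow_id, pm$cow_id), setdiff(pm$cow_id, am$cow_id))
  for (id in orphan) {
    issues[[length(issues) + 1L]] <- data.frame(
      cow_id = id, issue = "orphan session (missing AM or PM row)")
  }
  both <- intersect(am$cow_id, pm$cow_id)
  am <- am[match(both, am$cow_id), ]
  pm <- pm[match(both, pm$cow_id), ]
  pairs <- data.frame(
    cow_id = both,
    t_am = am$interval_h, t_pm = pm$interval_h,
    x_am = am$single_yield_kg, x_pm = pm$single_yield_kg,
    y = am$daily_yield_kg, dim = am$dim
  )
  bad_y <- abs(pairs$x_am + pairs$x_pm - pairs$y) > tol_yield |
    abs(pm$daily_yield_kg - am$daily_yield_kg) > tol_yield
  for (id in pairs$cow_id[bad_y]) {
    issues[[length(issues) + 1L]] <- data.frame(
      cow_id = id, issue = "additivity violated (x_AM + x_PM != daily yield)")
  }
  bad_t <- abs(pairs$t_am + pairs$t_pm - 24) > tol_interval
  for (id in pairs$cow_id[bad_t]) {
    issues[[length(issues) + 1L]] <- data.frame(
      cow_id = id, issue = "intervals do not sum to 24 h")
  }
  pairs <- pairs[!bad_y, , drop = FALSE]
  rownames(pairs) <- NULL
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(cow_id = character(), issue = character())
  list(pairs = pairs, issues = issues)
}

#' Read and write milking-record tables
#'
#' Plain CSV with header, UTF-8, "." decimal separator; columns `cow_id`,
#' `session`, `interval_h`, `single_yield_kg`, `daily_yield_kg` and optional
#' `dim`. Reads are schema-validated; writes are atomic (temporary file then
#' rename) and keep full numeric precision.
#'
#' @param path File path.
#' @param records A milking-record table.
#' @return `read_milking_records()` returns a validated `milking_records`
#'   data frame; `write_milking_records()` returns `path` invisibly.
#' @export
read_milking_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_milking_records(x)
}

#' @rdname read_milking_records
#' @export
write_milking_records <- function(records, path) {
  records <- as_milking_records(records)
  atomic_write_csv(as.data.frame(records), path)
  invisible(path)
}

# shared atomic CSV writer: write to a sibling temp file, then rename
atomic_write_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  if (!file.rename(tmp, path)) {
    stop("could not write file: ", path, call. = FALSE)
  }
  invisible(path)
}

# pairs -> long milking_records
pairs_to_records <- function(pairs) {
  as_milking_records(data.frame(
    cow_id = rep(pairs$cow_id, 2L),
    session = rep(c("AM", "PM"), each = nrow(pairs)),
    interval_h = c(pairs$t_am, pairs$t_pm),
    single_yield_kg = c(pairs$x_am, pairs$x_pm),
    daily_yield_kg = rep(pairs$y, 2L),
    dim = rep(pairs$dim, 2L)
  ))
}
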