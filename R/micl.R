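#' Milking-interval class (MICL) scheme
#'
#' Discretizes milking-interval time (hours since the previous milking) into
#' `K` half-open interior classes `[a, a + width)` plus two open edge classes
#' that catch intervals below `lo_h` or at/above `hi_h`. Correction-factor
#' tables are indexed by these classes; interior midpoints are exact
#' (`lo + (k - 0.5) * width`), edge-class midpoints are taken as the empirical
#' mean interval of their members when a table is built.
#'
#' @param lo_h Lower bound of the first interior class, hours. Default 9.
#' @param hi_h Upper bound of the last interior class, hours. Default 15.
#' @param width_h Class width in hours; `(hi_h - lo_h) / width_h` must be an
#'   integer. Default 0.5.
#'
#' @return An object of class `"micl_scheme"`: a list with elements `lo`,
#'   `hi`, `width`, `K` (number of interior classes), `midpoints` (interior
#'   midpoints, hours), and `classes` (integer codes `0:(K + 1)`, where 0 is
#'   the lower edge class and `K + 1` the upper edge class).
#'
#' @details The default range 9--15 h covers nearly all AM (and PM) intervals
#' of twice-daily milked herds; intervals in the short tails are kept, not
#' discarded, by routing them to the edge classes. With a scheme symmetric
#' about 12 h (`lo_h + hi_h == 24`), the AM class of a cow-day and the PM
#' class of the same cow-day are mirror images (see [micl_mirror()]).
#'
#' @examples
#' sch <- micl_scheme(9, 15, 0.5)
#' sch$K          # 12 interior classes
#' sch$midpoints  # 9.25, 9.75, ..., 14.75
#' @export
micl_scheme <- function(lo_h = 9, hi_h = 15, width_h = 0.5) {
  stopifnot(is.numeric(lo_h), is.numeric(hi_h), is.numeric(width_h))
  if (!(lo_h < hi_h)) {
    stop("micl_scheme: 'lo_h' must be smaller than 'hi_h'", call. = FALSE)
  }
  if (width_h <= 0) {
    stop("micl_scheme: 'width_h' must be positive", call. = FALSE)
  }
  k_real <- (hi_h - lo_h) / width_h
  if (abs(k_real - round(k_real)) > 1e-9) {
    stop(sprintf(
      "micl_scheme: (hi_h - lo_h)/width_h = %.6f is not an integer number of classes",
      k_real
    ), call. = FALSE)
  }
  K <- as.integer(round(k_real))
  structure(
    list(
      lo = lo_h, hi = hi_h, width = width_h, K = K,
      midpoints = lo_h + (seq_len(K) - 0.5) * width_h,
      classes = 0:(K + 1L)
    ),
    class = "micl_scheme"
  )
}

#' @export
print.micl_scheme <- function(x, ...) {
  cat(sprintf(
    "MICL scheme: %d interior classes of %.3g h over [%.3g, %.3g) h + 2 edge classes\n",
    x$K, x$width, x$lo, x$hi
  ))
  invisible(x)
}

#' Assign milking intervals to MICL classes
#'
#' @param t Numeric vector of milking intervals, hours; must lie in (0, 24).
#' @param scheme A [micl_scheme()].
#' @return Integer vector of class codes: 0 for the lower edge class
#'   (`t < lo`), `1:K` for interior classes (half-open, ties go up), `K + 1`
#'   for the upper edge class (`t >= hi`).
#' @examples
#' sch <- micl_scheme(9, 15, 0.5)
#' assign_micl(c(12.3, 12.5, 8.2), sch)  # 7, 8, 0
#' @export
assign_micl <- function(t, scheme) {
  stopifnot(inherits(scheme, "micl_scheme"))
  if (any(!is.finite(t)) || any(t <= 0) || any(t >= 24)) {
    stop("assign_micl: milking intervals must lie in (0, 24) hours", call. = FALSE)
  }
  k <- floor((t - scheme$lo) / scheme$width) + 1L
  k[t < scheme$lo] <- 0L
  k[t >= scheme$hi] <- scheme$K + 1L
  # guard against floating-point droop just below a class boundary
  pmin.int(pmax.int(as.integer(k), 0L), scheme$K + 1L)
}

#' Mirror class of a MICL class
#'
#' For a scheme symmetric about 12 h, the PM interval of a cow-day
#' (`24 - t_AM`) falls in the mirror image of the AM class: interior class
#' `k` maps to `K + 1 - k` and the edge classes swap. Used to check the
#' per-class zero-sum identity of additive factors and the reciprocal-sum
#' identity of bulk-ratio factors.
#'
#' @param k Integer vector of class codes.
#' @param scheme A [micl_scheme()]; must satisfy `lo + hi == 24`.
#' @return Integer vector of mirrored class codes.
#' @export
micl_mirror <- function(k, scheme) {
  stopifnot(inherits(scheme, "micl_scheme"))
  if (abs(scheme$lo + scheme$hi - 24) > 1e-9) {
    stop("micl_mirror: scheme is not symmetric about 12 h (lo + hi != 24)",
         call. = FALSE)
  }
  m <- scheme$K + 1L - as.integer(k)
  m[k == 0L] <- scheme$K + 1L
  m[k == scheme$K + 1L] <- 0L
  m
}

#' Class midpoints, with empirical midpoints for edge classes
#'
#' @param scheme A [micl_scheme()].
#' @param k Integer vector of class codes for which midpoints are wanted.
#' @param t Optional numeric vector of intervals (the training records'
#'   intervals) used to compute the empirical mean interval of edge-class
#'   members. Without it, edge-class midpoints are `NA`.
#' @return Numeric vector of midpoints (hours), matched to `k`.
#' @export
micl_midpoint <- function(scheme, k, t = NULL) {
  stopifnot(inherits(scheme, "micl_scheme"))
  k <- as.integer(k)
  mid <- rep(NA_real_, length(k))
  interior <- k >= 1L & k <= scheme$K
  mid[interior] <- scheme$midpoints[k[interior]]
  if (!is.null(t) && length(t)) {
    kt <- assign_micl(t, scheme)
    if (any(k == 0L)) mid[k == 0L] <- mean(t[kt == 0L])
    if (any(k == scheme$K + 1L)) mid[k == scheme$K + 1L] <- mean(t[kt == scheme$K + 1L])
  }
  mid
}

#' Class bounds of MICL classes
#'
#' @param scheme A [micl_scheme()].
#' @param k Integer vector of class codes.
#' @return A two-column matrix `lo`, `hi` (hours); edge classes are open
#'   towards 0 and 24 respectively.
#' @keywords internal
micl_bounds <- function(scheme, k) {
  k <- as.integer(k)
  lo <- scheme$lo + (k - 1L) * scheme$width
  hi <- lo + scheme$width
  lo[k == 0L] <- 0
  hi[k == 0L] <- scheme$lo
  lo[k == scheme$K + 1L] <- scheme$hi
  hi[k == scheme$K + 1L] <- 24
  cbind(lo = lo, hi = hi)
}
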