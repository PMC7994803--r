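#' Age interval in Ma before present
#'
#' The universal currency of the chronology analysis: a closed interval of
#' ages in million years before present, stored as an (older, younger) pair
#' with `older >= younger >= 0`. All HPD bounds, lineage availability windows
#' and transfer windows are `time_interval` objects.
#'
#' @param older Older (larger) bound in Ma.
#' @param younger Younger (smaller) bound in Ma.
#' @return An object of class `time_interval` with elements `older` and
#'   `younger`.
#' @examples
#' ti <- time_interval(1658, 440)
#' interval_width(ti)
#' @export
time_interval <- function(older, younger) {
  stopifnot(is.numeric(older), is.numeric(younger),
            length(older) == 1L, length(younger) == 1L)
  if (is.na(older) || is.na(younger)) {
    stop("time_interval bounds must not be NA", call. = FALSE)
  }
  if (younger < 0) {
    stop("time_interval: younger bound must be >= 0 (got ", younger, ")",
         call. = FALSE)
  }
  if (older < younger) {
    stop("time_interval: older bound (", older,
         ") must be >= younger bound (", younger, ")", call. = FALSE)
  }
  structure(list(older = as.numeric(older), younger = as.numeric(younger)),
            class = "time_interval")
}

#' @export
print.time_interval <- function(x, ...) {
  cat(sprintf("[%g, %g] Ma (width %g)\n", x$older, x$younger,
              interval_width(x)))
  invisible(x)
}

#' Width of an age interval
#'
#' @param x A [time_interval()].
#' @return `older - younger`, in Ma (always `>= 0`).
#' @export
interval_width <- function(x) {
  stopifnot(inherits(x, "time_interval"))
  x$older - x$younger
}

#' @export
format.time_interval <- function(x, ...) {
  sprintf("[%g, %g]", x$older, x$younger)
}

is_time_interval <- function(x) inherits(x, "time_interval")

#' Does one interval contain a given age?
#' @param x A [time_interval()].
#' @param age Numeric age in Ma.
#' @return Logical.
#' @export
interval_contains <- function(x, age) {
  stopifnot(is_time_interval(x))
  age >= x$younger & age <= x$older
}
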