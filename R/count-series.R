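#' A named, time-ordered series of cell counts
#'
#' One row per observation: series name, time in days, the raw (integer)
#' count, and one or more sampling-fraction columns \code{sample1},
#' \code{sample2}, ... giving the fraction of cells carried through each
#' sampling stage for that observation.
#'
#' @param name series label (single string).
#' @param time observation times (days); must be strictly increasing after
#'   sorting, i.e. no duplicates.
#' @param count non-negative integer counts.
#' @param fractions either a \code{\link{sampling_scheme}} applied to every
#'   row, or a numeric matrix (rows x stages) of per-row fractions.
#' @return a \code{count_series} data frame with columns \code{name},
#'   \code{time}, \code{count}, \code{sample1}, ...
#' @export
count_series <- function(name, time, count, fractions = sampling_scheme(1)) {
  stopifnot(is.character(name), length(name) == 1)
  n <- length(time)
  if (length(count) != n) stop("time and count must have equal length")
  if (any(!is.finite(time))) stop("times must be finite")
  if (any(count < 0) || any(count != round(count)))
    stop("counts must be non-negative integers")
  if (inherits(fractions, "sampling_scheme"))
    fractions <- matrix(fractions$fractions, nrow = n,
                        ncol = length(fractions$fractions), byrow = TRUE)
  if (!is.matrix(fractions) || nrow(fractions) != n)
    stop("fractions must be a sampling_scheme or an n x stages matrix")
  if (any(fractions <= 0) || any(fractions > 1))
    stop("sampling fractions must lie in (0, 1]")
  ord <- order(time)
  if (anyDuplicated(time)) stop("duplicate observation times in series '", name, "'")
  df <- data.frame(name = name, time = time[ord], count = as.numeric(count[ord]),
                   fractions[ord, , drop = FALSE])
  names(df)[-(1:3)] <- paste0("sample", seq_len(ncol(fractions)))
  structure(df, class = c("count_series", "data.frame"))
}

fraction_matrix <- function(series) {
  cols <- grep("^sample[0-9]+$", names(series), value = TRUE)
  as.matrix(series[, cols, drop = FALSE])
}

row_scheme <- function(series, i = 1L) {
  sampling_scheme(as.numeric(fraction_matrix(series)[i, ]))
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> '%s': %d observations over [%g, %g] days\n",
              x$name[1], nrow(x), min(x$time), max(x$time)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
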