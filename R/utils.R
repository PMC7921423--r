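#' Trim extreme outliers by the 5 x IQR rule
#'
#' Values below `Q1 - k * IQR` or above `Q3 + k * IQR` (default `k = 5`,
#' a deliberately permissive bound that removes only gross artefacts such
#' as a mis-segmented cell) are flagged for removal. Quartiles use linear
#' interpolation (type 7, R's default). With fewer than 4 values the
#' quartiles are not meaningful, so nothing is trimmed and a warning is
#' raised.
#'
#' @param x Numeric vector.
#' @param k IQR multiplier (default 5).
#' @return List with `values` (retained), `keep` (logical mask on `x`),
#'   and `bounds` (`c(lower, upper)`, `NA` when not computed).
#' @export
#' @examples
#' trim_extreme(c(10, 11, 12, 13, 1000))$values
trim_extreme <- function(x, k = 5) {
  stopifnot(is.numeric(x), k >= 0)
  if (length(x) < 4L) {
    warning("fewer than 4 values: extreme-outlier trim skipped")
    return(list(values = x, keep = rep(TRUE, length(x)),
                bounds = c(NA_real_, NA_real_)))
  }
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  iqr <- q[2] - q[1]
  bounds <- c(q[1] - k * iqr, q[2] + k * iqr)
  keep <- !is.na(x) & x >= bounds[1] & x <= bounds[2]
  list(values = x[keep], keep = keep, bounds = bounds)
}
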