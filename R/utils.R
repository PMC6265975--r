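#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with a classed condition so tests can match
# on class rather than message text.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "eegstress_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# z-score fit/apply split so that test folds are always standardized with
# statistics estimated on the training fold only.

#' Fit per-column standardization statistics
#'
#' Computes column means and standard deviations on a training matrix.
#' Columns with zero standard deviation get scale 1 so that constant
#' features map to 0 rather than NaN.
#'
#' @param x numeric matrix (rows = observations).
#' @return list with `center` and `scale` vectors, class `zscore_fit`.
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(center = ctr, scale = scl), class = "zscore_fit")
}

#' Apply previously fitted standardization
#'
#' @param fit object from [zscore_fit()].
#' @param x matrix with the same columns as the fitting matrix.
#' @return standardized matrix.
#' @export
zscore_apply <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(fit$center)) {
    abort("column count does not match standardization fit", "eegstress_shape_error")
  }
  sweep(sweep(x, 2, fit$center, "-"), 2, fit$scale, "/")
}
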