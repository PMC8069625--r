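# The eight per-day vector-magnitude features and the train-fitted scaler.

#' Absolute energy of a series
#'
#' Sum of squared values, `sum(x_i^2)`.
#'
#' @param x nonempty numeric vector.
#' @return a single nonnegative number.
#' @examples absoluteEnergy(c(1, 2, 3))  # 14
#' @export
absoluteEnergy <- function(x) {
  if (length(x) == 0L) wd_domain_error("absoluteEnergy needs a nonempty vector")
  sum(x^2)
}

#' Absolute change of a series
#'
#' Sum of absolute successive differences, `sum(|x_{i+1} - x_i|)`.
#'
#' @param x numeric vector of length at least 2.
#' @return a single nonnegative number.
#' @examples absoluteChange(c(1, 3, 2))  # 3
#' @export
absoluteChange <- function(x) {
  if (length(x) < 2L) wd_domain_error("absoluteChange needs at least 2 values")
  sum(abs(diff(x)))
}

.feature_names <- c("mean", "variance", "maximum", "q95",
                    "absolute_energy", "absolute_change",
                    "kurtosis", "skewness")

#' Extract the eight day-level features
#'
#' Computes, for every day, the mean, variance, maximum, 95th quantile,
#' absolute energy, absolute change, kurtosis and skewness of the full
#' 1440-minute vector-magnitude series. Padded minutes are included as
#' zeros: the feature models must see truncated boundary days exactly as
#' the raw-input networks do, which receive the zero-padded array.
#'
#' Moment conventions: variance is the biased (divide-by-n) second central
#' moment; skewness is `m3 / m2^(3/2)`; kurtosis is `m4 / m2^2`
#' (non-excess; set `excessKurtosis = TRUE` to subtract 3). A constant
#' series has skewness and kurtosis 0 by convention. The 95th quantile
#' uses linearly interpolated order statistics (`type = 7`); alternative
#' rules differ in the 4th decimal on 1440 points and are selectable via
#' `quantileType`.
#'
#' @param days a [DayArray].
#' @param excessKurtosis subtract 3 from kurtosis? Default FALSE.
#' @param quantileType passed to [stats::quantile()].
#' @return a data.frame with one row per day: `participantId`,
#'   `assessmentId`, `date`, `label`, and the eight feature columns.
#' @export
extractFeatures <- function(days, excessKurtosis = FALSE, quantileType = 7) {
  stopifnot(is(days, "DayArray"))
  cd <- SummarizedExperiment::colData(days)
  data.frame(
    participantId = cd$participantId,
    assessmentId = cd$assessmentId,
    date = cd$date,
    label = cd$label,
    vm_features(vectorMagnitude(days), excessKurtosis, quantileType),
    row.names = colnames(days))
}

# Feature computation proper: one column of `vm` per day, rows = minutes.
vm_features <- function(vm, excessKurtosis = FALSE, quantileType = 7) {
  vm <- as.matrix(vm)
  n <- nrow(vm)
  mu <- colMeans(vm)
  ctr <- sweep(vm, 2L, mu)
  m2 <- colMeans(ctr^2)
  m3 <- colMeans(ctr^3)
  m4 <- colMeans(ctr^4)
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2, 0)
  if (excessKurtosis) kurt <- ifelse(m2 > 0, kurt - 3, 0)
  data.frame(
    mean = mu,
    variance = m2,
    maximum = apply(vm, 2L, max),
    q95 = apply(vm, 2L, stats::quantile, probs = 0.95, names = FALSE,
                type = quantileType),
    absolute_energy = colSums(vm^2),
    absolute_change = colSums(abs(vm[-1L, , drop = FALSE] -
                                    vm[-n, , drop = FALSE])),
    kurtosis = kurt,
    skewness = skew)
}

#' Fit a centering/scaling transform on training data
#'
#' Learns per-feature (for a feature table) or per-axis (for a [DayArray])
#' means and standard deviations from training data only, so that held-out
#' data are transformed with training parameters. Entries with zero
#' standard deviation get scale 1, which maps a constant column to all
#' zeros.
#'
#' @param x a feature data.frame (as from [extractFeatures()]) or a
#'   [DayArray] (raw per-axis scaling over all training minutes).
#' @return a [DayScaler].
#' @export
fitScaler <- function(x) {
  if (is(x, "DayArray")) {
    a <- SummarizedExperiment::assays(x)
    center <- c(x = mean(a$x), y = mean(a$y), z = mean(a$z))
    scale <- c(x = stats::sd(a$x), y = stats::sd(a$y), z = stats::sd(a$z))
    kind <- "raw"
  } else {
    cols <- intersect(.feature_names, names(x))
    if (!length(cols)) wd_contract_error("no feature columns to scale")
    m <- as.matrix(x[, cols, drop = FALSE])
    center <- colMeans(m)
    scale <- apply(m, 2L, stats::sd)
    kind <- "features"
  }
  scale[!is.finite(scale) | scale == 0] <- 1
  new("DayScaler", kind = kind, center = center, scale = scale)
}

#' Apply or invert a fitted scaler
#'
#' @param scaler a [DayScaler].
#' @param x data matching the scaler kind: a feature data.frame, or for
#'   `kind = "raw"` an array with axes as the last dimension (e.g. the
#'   days x 1440 x 3 stack fed to the networks).
#' @return the transformed object, same shape as `x`.
#' @export
applyScaler <- function(scaler, x) .scale_impl(scaler, x, invert = FALSE)

#' @rdname applyScaler
#' @export
invertScaler <- function(scaler, x) .scale_impl(scaler, x, invert = TRUE)

.scale_impl <- function(scaler, x, invert) {
  stopifnot(is(scaler, "DayScaler"))
  if (scaler@kind == "features") {
    cols <- names(scaler@center)
    if (!all(cols %in% names(x)))
      wd_contract_error("data lack the feature columns the scaler was fit on")
    for (j in cols) {
      x[[j]] <- if (invert) x[[j]] * scaler@scale[[j]] + scaler@center[[j]]
      else (x[[j]] - scaler@center[[j]]) / scaler@scale[[j]]
    }
    x
  } else {
    d <- dim(x)
    if (is.null(d) || d[length(d)] != 3L)
      wd_contract_error("raw scaler expects an array with 3 axes in the last dimension")
    out <- x
    idx <- slice.index(x, length(d))
    for (a in 1:3) {
      sel <- idx == a
      out[sel] <- if (invert) x[sel] * scaler@scale[[a]] + scaler@center[[a]]
      else (x[sel] - scaler@center[[a]]) / scaler@scale[[a]]
    }
    out
  }
}

setMethod("show", "DayScaler", function(object) {
  cat(sprintf("DayScaler (%s): %d entr%s\n", object@kind,
              length(object@center), if (length(object@center) == 1L) "y" else "ies"))
})

#' Write a per-day feature table to CSV
#'
#' @param features data.frame from [extractFeatures()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureCsv <- function(features, path) {
  out <- features
  out$date <- format(out$date)
  data.table::fwrite(out, path)
  invisible(path)
}
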