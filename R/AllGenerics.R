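#' @rdname EpochSeries-class
#' @param x an object.
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))

#' @rdname EpochSeries-class
#' @export
setGeneric("assessmentId", function(x) standardGeneric("assessmentId"))

#' @rdname EpochSeries-class
#' @export
setGeneric("epochSeconds", function(x) standardGeneric("epochSeconds"))

#' @rdname EpochSeries-class
#' @export
setGeneric("epochCounts", function(x) standardGeneric("epochCounts"))

#' @rdname EpochSeries-class
#' @export
setGeneric("epochTime", function(x) standardGeneric("epochTime"))

#' Collapse sub-minute epochs to 1-minute resolution
#'
#' Sums the per-axis counts of all epochs falling in the same wall-clock
#' minute. Minutes are aligned to seconds 0-59 of the clock, not to the
#' first sample, so collapsed series segment identically to native 1-min
#' recordings. Partial boundary minutes are summed over the epochs present.
#' Total per-axis counts are conserved, and the operation is the identity
#' on data already at 60-s epochs.
#'
#' @param x an [EpochSeries] whose epoch length divides 60 s.
#' @return an [EpochSeries] at 60-s epochs.
#' @export
setGeneric("collapseToMinute", function(x) standardGeneric("collapseToMinute"))

#' @rdname DayArray-class
#' @param x an object.
#' @export
setGeneric("dayLabels", function(x) standardGeneric("dayLabels"))

#' @rdname DayArray-class
#' @export
setGeneric("paddedMask", function(x) standardGeneric("paddedMask"))

#' Per-minute vector magnitude of a day stack
#'
#' Euclidean norm `sqrt(x^2 + y^2 + z^2)` of the three axis counts at each
#' minute of each day.
#'
#' @param x a [DayArray].
#' @return a 1440-by-`ncol(x)` numeric matrix.
#' @export
setGeneric("vectorMagnitude", function(x) standardGeneric("vectorMagnitude"))

#' Per-day totals used by the processing filters
#'
#' For each day, the total vector-magnitude counts and the number of active
#' minutes (vector magnitude strictly greater than zero). Zero-padded
#' minutes are excluded from both, so padding can neither rescue nor doom a
#' boundary day.
#'
#' @param x a [DayArray].
#' @return a data.frame with columns `totalVm` and `activeMinutes`.
#' @export
setGeneric("daySummary", function(x) standardGeneric("daySummary"))

#' Fit a day classifier
#'
#' Dispatches on the [ModelSpec] family. Feature-input families (`rf`,
#' `glm_rcs`, `glmm_rcs`, `mlp`) extract the eight vector-magnitude features
#' internally; raw-input families (`cnn`, `rnn`, `crnn`) standardize and
#' consume the 1440-by-3 count arrays. The scaler (and, for spline models,
#' the knots) are learned from the training data only and stored in the
#' returned model, so held-out prediction applies the training transform.
#'
#' @param spec a [ModelSpec].
#' @param x a labeled [DayArray] (every day labeled 0 or 1).
#' @param ... passed to family-specific fitters.
#' @return a [WearModel].
#' @export
setGeneric("fitModel", function(spec, x, ...) standardGeneric("fitModel"))

#' Predict delivery probabilities for days
#'
#' Applies the model's own training-time scaler (and spline knots) before
#' scoring, and returns one forecast probability per day for the positive
#' class, delivery (label 1).
#'
#' @param object a [WearModel].
#' @param x a [DayArray] of days to score.
#' @param ... unused.
#' @return a data.frame (one row per day) with identifier columns, the
#'   forecast `f` in `[0, 1]`, and the true outcome `o` (NA if unlabeled).
#' @export
setGeneric("predictProb", function(object, x, ...) standardGeneric("predictProb"))

#' @rdname CvReport-class
#' @param x an object.
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))
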