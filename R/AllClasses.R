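#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' EpochSeries: one assessment's epoch-level activity counts
#'
#' Holds the raw stream for a single mailed-device assessment: a strictly
#' regular, strictly increasing grid of timestamps and the nonnegative
#' integer activity counts on the x, y and z axes at each epoch.
#'
#' @slot participantId character(1) participant identifier.
#' @slot assessmentId character(1) assessment identifier.
#' @slot epochSeconds integer(1), epoch length in seconds (60 for 1-min data).
#' @slot time POSIXct vector of epoch start times (UTC).
#' @slot counts integer matrix with one row per epoch and columns x, y, z.
#'
#' @seealso [epochSeries()], [readEpochCsv()], [collapseToMinute()]
#' @export
setClass("EpochSeries",
  representation(
    participantId = "character",
    assessmentId = "character",
    epochSeconds = "integer",
    time = "POSIXct",
    counts = "matrix"
  )
)

setValidity("EpochSeries", function(object) {
  msg <- character()
  if (length(object@participantId) != 1L) msg <- c(msg, "participantId must be length 1")
  if (length(object@assessmentId) != 1L) msg <- c(msg, "assessmentId must be length 1")
  es <- object@epochSeconds
  if (length(es) != 1L || is.na(es) || es < 1L) msg <- c(msg, "epochSeconds must be a positive integer")
  cts <- object@counts
  if (ncol(cts) != 3L || !identical(colnames(cts), c("x", "y", "z")))
    msg <- c(msg, "counts must have columns x, y, z")
  if (nrow(cts) != length(object@time))
    msg <- c(msg, "counts and time must have the same length")
  if (nrow(cts) > 0L && any(cts < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (length(object@time) > 1L) {
    d <- diff(as.numeric(object@time))
    if (any(d <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
    else if (any(abs(d - es) > 1e-6))
      msg <- c(msg, sprintf("timestamps must be regularly spaced at %d s", es))
  }
  if (length(msg)) msg else TRUE
})

#' DayArray: midnight-aligned days of activity counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one column per
#' calendar day and 1440 rows (minutes of the day). Assays `"x"`, `"y"`,
#' `"z"` carry the per-minute counts; assay `"padded"` is a logical mask,
#' TRUE for minutes that were zero-filled because the device was activated
#' after midnight on the first day or deactivated before midnight on the
#' last. Column metadata holds `participantId`, `assessmentId`, `date`,
#' `label` (0 wear, 1 delivery, NA unknown) and `adherent`.
#'
#' @seealso [segmentDays()], [vectorMagnitude()], [applyFullProcessing()]
#' @export
setClass("DayArray", contains = "SummarizedExperiment")

setValidity("DayArray", function(object) {
  msg <- character()
  need <- c("x", "y", "z", "padded")
  if (!all(need %in% names(SummarizedExperiment::assays(object))))
    msg <- c(msg, "assays x, y, z and padded are required")
  if (nrow(object) != 1440L)
    msg <- c(msg, "a DayArray must have exactly 1440 rows (minutes of day)")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("participantId", "assessmentId", "date", "label"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", f))
  if (!length(msg) && ncol(object) > 0L) {
    pad <- SummarizedExperiment::assay(object, "padded")
    for (ax in c("x", "y", "z")) {
      a <- SummarizedExperiment::assay(object, ax)
      if (any(a < 0)) { msg <- c(msg, "counts must be nonnegative"); break }
      if (any(a[pad] != 0)) { msg <- c(msg, "padded minutes must hold zero counts"); break }
    }
  }
  if (length(msg)) msg else TRUE
})

#' DayScaler: centering/scaling parameters learned from training data
#'
#' @slot kind `"features"` (one center/scale per feature column) or `"raw"`
#'   (one center/scale per accelerometer axis).
#' @slot center,scale named numeric vectors; `scale` entries are 1 where the
#'   training standard deviation was zero.
#' @export
setClass("DayScaler",
  representation(kind = "character", center = "numeric", scale = "numeric")
)

setValidity("DayScaler", function(object) {
  if (!object@kind %in% c("features", "raw")) return("kind must be 'features' or 'raw'")
  if (length(object@center) != length(object@scale)) return("center/scale length mismatch")
  if (any(object@scale <= 0)) return("scale entries must be positive")
  TRUE
})

#' ModelSpec: a day-classifier configuration
#'
#' @slot family one of `"rf"`, `"glm_rcs"`, `"glmm_rcs"`, `"mlp"`, `"cnn"`,
#'   `"rnn"`, `"crnn"`, or the testing baselines `"oracle"` / `"constant"`.
#' @slot params family-specific hyperparameters (validated at construction).
#' @slot seed integer seed used for every stochastic step of fitting.
#' @seealso [modelSpec()], [fitModel()]
#' @export
setClass("ModelSpec",
  representation(family = "character", params = "list", seed = "integer")
)

#' WearModel: a fitted day classifier
#'
#' @slot spec the [ModelSpec] the model was fitted under.
#' @slot fit opaque learned parameters (family-specific).
#' @slot scaler the [DayScaler] fitted on the training split (or NULL).
#' @slot knots per-feature restricted-cubic-spline knots (rcs families).
#' @slot meta training metadata: days, participants, epochs trained, etc.
#' @export
setClass("WearModel",
  representation(spec = "ModelSpec", fit = "ANY", scaler = "ANY",
                 knots = "ANY", meta = "list")
)

#' SplitPlan: participant-grouped Monte Carlo train/test partitions
#'
#' @slot reps list of repetitions, each `list(train = , test = )` of
#'   participant ids with empty intersection and full union.
#' @slot testFraction fraction of participants sampled into each test set.
#' @slot masterSeed seed the partitions were drawn from.
#' @seealso [makeMcSplits()], [runCv()]
#' @export
setClass("SplitPlan",
  representation(reps = "list", testFraction = "numeric", masterSeed = "integer")
)

setValidity("SplitPlan", function(object) {
  for (r in object@reps) {
    if (length(intersect(r$train, r$test)) > 0L)
      return("train and test participants must be disjoint")
    if (!length(r$train) || !length(r$test))
      return("train and test sets must be nonempty")
  }
  if (object@testFraction <= 0 || object@testFraction >= 1)
    return("testFraction must be in (0, 1)")
  TRUE
})

#' CvReport: cross-validated performance of one model configuration
#'
#' @slot perRep data.frame with one row per Monte Carlo repetition and
#'   columns sensitivity, ppv, f1, brier (NA where undefined), nTest.
#' @slot family model family evaluated.
#' @slot mode processing mode, `"minimal"` or `"full"`.
#' @slot threshold probability cut used to harden forecasts into labels.
#' @seealso [runCv()], [cvSummary()]
#' @export
setClass("CvReport",
  representation(perRep = "data.frame", family = "character",
                 mode = "character", threshold = "numeric")
)
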