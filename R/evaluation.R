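# Participant-grouped Monte Carlo cross-validation and the four forecast
# metrics (sensitivity, positive predictive value, F1, Brier), with
# delivery (label 1) as the positive class throughout.

#' Draw participant-grouped Monte Carlo splits
#'
#' Each repetition is an independent random partition of the participants
#' into a test set of `round(testFraction * n)` and a training set of the
#' rest, so all days of a participant always travel together. This is
#' repeated random resampling (the same participant can be tested in
#' several repetitions), not a disjoint k-way partition.
#'
#' @param participants character vector of participant ids (duplicates
#'   tolerated and ignored).
#' @param nReps number of repetitions (default 5).
#' @param testFraction fraction of participants per test set (default 0.3).
#' @param masterSeed seed; repetition r uses a seed derived from it.
#' @return a [SplitPlan].
#' @examples
#' sp <- makeMcSplits(sprintf("P%02d", 1:10), masterSeed = 1)
#' lengths(sp@reps[[1]])
#' @export
makeMcSplits <- function(participants, nReps = 5L, testFraction = 0.3,
                         masterSeed = 1L) {
  ids <- unique(as.character(participants))
  n <- length(ids)
  if (n < 2L) wd_config_error("need at least 2 participants to split")
  nTest <- round(testFraction * n)
  if (nTest < 1L || nTest >= n)
    wd_config_error(sprintf(
      "testFraction %.2f of %d participants leaves an empty train or test set",
      testFraction, n))
  reps <- lapply(seq_len(nReps), function(r) {
    test <- with_seed(derive_seed(masterSeed, r), sample(ids, nTest))
    list(train = setdiff(ids, test), test = test)
  })
  new("SplitPlan", reps = reps, testFraction = testFraction,
      masterSeed = as.integer(masterSeed))
}

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan: %d repetition(s), test fraction %.2f, seed %d\n",
              length(object@reps), object@testFraction, object@masterSeed))
})

.confusion <- function(predictions, threshold) {
  stopifnot(all(c("f", "o") %in% names(predictions)))
  if (!nrow(predictions)) wd_contract_error("empty prediction set")
  if (any(predictions$f < 0 | predictions$f > 1))
    wd_contract_error("forecast probabilities must lie in [0, 1]")
  pred <- as.integer(predictions$f >= threshold)
  o <- predictions$o
  list(tp = sum(pred == 1L & o == 1L), fp = sum(pred == 1L & o == 0L),
       fn = sum(pred == 0L & o == 1L), tn = sum(pred == 0L & o == 0L))
}

#' Forecast metrics for day classification
#'
#' `sensitivity()` (recall) is TP / (TP + FN); `ppv()` (precision) is
#' TP / (TP + FP); `f1Score()` is their harmonic mean; `brierScore()` is
#' the mean squared difference between forecast probability and outcome.
#' Delivery (outcome 1) is the positive class. A metric whose denominator
#' is empty (no true positives + false negatives, or no predicted
#' positives) is undefined and returned as NA with a warning rather than
#' imputed.
#'
#' @param predictions data.frame with columns `f` (forecast probability in
#'   `[0, 1]`) and `o` (outcome, 0 or 1), as returned by [predictProb()].
#' @param threshold probability cut converting forecasts to hard labels.
#' @return a single number (NA if undefined).
#' @examples
#' p <- data.frame(f = c(1, 0, 1), o = c(1, 0, 0))
#' brierScore(p)  # 1/3
#' @export
sensitivity <- function(predictions, threshold = 0.5) {
  cm <- .confusion(predictions, threshold)
  if (cm$tp + cm$fn == 0L) {
    warning("no positive outcomes: sensitivity undefined")
    return(NA_real_)
  }
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname sensitivity
#' @export
ppv <- function(predictions, threshold = 0.5) {
  cm <- .confusion(predictions, threshold)
  if (cm$tp + cm$fp == 0L) {
    warning("no predicted positives: PPV undefined")
    return(NA_real_)
  }
  cm$tp / (cm$tp + cm$fp)
}

#' @rdname sensitivity
#' @param sens,ppv sensitivity and positive predictive value in `[0, 1]`.
#' @export
f1Score <- function(sens, ppv) {
  if (is.na(sens) || is.na(ppv)) return(NA_real_)
  if (sens == 0 && ppv == 0) {
    warning("sensitivity and PPV both 0: F1 defined as 0")
    return(0)
  }
  2 * sens * ppv / (sens + ppv)
}

#' @rdname sensitivity
#' @export
brierScore <- function(predictions) {
  if (!nrow(predictions)) wd_contract_error("empty prediction set")
  mean((predictions$f - predictions$o)^2)
}

#' Run participant-grouped Monte Carlo cross-validation
#'
#' For each repetition of the plan: restrict the processed day set to the
#' training participants, fit the model (its scaler, spline knots and all
#' stochastic steps are re-derived from the repetition seed on training
#' data only), predict the held-out participants' days, and compute
#' sensitivity, PPV, F1 and Brier. Undefined metrics are recorded as NA
#' and excluded (with how many, in the report) from the means.
#'
#' @param days a labeled [DayArray], already minimally or fully processed
#'   (see `mode`, which is recorded in the report and — when the provenance
#'   log is absent — applied here).
#' @param spec a [ModelSpec].
#' @param splitPlan a [SplitPlan] over the participants of `days`.
#' @param mode `"minimal"` or `"full"`; if `days` has not yet been through
#'   the corresponding processing step it is applied first.
#' @param threshold hard-classification cut (default 0.5).
#' @return a [CvReport].
#' @export
runCv <- function(days, spec, splitPlan, mode = c("minimal", "full"),
                  threshold = 0.5) {
  stopifnot(is(days, "DayArray"), is(spec, "ModelSpec"),
            is(splitPlan, "SplitPlan"))
  mode <- match.arg(mode)
  prov <- S4Vectors::metadata(days)$processing
  if (!mode %in% (prov %||% character())) {
    days <- if (mode == "minimal") applyMinimalProcessing(days)
    else applyFullProcessing(days)
  }
  pid <- SummarizedExperiment::colData(days)$participantId
  rows <- lapply(seq_along(splitPlan@reps), function(r) {
    rep <- splitPlan@reps[[r]]
    trainDays <- days[, pid %in% rep$train]
    testDays <- days[, pid %in% rep$test]
    if (!ncol(trainDays) || !ncol(testDays))
      wd_config_error(sprintf("repetition %d has an empty train or test day set", r))
    repSpec <- spec
    repSpec@seed <- derive_seed(spec@seed, 100L + r)
    model <- fitModel(repSpec, new("DayArray", trainDays))
    preds <- predictProb(model, new("DayArray", testDays))
    sens <- suppressWarnings(sensitivity(preds, threshold))
    prec <- suppressWarnings(ppv(preds, threshold))
    data.frame(rep = r,
               sensitivity = sens, ppv = prec,
               f1 = suppressWarnings(f1Score(sens, prec)),
               brier = brierScore(preds),
               nTest = nrow(preds))
  })
  new("CvReport", perRep = do.call(rbind, rows), family = spec@family,
      mode = mode, threshold = threshold)
}

#' @rdname CvReport-class
#' @aliases cvSummary,CvReport-method
setMethod("cvSummary", "CvReport", function(x) {
  pr <- x@perRep
  mets <- c("sensitivity", "ppv", "f1", "brier")
  data.frame(metric = mets,
             mean = vapply(mets, function(m) mean(pr[[m]], na.rm = TRUE), 0),
             sd = vapply(mets, function(m) stats::sd(pr[[m]], na.rm = TRUE), 0),
             nMissing = vapply(mets, function(m) sum(is.na(pr[[m]])), 0L),
             row.names = NULL)
})

setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport: %s on %s-processed data, %d repetition(s)\n",
              object@family, object@mode, nrow(object@perRep)))
  s <- cvSummary(object)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f (sd %.3f)%s\n", s$metric[i], s$mean[i], s$sd[i],
                if (s$nMissing[i]) sprintf(" [%d undefined]", s$nMissing[i]) else ""))
})

#' Write a CvReport to JSON
#'
#' @param report a [CvReport].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeCvReport <- function(report, path) {
  stopifnot(is(report, "CvReport"))
  jsonlite::write_json(
    list(family = report@family, mode = report@mode,
         threshold = report@threshold,
         perRepetition = report@perRep, summary = cvSummary(report)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}
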