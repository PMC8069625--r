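# Midnight-aligned day segmentation, vector magnitude, and the minimal /
# full processing filters.

#' Segment an assessment into midnight-aligned days
#'
#' Splits a 1-min [EpochSeries] into one 1440-minute column per calendar
#' date it touches. The first day is zero-padded from midnight to device
#' activation and the last from deactivation to the next midnight; interior
#' days must be complete (a gap there is a data-integrity error, since
#' gapped input is rejected at read time). Day labels, when provided, are
#' attached by date; days without a label entry are marked unknown (NA).
#'
#' @param series an [EpochSeries] at 60-s epochs (see [collapseToMinute()]).
#' @param labels optional data.frame as returned by [readDayLabels()].
#' @return a [DayArray] with one column per date.
#' @examples
#' t0 <- as.POSIXct("2020-01-06 10:00:00", tz = "UTC")
#' es <- epochSeries("P1", "A1", t0 + 60 * (0:1439), matrix(5L, 1440, 3))
#' da <- segmentDays(es)
#' sum(paddedMask(da)[, 1])  # minutes 0..599 of the first day are padded
#' @export
segmentDays <- function(series, labels = NULL) {
  stopifnot(is(series, "EpochSeries"))
  if (series@epochSeconds != 60L)
    wd_contract_error("segmentDays requires 1-min epochs; collapseToMinute() first")
  tn <- as.numeric(series@time)
  day0 <- floor(tn[1L] / 86400)
  dayIdx <- floor(tn / 86400) - day0            # 0-based day within assessment
  minute <- (tn %/% 60) %% 1440                 # 0-based minute of day
  nDays <- dayIdx[length(dayIdx)] + 1L
  if (length(unique(dayIdx)) != nDays)
    wd_integrity_error("interior date with no measurements")

  flat <- dayIdx * 1440 + minute + 1            # position in the day stack
  make_axis <- function(ax) {
    m <- matrix(0L, 1440L, nDays)
    m[flat] <- series@counts[, ax]
    m
  }
  padded <- matrix(TRUE, 1440L, nDays)
  padded[flat] <- FALSE
  # interior days must be fully observed
  if (nDays > 2L && any(padded[, 2:(nDays - 1L)]))
    wd_integrity_error("interior day with missing minutes")
  dates <- as.Date(as.numeric(day0 + 0:(nDays - 1L)), origin = "1970-01-01")

  lab <- rep(NA_integer_, nDays)
  adh <- rep(NA, nDays)
  if (!is.null(labels)) {
    sel <- labels$participant_id == series@participantId &
      labels$assessment_id == series@assessmentId
    hit <- match(dates, as.Date(labels$date[sel]))
    lab <- labels$label[sel][hit]
    if ("adherent" %in% names(labels)) adh <- labels$adherent[sel][hit]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = make_axis("x"), y = make_axis("y"), z = make_axis("z"),
                  padded = padded),
    rowData = S4Vectors::DataFrame(minute = 0:1439),
    colData = S4Vectors::DataFrame(
      participantId = rep(series@participantId, nDays),
      assessmentId = rep(series@assessmentId, nDays),
      date = dates, label = as.integer(lab), adherent = adh,
      row.names = paste(series@participantId, series@assessmentId,
                        format(dates), sep = ":")))
  new("DayArray", se)
}

#' Segment every assessment of a simulated dataset
#'
#' Convenience wrapper binding the per-assessment [segmentDays()] results
#' into one [DayArray].
#'
#' @param dataset result of [simulateDataset()].
#' @return a [DayArray] covering all assessments.
#' @export
segmentDataset <- function(dataset) {
  parts <- lapply(dataset$assessments, function(a)
    segmentDays(collapseToMinute(a$series), dataset$labels))
  da <- do.call(cbind, unname(parts))
  new("DayArray", da)
}

#' @rdname DayArray-class
setMethod("dayLabels", "DayArray", function(x)
  SummarizedExperiment::colData(x)$label)

#' @rdname DayArray-class
setMethod("paddedMask", "DayArray", function(x)
  SummarizedExperiment::assay(x, "padded"))

#' @rdname vectorMagnitude
setMethod("vectorMagnitude", "DayArray", function(x) {
  a <- SummarizedExperiment::assays(x)
  sqrt(a$x^2 + a$y^2 + a$z^2)
})

#' @rdname daySummary
setMethod("daySummary", "DayArray", function(x) {
  vm <- vectorMagnitude(x)
  vm[paddedMask(x)] <- 0          # padded minutes contribute nothing
  data.frame(totalVm = colSums(vm),
             activeMinutes = colSums(vm > 0),
             row.names = colnames(x))
})

setMethod("show", "DayArray", function(object) {
  cd <- SummarizedExperiment::colData(object)
  lab <- cd$label
  cat(sprintf("DayArray: %d day(s), %d participant(s)\n",
              ncol(object), length(unique(cd$participantId))))
  cat(sprintf("  labels: %d wear, %d delivery, %d unknown\n",
              sum(lab == 0L, na.rm = TRUE), sum(lab == 1L, na.rm = TRUE),
              sum(is.na(lab))))
  prov <- S4Vectors::metadata(object)$processing
  if (!is.null(prov)) cat(sprintf("  processing: %s\n", paste(prov, collapse = " -> ")))
})

#' Minimal processing
#'
#' Minimal processing consists of the zero-padding already performed during
#' segmentation, so this is the identity on the day set; it records the
#' step in the object's provenance log.
#'
#' @param days a [DayArray].
#' @return the same days, with `"minimal"` appended to
#'   `metadata(days)$processing`.
#' @export
applyMinimalProcessing <- function(days) {
  stopifnot(is(days, "DayArray"))
  S4Vectors::metadata(days)$processing <-
    c(S4Vectors::metadata(days)$processing, "minimal")
  days
}

#' Full processing: drop low-information and non-adherent days
#'
#' Removes any day whose total vector-magnitude counts fall below
#' `totalMin` (default 5000) or with fewer than `movementMin` (default 10)
#' minutes of movement; additionally removes wear-labeled days with fewer
#' than `wearMin` (default 120) active minutes, which indicates
#' non-adherence to the wearing protocol. A movement minute is one with
#' vector magnitude strictly greater than zero; padded minutes are excluded
#' from all totals. Rules are checked in the order total-counts, movement,
#' adherence, and the first rule that fires is the one reported.
#'
#' All days must be labeled: the adherence rule needs to know which days
#' are human wear.
#'
#' @param days a labeled [DayArray].
#' @param totalMin,movementMin,wearMin filter thresholds.
#' @param statistic `"vm"` (default) evaluates the count threshold on the
#'   vector-magnitude series; `"axis_sum"` on the sum of the three axis
#'   totals.
#' @return the surviving [DayArray]; the removal report (a data.frame with
#'   `participantId`, `assessmentId`, `date`, `rule`) is stored in
#'   `metadata(result)$removal` and retrievable with [removalReport()].
#' @export
applyFullProcessing <- function(days, totalMin = 5000, movementMin = 10,
                                wearMin = 120,
                                statistic = c("vm", "axis_sum")) {
  stopifnot(is(days, "DayArray"))
  statistic <- match.arg(statistic)
  lab <- dayLabels(days)
  if (anyNA(lab))
    wd_contract_error("full processing requires every day to be labeled 0/1")
  ds <- daySummary(days)
  total <- if (statistic == "vm") ds$totalVm else {
    a <- SummarizedExperiment::assays(days)
    pad <- paddedMask(days)
    tot <- a$x + a$y + a$z
    tot[pad] <- 0L
    colSums(tot)
  }
  rule <- rep(NA_character_, ncol(days))
  rule[total < totalMin] <- "total_counts"
  sel <- is.na(rule) & ds$activeMinutes < movementMin
  rule[sel] <- "movement_minutes"
  sel <- is.na(rule) & lab == 0L & ds$activeMinutes < wearMin
  rule[sel] <- "wear_adherence"

  cd <- SummarizedExperiment::colData(days)
  report <- data.frame(participantId = cd$participantId,
                       assessmentId = cd$assessmentId,
                       date = cd$date, rule = rule,
                       row.names = NULL)[!is.na(rule), , drop = FALSE]
  kept <- days[, is.na(rule)]
  kept <- new("DayArray", kept)
  S4Vectors::metadata(kept)$processing <-
    c(S4Vectors::metadata(kept)$processing, "full")
  S4Vectors::metadata(kept)$removal <- report
  kept
}

#' @rdname applyFullProcessing
#' @export
removalReport <- function(days) {
  stopifnot(is(days, "DayArray"))
  S4Vectors::metadata(days)$removal
}

#' Write the removal report of a fully processed DayArray to CSV
#'
#' @param days output of [applyFullProcessing()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRemovalReport <- function(days, path) {
  rep <- removalReport(days)
  if (is.null(rep)) wd_contract_error("no removal report: apply full processing first")
  rep$date <- format(rep$date)
  data.table::fwrite(rep, path)
  invisible(path)
}
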