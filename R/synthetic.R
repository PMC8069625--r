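# Synthetic generator of delivery-adulterated accelerometry assessments.
#
# Emulates the structure of a mailed-device protocol: a pre-delivery block of
# near-zero days with sparse transport bursts, about a week of diurnal human
# wear (occasionally non-adherent), a return-delivery block, and truncated
# first/last days from mid-day activation/deactivation.

#' Simulation configuration
#'
#' Parameters of the synthetic assessment generator, with defaults chosen to
#' resemble a one-week mailed-accelerometer protocol at 1-min epochs. All
#' probabilities must lie in `[0, 1]`; ranges must be nonempty with lower
#' bound at most the upper; the wake window must sit inside `[0, 1440)`.
#'
#' @param nParticipants number of participants.
#' @param assessmentsPerParticipant assessments per participant (1, 2 or 3).
#' @param wearDaysMean mean number of wear days per assessment (Poisson,
#'   truncated to at least 1).
#' @param preDeliveryDaysRange,postDeliveryDaysRange integer ranges (uniform)
#'   for the number of outbound / return transit days.
#' @param deliveryBurstProb per-minute probability of a transport jolt on a
#'   delivery day.
#' @param deliveryBurstScale mean vector-magnitude counts of a jolt minute
#'   (exponential, rounded to integer).
#' @param wakeWindow minute-of-day interval `[start, end)` of waking hours.
#' @param wearIntensityPeak mean counts/min at the diurnal peak of an active
#'   waking minute.
#' @param wearActiveProb probability a waking minute of an adherent wear day
#'   is active.
#' @param nonadherenceProb probability a wear day is non-adherent (its
#'   active probability is scaled down by 0.05).
#' @param truncateFirstLast if TRUE, the first day starts and the last day
#'   ends at a uniformly random minute, so boundary days are incomplete.
#' @param epochSeconds epoch length (must divide 60).
#' @param seed master seed for [simulateDataset()].
#' @return a validated object of class `SimConfig` (a named list).
#' @examples
#' cfg <- simConfig(nParticipants = 2, seed = 1)
#' cfg$wearDaysMean
#' @export
simConfig <- function(nParticipants = 100L,
                      assessmentsPerParticipant = 2L,
                      wearDaysMean = 7,
                      preDeliveryDaysRange = c(2L, 8L),
                      postDeliveryDaysRange = c(2L, 8L),
                      deliveryBurstProb = 0.004,
                      deliveryBurstScale = 150,
                      wakeWindow = c(420L, 1320L),
                      wearIntensityPeak = 800,
                      wearActiveProb = 0.55,
                      nonadherenceProb = 0.1,
                      truncateFirstLast = TRUE,
                      epochSeconds = 60L,
                      seed = 1L) {
  cfg <- list(nParticipants = as.integer(nParticipants),
              assessmentsPerParticipant = as.integer(assessmentsPerParticipant),
              wearDaysMean = as.numeric(wearDaysMean),
              preDeliveryDaysRange = as.integer(preDeliveryDaysRange),
              postDeliveryDaysRange = as.integer(postDeliveryDaysRange),
              deliveryBurstProb = as.numeric(deliveryBurstProb),
              deliveryBurstScale = as.numeric(deliveryBurstScale),
              wakeWindow = as.integer(wakeWindow),
              wearIntensityPeak = as.numeric(wearIntensityPeak),
              wearActiveProb = as.numeric(wearActiveProb),
              nonadherenceProb = as.numeric(nonadherenceProb),
              truncateFirstLast = isTRUE(truncateFirstLast),
              epochSeconds = as.integer(epochSeconds),
              seed = as.integer(seed))
  .check_cfg(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

.check_cfg <- function(cfg) {
  bad <- function(field, why)
    wd_config_error(sprintf("invalid SimConfig field '%s': %s", field, why))
  if (is.na(cfg$nParticipants) || cfg$nParticipants < 1L)
    bad("nParticipants", "must be a positive integer")
  if (!cfg$assessmentsPerParticipant %in% 1:3)
    bad("assessmentsPerParticipant", "must be 1, 2 or 3")
  if (is.na(cfg$wearDaysMean) || cfg$wearDaysMean <= 0)
    bad("wearDaysMean", "must be positive")
  for (f in c("preDeliveryDaysRange", "postDeliveryDaysRange")) {
    r <- cfg[[f]]
    if (length(r) != 2L || anyNA(r) || r[1L] > r[2L] || r[1L] < 0L)
      bad(f, "must be a nonempty nonnegative integer interval [lo, hi]")
  }
  for (f in c("deliveryBurstProb", "wearActiveProb", "nonadherenceProb")) {
    p <- cfg[[f]]
    if (is.na(p) || p < 0 || p > 1) bad(f, "must be a probability in [0, 1]")
  }
  if (is.na(cfg$deliveryBurstScale) || cfg$deliveryBurstScale <= 0)
    bad("deliveryBurstScale", "must be positive")
  w <- cfg$wakeWindow
  if (length(w) != 2L || anyNA(w) || w[1L] >= w[2L] || w[1L] < 0L || w[2L] > 1440L)
    bad("wakeWindow", "must be an interval inside [0, 1440)")
  if (is.na(cfg$wearIntensityPeak) || cfg$wearIntensityPeak <= 0)
    bad("wearIntensityPeak", "must be positive")
  if (!cfg$epochSeconds %in% c(1L, 5L, 10L, 15L, 30L, 60L))
    bad("epochSeconds", "must be one of 1, 5, 10, 15, 30, 60")
  invisible(TRUE)
}

# One delivery day: per-minute vector-magnitude jolts, returned as a
# 1440 x 3 integer matrix. Each jolt puts the same rounded exponential
# count on a random nonempty subset of axes.
.sim_delivery_day <- function(cfg) {
  cts <- matrix(0L, 1440L, 3L)
  hit <- which(stats::runif(1440L) < cfg$deliveryBurstProb)
  for (m in hit) {
    v <- as.integer(round(stats::rexp(1L, rate = 1 / cfg$deliveryBurstScale)))
    axes <- sample.int(3L, sample.int(3L, 1L))
    cts[m, axes] <- v
  }
  cts
}

# One wear day: waking minutes are active with probability `activeProb`;
# active vector-magnitude counts are Poisson with a raised-cosine diurnal
# intensity peaking mid-window. The squared magnitude is split across axes
# with Dirichlet(1,1,1) weights so per-axis and VM features stay consistent.
.sim_wear_day <- function(cfg, activeProb) {
  cts <- matrix(0L, 1440L, 3L)
  w0 <- cfg$wakeWindow[1L]; w1 <- cfg$wakeWindow[2L]
  wake <- (w0 + 1L):w1
  act <- wake[stats::runif(length(wake)) < activeProb]
  if (length(act)) {
    phase <- (act - 1L - w0) / (w1 - w0)
    lambda <- cfg$wearIntensityPeak * 0.5 * (1 - cos(2 * pi * phase))
    vm <- stats::rpois(length(act), lambda)
    g <- matrix(stats::rgamma(length(act) * 3L, shape = 1), ncol = 3L)
    wts <- sqrt(g / rowSums(g))
    cts[act, ] <- matrix(as.integer(round(wts * vm)), ncol = 3L)
  }
  cts
}

# Spread 1-min counts over sub-minute epochs (multinomial split), used when
# epochSeconds < 60. Returns an (1440 * k) x 3 matrix, k epochs per minute.
.split_subepochs <- function(cts, epochSeconds) {
  k <- 60L %/% epochSeconds
  out <- matrix(0L, nrow(cts) * k, 3L)
  nz <- which(rowSums(cts) > 0L)
  for (m in nz) for (a in 1:3) if (cts[m, a] > 0L) {
    out[((m - 1L) * k + 1L):(m * k), a] <-
      as.integer(stats::rmultinom(1L, cts[m, a], rep(1, k)))
  }
  out
}

#' Simulate one labeled assessment
#'
#' Draws one mailed-device assessment under the current RNG state: a block
#' of outbound delivery days (label 1), a truncated-Poisson number of wear
#' days (label 0, each non-adherent with probability `nonadherenceProb`),
#' and a block of return delivery days (label 1). With
#' `truncateFirstLast = TRUE` the first day starts and the last day ends at
#' a uniformly random minute, mimicking mid-day device activation and
#' deactivation.
#'
#' Call [set.seed()] (or use [simulateDataset()], which derives per-
#' assessment seeds from the config seed) for reproducibility.
#'
#' @param cfg a [simConfig()].
#' @param participantId,assessmentId identifiers for the assessment.
#' @param startDate first calendar date of the assessment.
#' @return a list with `series` (an [EpochSeries]) and `dayLabels` (a
#'   data.frame with one row per calendar date: `participant_id`,
#'   `assessment_id`, `date`, `label` (0 wear / 1 delivery), `adherent`).
#' @export
simulateAssessment <- function(cfg, participantId, assessmentId,
                               startDate = as.Date("2020-01-06")) {
  stopifnot(inherits(cfg, "SimConfig"))
  nPre <- sample(cfg$preDeliveryDaysRange[1L]:cfg$preDeliveryDaysRange[2L], 1L)
  nPost <- sample(cfg$postDeliveryDaysRange[1L]:cfg$postDeliveryDaysRange[2L], 1L)
  nWear <- max(1L, stats::rpois(1L, cfg$wearDaysMean))
  labels <- c(rep(1L, nPre), rep(0L, nWear), rep(1L, nPost))
  adherent <- rep(NA, length(labels))
  adherent[labels == 0L] <- stats::runif(nWear) >= cfg$nonadherenceProb

  days <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    days[[i]] <- if (labels[i] == 1L) .sim_delivery_day(cfg)
    else .sim_wear_day(cfg, cfg$wearActiveProb * if (adherent[i]) 1 else 0.05)
  }
  cts <- do.call(rbind, days)
  k <- 60L %/% cfg$epochSeconds
  if (k > 1L) cts <- .split_subepochs(cts, cfg$epochSeconds)
  nDays <- length(labels)
  epoch0 <- as.POSIXct(as.POSIXlt(startDate, tz = "UTC"), tz = "UTC")
  time <- epoch0 + cfg$epochSeconds * (seq_len(nDays * 1440L * k) - 1L)

  keep <- rep(TRUE, length(time))
  if (cfg$truncateFirstLast && nDays >= 2L) {
    startMin <- sample(0:1439, 1L)
    endMin <- sample(0:1439, 1L)
    keep[seq_len(startMin * k)] <- FALSE
    lastStart <- (nDays - 1L) * 1440L * k
    if (endMin < 1439L)
      keep[(lastStart + (endMin + 1L) * k + 1L):length(keep)] <- FALSE
  }
  series <- epochSeries(participantId, assessmentId, time[keep],
                        cts[keep, , drop = FALSE], cfg$epochSeconds)
  list(series = series,
       dayLabels = data.frame(
         participant_id = as.character(participantId),
         assessment_id = as.character(assessmentId),
         date = startDate + seq_len(nDays) - 1L,
         label = labels,
         adherent = adherent))
}

#' Simulate a full labeled dataset
#'
#' Generates `nParticipants x assessmentsPerParticipant` assessments with
#' unique identifiers, deterministic under the config seed. Assessments of
#' the same participant are spaced 60 days apart.
#'
#' @param cfg a [simConfig()].
#' @return a list with `assessments` (list of [simulateAssessment()]
#'   results), `labels` (all day labels, row-bound) and `manifest` (a list
#'   with counts per assessment).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  ids <- expand.grid(p = seq_len(cfg$nParticipants),
                     a = seq_len(cfg$assessmentsPerParticipant))
  ids <- ids[order(ids$p, ids$a), , drop = FALSE]
  assessments <- vector("list", nrow(ids))
  for (i in seq_len(nrow(ids))) {
    pid <- sprintf("P%03d", ids$p[i])
    aid <- sprintf("A%d", ids$a[i])
    assessments[[i]] <- with_seed(
      derive_seed(cfg$seed, i),
      simulateAssessment(cfg, pid, aid,
                         startDate = as.Date("2020-01-06") + (ids$a[i] - 1L) * 60L))
  }
  names(assessments) <- vapply(assessments, function(a)
    paste(a$series@participantId, a$series@assessmentId, sep = ":"), "")
  labels <- do.call(rbind, lapply(assessments, `[[`, "dayLabels"))
  rownames(labels) <- NULL
  manifest <- list(
    nParticipants = cfg$nParticipants,
    nAssessments = length(assessments),
    seed = cfg$seed,
    perAssessment = data.frame(
      participant_id = labels$participant_id[!duplicated(paste(labels$participant_id, labels$assessment_id))],
      assessment_id = labels$assessment_id[!duplicated(paste(labels$participant_id, labels$assessment_id))],
      nDays = as.vector(tapply(labels$label, paste(labels$participant_id, labels$assessment_id),
                               length)[unique(paste(labels$participant_id, labels$assessment_id))]),
      nDelivery = as.vector(tapply(labels$label, paste(labels$participant_id, labels$assessment_id),
                                   sum)[unique(paste(labels$participant_id, labels$assessment_id))]),
      row.names = NULL))
  list(assessments = assessments, labels = labels, manifest = manifest)
}

#' Write a simulated dataset to disk
#'
#' Writes `epochs.csv` (ISO-8601 timestamps, ids, x/y/z counts),
#' `labels.csv` (one row per day) and `manifest.json` into `dir`.
#'
#' @param dataset result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEpochCsv(lapply(dataset$assessments, `[[`, "series"),
                file.path(dir, "epochs.csv"))
  lab <- dataset$labels
  lab$date <- format(lab$date)
  data.table::fwrite(lab, file.path(dir, "labels.csv"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a day-label CSV
#'
#' @param path CSV with columns `participant_id`, `assessment_id`, `date`,
#'   `label` and optionally `adherent`.
#' @return a data.frame with `date` parsed as Date.
#' @export
readDayLabels <- function(path) {
  if (!file.exists(path)) wd_schema_error(sprintf("file not found: %s", path))
  lab <- as.data.frame(data.table::fread(path))
  need <- c("participant_id", "assessment_id", "date", "label")
  missing <- setdiff(need, names(lab))
  if (length(missing))
    wd_schema_error(sprintf("label file lacks column(s): %s",
                            paste(missing, collapse = ", ")))
  lab$date <- as.Date(lab$date)
  if (!all(lab$label %in% c(0L, 1L)))
    wd_integrity_error("labels must be 0 (wear) or 1 (delivery)")
  lab
}
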