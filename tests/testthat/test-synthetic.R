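test_that("config validation names the offending field", {
  expect_error(simConfig(nParticipants = 0), class = "wearday_config_error")
  expect_error(simConfig(deliveryBurstProb = 1.5), "deliveryBurstProb",
               class = "wearday_config_error")
  expect_error(simConfig(wakeWindow = c(100, 1500)), "wakeWindow",
               class = "wearday_config_error")
  expect_error(simConfig(preDeliveryDaysRange = c(5, 2)),
               "preDeliveryDaysRange", class = "wearday_config_error")
  expect_error(simConfig(epochSeconds = 7), "epochSeconds",
               class = "wearday_config_error")
})

test_that("zero burst probability gives all-zero delivery days", {
  cfg <- simConfig(nParticipants = 1, assessmentsPerParticipant = 1,
                   deliveryBurstProb = 0, truncateFirstLast = FALSE, seed = 3)
  set.seed(3)
  a <- simulateAssessment(cfg, "P1", "A1")
  da <- segmentDays(a$series, a$dayLabels)
  vm <- vectorMagnitude(da)
  delivery <- dayLabels(da) == 1L
  expect_gt(sum(delivery), 0)
  expect_true(all(vm[, delivery] == 0))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simConfig(nParticipants = 2, seed = 11)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(lapply(d1$assessments, function(a) a$series@counts),
                   lapply(d2$assessments, function(a) a$series@counts))
  expect_identical(d1$labels, d2$labels)
  d3 <- simulateDataset(simConfig(nParticipants = 2, seed = 12))
  expect_false(identical(d1$labels$label, d3$labels$label))
})

test_that("every date in the series has exactly one label entry", {
  cfg <- simConfig(nParticipants = 3, seed = 5)
  ds <- simulateDataset(cfg)
  for (a in ds$assessments) {
    dates <- unique(as.Date(floor(as.numeric(a$series@time) / 86400),
                            origin = "1970-01-01"))
    expect_setequal(format(dates), format(a$dayLabels$date))
    expect_false(anyDuplicated(a$dayLabels$date) > 0)
  }
})

test_that("untruncated assessments have exactly 1440 rows per day", {
  cfg <- simConfig(nParticipants = 1, truncateFirstLast = FALSE, seed = 2)
  set.seed(2)
  a <- simulateAssessment(cfg, "P1", "A1")
  expect_identical(nrow(a$series@counts) %% 1440L, 0L)
  expect_identical(nrow(a$series@counts) %/% 1440L, nrow(a$dayLabels))
})

test_that("dataset size and ids follow the config", {
  ds <- simulateDataset(simConfig(nParticipants = 3,
                                  assessmentsPerParticipant = 2, seed = 9))
  expect_length(ds$assessments, 6L)
  pids <- vapply(ds$assessments, function(a) a$series@participantId, "")
  expect_length(unique(pids), 3L)
  expect_false(anyDuplicated(names(ds$assessments)) > 0)
})

test_that("delivery-day burst rate matches the Bernoulli model", {
  # ~1000 delivery days; mean fraction of nonzero minutes should sit within
  # 3 standard errors of the per-minute burst probability.
  cfg <- simConfig(nParticipants = 100, assessmentsPerParticipant = 1,
                   truncateFirstLast = FALSE, seed = 21)
  ds <- simulateDataset(cfg)
  fracs <- unlist(lapply(ds$assessments, function(a) {
    da <- segmentDays(a$series, a$dayLabels)
    vm <- vectorMagnitude(da)
    del <- dayLabels(da) == 1L
    colSums(vm[, del, drop = FALSE] > 0) / 1440
  }))
  expect_gt(length(fracs), 900)
  p <- cfg$deliveryBurstProb
  se <- sqrt(p * (1 - p) / 1440 / length(fracs))
  expect_lt(abs(mean(fracs) - p), 3 * se)
})

test_that("wear-day count per assessment averages near its mean", {
  cfg <- simConfig(nParticipants = 200, assessmentsPerParticipant = 1,
                   seed = 31)
  ds <- simulateDataset(cfg)
  wear <- tapply(ds$labels$label == 0L,
                 paste(ds$labels$participant_id, ds$labels$assessment_id), sum)
  m <- mean(wear)
  expect_gt(m, 6)
  expect_lt(m, 8)
})

test_that("adherent wear days are far more active than delivery days", {
  cfg <- simConfig(nParticipants = 30, assessmentsPerParticipant = 1,
                   truncateFirstLast = FALSE, seed = 41)
  ds <- simulateDataset(cfg)
  da <- segmentDataset(ds)
  ds_sum <- daySummary(da)
  lab <- dayLabels(da)
  adh <- SummarizedExperiment::colData(da)$adherent
  wearTotals <- ds_sum$totalVm[lab == 0L & adh %in% TRUE]
  delTotals <- ds_sum$totalVm[lab == 1L]
  expect_gte(length(wearTotals), 100)
  expect_gte(length(delTotals), 100)
  expect_gt(mean(wearTotals), mean(delTotals))
})

test_that("sub-minute simulation conserves counts through collapsing", {
  cfg <- simConfig(nParticipants = 1, assessmentsPerParticipant = 1,
                   epochSeconds = 10L, truncateFirstLast = FALSE, seed = 8)
  set.seed(8)
  a <- simulateAssessment(cfg, "P1", "A1")
  collapsed <- collapseToMinute(a$series)
  expect_identical(epochSeconds(collapsed), 60L)
  expect_identical(colSums(epochCounts(collapsed)), colSums(epochCounts(a$series)))
})
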