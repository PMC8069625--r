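test_that("boundary days are padded from midnight / to midnight", {
  # starts 10:00 -> minutes 0..599 of the first day are padded
  es <- flat_series(startMin = 600L, nMinutes = 1440L)
  da <- segmentDays(es)
  expect_identical(ncol(da), 2L)
  expect_identical(sum(paddedMask(da)[, 1]), 600L)
  expect_true(all(which(paddedMask(da)[, 1]) == 1:600))

  # exactly one full day: a single unpadded column
  full <- segmentDays(flat_series(startMin = 0L, nMinutes = 1440L))
  expect_identical(ncol(full), 1L)
  expect_false(any(paddedMask(full)))

  # ends 22:00 -> minutes 1320..1439 of the last day are padded
  es2 <- flat_series(startMin = 0L, nMinutes = 1440L + 1320L)
  da2 <- segmentDays(es2)
  expect_identical(which(paddedMask(da2)[, 2]), 1321:1440)
})

test_that("padded minutes hold zero counts and labels attach by date", {
  es <- flat_series(startMin = 300L, nMinutes = 2000L, counts = c(3L, 4L, 0L))
  lab <- data.frame(participant_id = "P1", assessment_id = "A1",
                    date = as.Date("2020-01-06") + 0:1, label = c(1L, 0L),
                    adherent = c(NA, TRUE))
  da <- segmentDays(es, lab)
  expect_identical(dayLabels(da), c(1L, 0L))
  a <- SummarizedExperiment::assay(da, "x")
  expect_true(all(a[paddedMask(da)] == 0))
  expect_error(validObject(da), NA)
})

test_that("vector magnitude follows the Euclidean norm", {
  m <- matrix(0L, 1440L, 3L)
  m[1, ] <- c(3L, 4L, 0L)
  m[2, ] <- c(1L, 1L, 1L)
  da <- make_day_array(list(m), labels = 1L)
  vm <- vectorMagnitude(da)
  expect_equal(unname(vm[1, 1]), 5)
  expect_equal(unname(vm[2, 1]), sqrt(3))
  expect_true(all(vm[3:1440, 1] == 0))
})

test_that("daySummary counts only unpadded movement", {
  # 12 minutes of (3,4,0) -> total 60, active 12
  da <- make_day_array(list(day_counts(12L, 5L)), labels = 1L)
  s <- daySummary(da)
  expect_equal(s$totalVm, 60)
  expect_equal(s$activeMinutes, 12)

  # fully padded day: zero everything
  pad <- matrix(TRUE, 1440L, 1L)
  da0 <- make_day_array(list(matrix(0L, 1440L, 3L)), labels = 1L, padded = pad)
  expect_equal(daySummary(da0)$totalVm, 0)
  expect_equal(daySummary(da0)$activeMinutes, 0)

  # padding excluded: same counts, padded elsewhere, identical summary
  halfpad <- matrix(FALSE, 1440L, 1L)
  halfpad[1:100, 1] <- TRUE   # below the active block, which starts at 200
  da1 <- make_day_array(list(day_counts(12L, 5L)), labels = 1L, padded = halfpad)
  expect_equal(daySummary(da1), daySummary(da), ignore_attr = TRUE)
})

test_that("minimal processing is the identity with provenance", {
  da <- make_day_array(replicate(10, day_counts(20L, 10L), simplify = FALSE),
                       labels = rep(c(0L, 1L), 5))
  out <- applyMinimalProcessing(da)
  expect_identical(ncol(out), 10L)
  expect_identical(S4Vectors::metadata(out)$processing, "minimal")
  expect_identical(SummarizedExperiment::assay(out, "x"),
                   SummarizedExperiment::assay(da, "x"))
})

test_that("full processing applies the three rules at their boundaries", {
  # days straddling the 5000-count, 10-minute and 120-minute rules at +/-1
  counts <- list(
    del_count_lo  = day_counts(30L, 166L),   # total 4980 -> count rule
    del_count_hi  = day_counts(30L, 167L),   # total 5010, active 30 -> kept
    del_move_lo   = day_counts(9L, 600L),    # total 5400, active 9  -> movement
    del_move_hi   = day_counts(10L, 600L),   # total 6000, active 10 -> kept
    wear_adh_lo   = day_counts(119L, 50L),   # total 5950, active 119 -> adherence
    wear_adh_hi   = day_counts(121L, 50L),   # total 6050, active 121 -> kept
    del_total_lo  = day_counts(833L, 6L),    # total 4998 -> count rule
    del_total_hi  = day_counts(1000L, 5L),   # total 5000 -> kept (rule is strict <)
    wear_total_lo = day_counts(999L, 5L),    # wear, total 4995 -> count rule first
    wear_ok       = day_counts(300L, 100L),  # comfortably retained wear day
    del_zero      = day_counts(0L, 0L),      # empty delivery day -> count rule
    wear_move_lo  = day_counts(9L, 700L)     # wear, total 6300, active 9 -> movement
  )
  labels <- c(1L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  da <- make_day_array(counts, labels)
  out <- applyFullProcessing(da)
  rep <- removalReport(out)

  survivors <- SummarizedExperiment::colData(out)$date
  expect_identical(sort(as.integer(survivors - as.Date("2020-01-06")) + 1L),
                   c(2L, 4L, 6L, 8L, 10L))
  expect_identical(nrow(rep), 7L)
  byDay <- setNames(rep$rule, format(rep$date))
  d0 <- as.Date("2020-01-06")
  expect_identical(unname(byDay[format(d0 + 0)]), "total_counts")
  expect_identical(unname(byDay[format(d0 + 2)]), "movement_minutes")
  expect_identical(unname(byDay[format(d0 + 4)]), "wear_adherence")
  expect_identical(unname(byDay[format(d0 + 6)]), "total_counts")
  expect_identical(unname(byDay[format(d0 + 8)]), "total_counts")
  expect_identical(unname(byDay[format(d0 + 10)]), "total_counts")
  expect_identical(unname(byDay[format(d0 + 11)]), "movement_minutes")
})

test_that("full processing demands labels", {
  da <- make_day_array(list(day_counts(300L, 100L)), labels = NA_integer_)
  expect_error(applyFullProcessing(da), class = "wearday_contract_error")
})

test_that("fully processed days are a subset of minimally processed days", {
  ds <- simulateDataset(simConfig(nParticipants = 5, seed = 17))
  da <- applyMinimalProcessing(segmentDataset(ds))
  full <- applyFullProcessing(da)
  expect_true(all(colnames(full) %in% colnames(da)))
  expect_identical(ncol(full) + nrow(removalReport(full)), ncol(da))
})

test_that("full processing removes delivery days at a higher rate than wear", {
  ds <- simulateDataset(simConfig(nParticipants = 10, seed = 19))
  da <- segmentDataset(ds)
  lab <- dayLabels(da)
  full <- applyFullProcessing(da)
  labFull <- dayLabels(full)
  removedDel <- (sum(lab == 1L) - sum(labFull == 1L)) / sum(lab == 1L)
  removedWear <- (sum(lab == 0L) - sum(labFull == 0L)) / sum(lab == 0L)
  expect_gt(removedDel, removedWear)
})

test_that("axis-sum variant of the count rule is available", {
  m <- matrix(0L, 1440L, 3L)
  m[1:20, ] <- 100L  # axis-sum total 6000; VM total 20*100*sqrt(3) = 3464
  da <- make_day_array(list(m), labels = 1L)
  expect_identical(ncol(applyFullProcessing(da, statistic = "vm")), 0L)
  expect_identical(ncol(applyFullProcessing(da, statistic = "axis_sum")), 1L)
})
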