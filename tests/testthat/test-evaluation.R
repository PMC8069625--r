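test_that("Monte Carlo splits are grouped, sized and reproducible", {
  ids <- sprintf("P%02d", 1:10)
  sp <- makeMcSplits(ids, nReps = 5L, testFraction = 0.3, masterSeed = 1)
  for (r in sp@reps) {
    expect_length(r$test, 3L)
    expect_length(r$train, 7L)
    expect_length(intersect(r$train, r$test), 0L)
    expect_setequal(c(r$train, r$test), ids)
  }
  sp2 <- makeMcSplits(ids, nReps = 5L, testFraction = 0.3, masterSeed = 1)
  expect_identical(sp@reps, sp2@reps)
  # repetitions differ from one another (random resampling, not one split)
  tests <- vapply(sp@reps, function(r) paste(sort(r$test), collapse = ","), "")
  expect_gt(length(unique(tests)), 1L)

  expect_error(makeMcSplits("P1"), class = "wearday_config_error")
  expect_error(makeMcSplits(ids, testFraction = 0.01),
               class = "wearday_config_error")
})

test_that("metrics match hand-counted confusion matrices", {
  p <- data.frame(f = c(rep(0.9, 9), 0.1, rep(0.8, 2), rep(0.2, 8)),
                  o = c(rep(1, 10), rep(0, 10)))
  expect_equal(sensitivity(p), 0.9)   # TP 9, FN 1
  expect_equal(ppv(p), 9 / 11)        # FP 2
  expect_equal(f1Score(1, 1), 1)
  expect_equal(f1Score(0.9, 0.8), 2 * 0.9 * 0.8 / 1.7)

  set.seed(55)
  for (i in 1:50) {
    f <- runif(40)
    o <- rbinom(40, 1, 0.4)
    pr <- data.frame(f = f, o = o)
    cm <- oracle_confusion(f, o)
    s <- suppressWarnings(sensitivity(pr))
    v <- suppressWarnings(ppv(pr))
    if (cm$tp + cm$fn > 0) expect_equal(s, cm$tp / (cm$tp + cm$fn))
    if (cm$tp + cm$fp > 0) expect_equal(v, cm$tp / (cm$tp + cm$fp))
    if (!is.na(s) && !is.na(v) && (s + v) > 0)
      expect_true(f1Score(s, v) >= min(s, v) - 1e-12 &&
                    f1Score(s, v) <= max(s, v) + 1e-12)
  }
})

test_that("Brier score follows its closed forms", {
  perfect <- data.frame(f = c(1, 0, 1), o = c(1, 0, 1))
  expect_equal(brierScore(perfect), 0)
  third <- data.frame(f = c(1, 0, 1), o = c(1, 0, 0))
  expect_equal(brierScore(third), 1 / 3)
  const <- data.frame(f = rep(0.5, 20), o = rbinom(20, 1, 0.7))
  expect_equal(brierScore(const), 0.25)
})

test_that("undefined metrics are NA with a warning, not imputed", {
  noPos <- data.frame(f = c(0.1, 0.2), o = c(0, 0))
  expect_warning(s <- sensitivity(noPos), "undefined")
  expect_true(is.na(s))
  noPredPos <- data.frame(f = c(0.1, 0.2), o = c(1, 0))
  expect_warning(v <- ppv(noPredPos), "undefined")
  expect_true(is.na(v))
  expect_warning(z <- f1Score(0, 0), "0")
  expect_identical(z, 0)
})

test_that("runCv keeps participants grouped and scores the held-out days", {
  da <- separable_day_array(perClass = 15L, seed = 44)
  pid <- SummarizedExperiment::colData(da)$participantId
  plan <- makeMcSplits(pid, nReps = 3L, masterSeed = 7)

  rep <- runCv(da, modelSpec("oracle"), plan, mode = "minimal")
  s <- cvSummary(rep)
  expect_equal(s$mean[s$metric == "f1"], 1)
  expect_equal(s$mean[s$metric == "brier"], 0)

  repC <- runCv(da, modelSpec("constant", p = 0.5), plan, mode = "minimal")
  expect_equal(cvSummary(repC)$mean[cvSummary(repC)$metric == "brier"], 0.25)

  repRf <- runCv(da, modelSpec("rf", nTrees = 100L, seed = 1), plan,
                 mode = "minimal")
  expect_identical(nrow(repRf@perRep), 3L)
  # the test day count of each repetition equals the days of its test set
  for (r in seq_len(3)) {
    expect_identical(repRf@perRep$nTest[r],
                     sum(pid %in% plan@reps[[r]]$test))
  }
})

test_that("report metrics equal metrics recomputed from raw predictions", {
  da <- separable_day_array(perClass = 12L, seed = 46)
  pid <- SummarizedExperiment::colData(da)$participantId
  plan <- makeMcSplits(pid, nReps = 2L, masterSeed = 3)
  spec <- modelSpec("rf", nTrees = 100L, seed = 2)
  rep <- runCv(da, spec, plan, mode = "minimal")
  for (r in 1:2) {
    repSpec <- spec
    repSpec@seed <- wearday:::derive_seed(spec@seed, 100L + r)
    train <- new("DayArray", da[, pid %in% plan@reps[[r]]$train])
    test <- new("DayArray", da[, pid %in% plan@reps[[r]]$test])
    preds <- predictProb(fitModel(repSpec, train), test)
    expect_equal(rep@perRep$brier[r], brierScore(preds))
    expect_equal(rep@perRep$sensitivity[r],
                 suppressWarnings(sensitivity(preds)))
  }
})

test_that("cross-validation report serializes to JSON", {
  da <- separable_day_array(perClass = 10L, seed = 47)
  plan <- makeMcSplits(SummarizedExperiment::colData(da)$participantId,
                       nReps = 2L, masterSeed = 5)
  rep <- runCv(da, modelSpec("oracle"), plan, mode = "minimal")
  path <- withr::local_tempfile(fileext = ".json")
  writeCvReport(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$family, "oracle")
  expect_equal(nrow(back$perRepetition), 2L)
})
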