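test_that("model specs validate family and hyperparameters", {
  expect_error(modelSpec("boost"), class = "wearday_config_error")
  expect_error(modelSpec("rf", nTrees = 0), class = "wearday_config_error")
  expect_error(modelSpec("rf", bogus = 1), class = "wearday_config_error")
  expect_error(modelSpec("crnn", filters = c(8L, 16L), pool = 4L),
               class = "wearday_config_error")
  s <- modelSpec("rf", seed = 5)
  expect_identical(s@params$nTrees, 500L)
  expect_identical(s@params$nodeSize, 1L)
})

test_that("random forest uses floor(log2(p)) features per split", {
  da <- separable_day_array(perClass = 20L, seed = 1)
  m <- fitModel(modelSpec("rf", seed = 1), da)
  expect_identical(m@meta$mtry, 3L)  # floor(log2(8))
  expect_identical(m@fit$rf$ntree, 500L)
})

test_that("random forest separates the toy problem and is seed-stable", {
  da <- separable_day_array(perClass = 20L, seed = 1)
  m <- fitModel(modelSpec("rf", seed = 9), da)
  p <- predictProb(m, da)
  sens <- sensitivity(p)
  prec <- ppv(p)
  expect_identical(f1Score(sens, prec), 1)
  m2 <- fitModel(modelSpec("rf", seed = 9), da)
  expect_identical(predictProb(m2, da)$f, p$f)

  oneClass <- da[, dayLabels(da) == 1L]
  expect_error(fitModel(modelSpec("rf", seed = 1), new("DayArray", oneClass)),
               class = "wearday_contract_error")
})

test_that("logistic-RCS predictions are the inverse logit of the design", {
  da <- separable_day_array(perClass = 20L, seed = 2)
  m <- fitModel(modelSpec("glm_rcs", seed = 1), da)
  p <- predictProb(m, da)
  expect_true(all(p$f >= 0 & p$f <= 1))

  # zero coefficients -> probability 0.5 everywhere
  m0 <- m
  m0@fit$beta[] <- 0
  expect_true(all(predictProb(m0, da)$f == 0.5))

  # ridge-stabilized fit beats the intercept-only model in log-loss
  y <- p$o
  eps <- 1e-12
  ll <- -mean(y * log(p$f + eps) + (1 - y) * log(1 - p$f + eps))
  p0 <- mean(y)
  ll0 <- -mean(y * log(p0) + (1 - y) * log(1 - p0))
  expect_lt(ll, ll0)
})

test_that("mixed model defaults to the population intercept off-sample", {
  da <- separable_day_array(perClass = 16L, seed = 3)
  m <- suppressWarnings(fitModel(modelSpec("glmm_rcs", seed = 1), da))
  p <- predictProb(m, da)
  # predictions use fixed effects only, so recomputing by hand must agree
  feats <- extractFeatures(da)
  fm <- wearday:::.feature_matrix(applyScaler(m@scaler, feats))
  X <- wearday:::rcs_expand(fm, m@knots)
  expect_equal(p$f, unname(plogis(drop(cbind(1, X) %*% m@fit$beta))),
               tolerance = 1e-10)
})

test_that("mlp trains to valid probabilities with decreasing loss", {
  da <- separable_day_array(perClass = 20L, seed = 4)
  m <- fitModel(modelSpec("mlp", seed = 2), da)
  p <- predictProb(m, da)
  expect_true(all(p$f > 0 & p$f < 1))
  hist <- m@fit$history
  expect_lt(hist[length(hist)], hist[1])
  m2 <- fitModel(modelSpec("mlp", seed = 2), da)
  expect_identical(m2@fit$net, m@fit$net)
})

test_that("raw networks share the contract and honor shapes", {
  da <- separable_day_array(perClass = 10L, seed = 5)
  for (fam in c("cnn", "crnn")) {
    spec <- modelSpec(fam, epochs = 2L, seed = 3)
    m <- fitModel(spec, da)
    p <- predictProb(m, da)
    expect_identical(nrow(p), ncol(da))
    expect_true(all(p$f > 0 & p$f < 1))
  }
  # rnn at reduced epochs to keep the sequence loop cheap
  mr <- fitModel(modelSpec("rnn", epochs = 1L, seed = 3), da)
  pr <- predictProb(mr, da)
  expect_true(all(pr$f > 0 & pr$f < 1))
})

test_that("the crnn pool stack sets the recurrent sequence length", {
  expect_identical(wearday:::nn_crnn_seq_length(1440L, c(2L, 2L, 2L)), 180L)
  expect_identical(wearday:::nn_crnn_seq_length(1440L, c(4L, 4L)), 90L)
})

test_that("feature models ignore axis permutations that preserve VM", {
  da <- separable_day_array(perClass = 10L, seed = 6)
  a <- SummarizedExperiment::assays(da)
  perm <- da
  SummarizedExperiment::assays(perm) <-
    list(x = a$z, y = a$x, z = a$y, padded = a$padded)
  m <- fitModel(modelSpec("rf", seed = 4), da)
  expect_identical(predictProb(m, da)$f, predictProb(m, perm)$f)
})

test_that("models survive a save/load round trip", {
  da <- separable_day_array(perClass = 10L, seed = 8)
  dir <- withr::local_tempdir()
  for (fam in c("rf", "glm_rcs")) {
    m <- fitModel(modelSpec(fam, seed = 2), da)
    saveModel(m, file.path(dir, fam))
    back <- loadModel(file.path(dir, fam))
    expect_identical(back@spec@family, fam)
    expect_equal(predictProb(back, da)$f, predictProb(m, da)$f,
                 tolerance = 1e-12)
  }
})

test_that("baseline families provide closed-form checks", {
  da <- separable_day_array(perClass = 10L, seed = 9)
  or <- fitModel(modelSpec("oracle"), da)
  p <- predictProb(or, da)
  expect_identical(p$f, as.numeric(p$o))
  cst <- fitModel(modelSpec("constant", p = 0.5), da)
  pc <- predictProb(cst, da)
  expect_equal(brierScore(pc), 0.25)
})
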