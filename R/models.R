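# The seven day-classifier families behind a single fit/predict contract.
# Feature-input families: rf, glm_rcs, glmm_rcs, mlp. Raw-input families:
# cnn, rnn, crnn (standardized 1440 x 3 day arrays). Two testing baselines,
# "oracle" (forecasts the true label) and "constant" (forecasts `p`), share
# the contract so the cross-validation harness can be exercised in closed
# form.

.families <- c("rf", "glm_rcs", "glmm_rcs", "mlp", "cnn", "rnn", "crnn",
               "oracle", "constant")

#' Construct a model specification
#'
#' Validates family-specific hyperparameters at construction. Defaults:
#' * `rf` — `nTrees = 500`, `nodeSize = 1`, Gini splits, `mtry =
#'   floor(log2(p))` features per split (3 for the 8 standard features).
#' * `glm_rcs`, `glmm_rcs` — `nKnots = 3` restricted cubic spline per
#'   feature, `ridge = 1e-6` stabilizer (0 = pure maximum likelihood);
#'   the mixed model adds a participant random intercept.
#' * `mlp` — `hidden = c(32, 16)` ReLU layers on the 8 scaled features.
#' * `cnn` — conv blocks `filters = c(8, 16, 16)`, `kernel = 7`,
#'   `pool = c(4, 4, 2)`, global average pooling, sigmoid head.
#' * `rnn` — `units = 32` LSTM over the 1440-step, 3-channel sequence.
#' * `crnn` — conv blocks `filters = c(8, 16)`, `pool = c(4, 4)` feeding
#'   an `units = 32` LSTM.
#' All networks train with binary cross-entropy and Adam
#' (`lr = 0.001`) for `epochs = 10` at `batch = 32`.
#'
#' @param family one of `"rf"`, `"glm_rcs"`, `"glmm_rcs"`, `"mlp"`,
#'   `"cnn"`, `"rnn"`, `"crnn"`, `"oracle"`, `"constant"`.
#' @param ... family-specific hyperparameter overrides.
#' @param seed integer seed governing all stochastic parts of fitting.
#' @return a [ModelSpec].
#' @examples
#' modelSpec("rf", seed = 1)
#' modelSpec("crnn", units = 16, epochs = 5, seed = 1)
#' @export
modelSpec <- function(family, ..., seed = 1L) {
  if (!family %in% .families)
    wd_config_error(sprintf("unknown model family '%s'", family))
  defaults <- switch(family,
    rf = list(nTrees = 500L, nodeSize = 1L),
    glm_rcs = list(nKnots = 3L, ridge = 1e-6, maxit = 100L),
    glmm_rcs = list(nKnots = 3L, ridge = 1e-6),
    mlp = list(hidden = c(32L, 16L), epochs = 10L, batch = 32L, lr = 1e-3),
    cnn = list(filters = c(8L, 16L, 16L), kernel = 7L, pool = c(4L, 4L, 2L),
               epochs = 10L, batch = 32L, lr = 1e-3),
    rnn = list(units = 32L, epochs = 10L, batch = 32L, lr = 1e-3),
    crnn = list(filters = c(8L, 16L), kernel = 7L, pool = c(4L, 4L),
                units = 32L, epochs = 10L, batch = 32L, lr = 1e-3),
    oracle = list(),
    constant = list(p = 0.5))
  params <- utils::modifyList(defaults, list(...))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    wd_config_error(sprintf("unknown hyperparameter(s) for '%s': %s",
                            family, paste(unknown, collapse = ", ")))
  if (family == "rf" && (params$nTrees < 1L || params$nodeSize < 1L))
    wd_config_error("rf needs nTrees >= 1 and nodeSize >= 1")
  if (family %in% c("glm_rcs", "glmm_rcs") &&
      (params$nKnots < 3L || params$ridge < 0))
    wd_config_error("rcs models need nKnots >= 3 and ridge >= 0")
  if (family %in% c("cnn", "crnn") &&
      length(params$filters) != length(params$pool))
    wd_config_error("filters and pool must have the same length")
  if (family == "constant" && (params$p < 0 || params$p > 1))
    wd_config_error("constant family needs p in [0, 1]")
  new("ModelSpec", family = family, params = params, seed = as.integer(seed))
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s (seed %d)\n", object@family, object@seed))
})

setMethod("show", "WearModel", function(object) {
  cat(sprintf("WearModel: %s fitted on %s day(s), %s participant(s)\n",
              object@spec@family,
              object@meta$nDays %||% "?", object@meta$nParticipants %||% "?"))
})

.check_labels <- function(y) {
  if (anyNA(y)) wd_contract_error("training days must all be labeled 0/1")
  if (length(unique(y)) < 2L)
    wd_contract_error("degenerate training data: only one class present")
  as.integer(y)
}

.feature_matrix <- function(features) {
  as.matrix(features[, .feature_names, drop = FALSE])
}

# Stack the scaled per-axis day arrays into (days, 1440, 3).
.raw_array <- function(days) {
  a <- SummarizedExperiment::assays(days)
  n <- ncol(days)
  if (nrow(days) != 1440L)
    wd_contract_error(sprintf("day '%s' does not have 1440 minutes",
                              colnames(days)[1L]))
  out <- array(0, c(n, 1440L, 3L))
  out[, , 1L] <- t(a$x); out[, , 2L] <- t(a$y); out[, , 3L] <- t(a$z)
  out
}

#' @rdname fitModel
setMethod("fitModel", signature("ModelSpec", "DayArray"), function(spec, x, ...) {
  family <- spec@family
  cd <- SummarizedExperiment::colData(x)
  meta <- list(nDays = ncol(x),
               nParticipants = length(unique(cd$participantId)))

  if (family %in% c("oracle", "constant")) {
    return(new("WearModel", spec = spec, fit = NULL, scaler = NULL,
               knots = NULL, meta = meta))
  }
  y <- .check_labels(dayLabels(x))

  if (family %in% c("rf", "glm_rcs", "glmm_rcs", "mlp")) {
    features <- extractFeatures(x)
    scaler <- fitScaler(features)
    fm <- .feature_matrix(applyScaler(scaler, features))
    fit <- switch(family,
      rf = .fit_rf(fm, y, spec),
      glm_rcs = .fit_glm_rcs(fm, y, spec),
      glmm_rcs = .fit_glmm_rcs(fm, y, cd$participantId, spec),
      mlp = .fit_mlp(fm, y, spec))
    knots <- if (family %in% c("glm_rcs", "glmm_rcs")) fit$knots else NULL
    meta$mtry <- if (family == "rf") fit$mtry else NULL
    meta$epochsTrained <- if (family == "mlp") spec@params$epochs else NULL
    return(new("WearModel", spec = spec, fit = fit, scaler = scaler,
               knots = knots, meta = meta))
  }

  # raw-input networks
  scaler <- fitScaler(x)
  X <- applyScaler(scaler, .raw_array(x))
  net <- nn_build(family, spec@params, c(1440L, 3L), spec@seed)
  trained <- nn_train(net, X, y, epochs = spec@params$epochs,
                      batch = spec@params$batch, lr = spec@params$lr,
                      seed = derive_seed(spec@seed, 7L))
  meta$epochsTrained <- spec@params$epochs
  meta$finalLoss <- trained$history[length(trained$history)]
  new("WearModel", spec = spec, fit = trained$net, scaler = scaler,
      knots = NULL, meta = meta)
})

.fit_rf <- function(fm, y, spec) {
  mtry <- max(1L, as.integer(floor(log2(ncol(fm)))))
  fit <- with_seed(spec@seed,
    randomForest::randomForest(
      x = fm, y = factor(y, levels = c(0L, 1L)),
      ntree = spec@params$nTrees, mtry = mtry,
      nodesize = spec@params$nodeSize))
  list(rf = fit, mtry = mtry)
}

.fit_glm_rcs <- function(fm, y, spec) {
  knots <- rcs_fit_knots(fm, spec@params$nKnots)
  X <- rcs_expand(fm, knots)
  fit <- irls_logistic(X, y, ridge = spec@params$ridge,
                       maxit = spec@params$maxit)
  list(beta = fit$beta, knots = knots, iterations = fit$iterations)
}

.fit_glmm_rcs <- function(fm, y, participant, spec) {
  if (length(unique(participant)) < 2L)
    wd_contract_error("mixed model needs at least 2 participants")
  knots <- rcs_fit_knots(fm, spec@params$nKnots)
  X <- rcs_expand(fm, knots)
  colnames(X) <- paste0("V", seq_len(ncol(X)))      # syntactic names for the formula
  df <- data.frame(y = y, X, pid = factor(participant))
  form <- stats::as.formula(paste("y ~", paste(colnames(X), collapse = " + "),
                                  "+ (1 | pid)"))
  fit <- tryCatch(
    suppressMessages(lme4::glmer(form, data = df, family = stats::binomial,
                                 nAGQ = 1L,
                                 control = lme4::glmerControl(
                                   check.conv.singular = "ignore",
                                   calc.derivs = FALSE))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # Near-separated designs can make the mixed-model likelihood degenerate;
    # the variance component is then inestimable and the model collapses to
    # the fixed-effects logistic fit.
    warning("mixed-model fit failed (", conditionMessage(fit),
            "); falling back to the fixed-effects logistic model")
    fe <- irls_logistic(X, y, ridge = spec@params$ridge)
    return(list(glmm = NULL, beta = fe$beta, knots = knots,
                sdIntercept = NA_real_))
  }
  sdInt <- sqrt(unname(lme4::VarCorr(fit)$pid[1L]))
  if (sdInt < 1e-6)
    warning("random-intercept variance estimated at the boundary (0); ",
            "predictions equal the fixed-effects logistic model")
  list(glmm = fit, beta = lme4::fixef(fit), knots = knots, sdIntercept = sdInt)
}

.fit_mlp <- function(fm, y, spec) {
  net <- nn_build("mlp", spec@params, ncol(fm), spec@seed)
  trained <- nn_train(net, fm, y, epochs = spec@params$epochs,
                      batch = spec@params$batch, lr = spec@params$lr,
                      seed = derive_seed(spec@seed, 7L))
  trained
}

#' @rdname predictProb
setMethod("predictProb", signature("WearModel", "DayArray"), function(object, x, ...) {
  family <- object@spec@family
  cd <- SummarizedExperiment::colData(x)
  f <- switch(family,
    oracle = {
      if (anyNA(dayLabels(x)))
        wd_contract_error("oracle baseline needs labeled days")
      as.numeric(dayLabels(x))
    },
    constant = rep(object@spec@params$p, ncol(x)),
    rf = {
      fm <- .feature_matrix(applyScaler(object@scaler, extractFeatures(x)))
      unname(stats::predict(object@fit$rf, fm, type = "prob")[, "1"])
    },
    glm_rcs = {
      fm <- .feature_matrix(applyScaler(object@scaler, extractFeatures(x)))
      X <- rcs_expand(fm, object@knots)
      stats::plogis(drop(cbind(1, X) %*% object@fit$beta))
    },
    glmm_rcs = {
      # population-level prediction: unseen participants take random
      # intercept 0, i.e. the fixed-effects linear predictor only.
      fm <- .feature_matrix(applyScaler(object@scaler, extractFeatures(x)))
      X <- rcs_expand(fm, object@knots)
      stats::plogis(drop(cbind(1, X) %*% object@fit$beta))
    },
    mlp = {
      fm <- .feature_matrix(applyScaler(object@scaler, extractFeatures(x)))
      nn_predict(object@fit$net, fm)
    },
    {
      X <- applyScaler(object@scaler, .raw_array(x))
      nn_predict(object@fit, X)
    })
  data.frame(participantId = cd$participantId,
             assessmentId = cd$assessmentId,
             date = cd$date,
             f = f,
             o = as.integer(cd$label),
             row.names = NULL)
})

#' Save / load a fitted model directory
#'
#' Writes `spec.json` (family, hyperparameters, seed), `scaler.json`,
#' `knots.json` (spline families) and `fit.rds` (the opaque learned
#' parameters) into `dir`.
#'
#' @param model a [WearModel].
#' @param dir target directory (created if needed).
#' @return `dir` (save) or a [WearModel] (load).
#' @export
saveModel <- function(model, dir) {
  stopifnot(is(model, "WearModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(family = model@spec@family, params = model@spec@params,
         seed = model@spec@seed, meta = model@meta),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(model@scaler))
    jsonlite::write_json(
      list(kind = model@scaler@kind,
           center = as.list(model@scaler@center),
           scale = as.list(model@scaler@scale)),
      file.path(dir, "scaler.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(model@knots))
    jsonlite::write_json(model@knots, file.path(dir, "knots.json"),
                         digits = NA, null = "null")
  saveRDS(model@fit, file.path(dir, "fit.rds"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  sj <- jsonlite::read_json(file.path(dir, "spec.json"))
  spec <- do.call(modelSpec, c(list(family = sj$family), lapply(sj$params, function(p)
    if (is.list(p)) unlist(p) else p), list(seed = sj$seed)))
  scaler <- NULL
  if (file.exists(file.path(dir, "scaler.json"))) {
    scj <- jsonlite::read_json(file.path(dir, "scaler.json"))
    scaler <- new("DayScaler", kind = scj$kind,
                  center = unlist(scj$center), scale = unlist(scj$scale))
  }
  knots <- NULL
  if (file.exists(file.path(dir, "knots.json"))) {
    kj <- jsonlite::read_json(file.path(dir, "knots.json"), simplifyVector = TRUE)
    knots <- lapply(kj, function(k) if (length(k)) as.numeric(k) else NULL)
  }
  fit <- readRDS(file.path(dir, "fit.rds"))
  meta <- lapply(sj$meta, function(m) if (is.list(m)) unlist(m) else m)
  new("WearModel", spec = spec, fit = fit, scaler = scaler, knots = knots,
      meta = meta)
}
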