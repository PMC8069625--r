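#' Construct an EpochSeries
#'
#' @param participantId,assessmentId identifiers (length-1 character).
#' @param time POSIXct epoch start times, strictly increasing on a regular
#'   grid of `epochSeconds`.
#' @param counts numeric matrix (epochs x 3) of nonnegative integer counts;
#'   columns are taken as x, y, z.
#' @param epochSeconds epoch length in seconds.
#' @return an [EpochSeries].
#' @examples
#' t0 <- as.POSIXct("2020-01-06 10:00:00", tz = "UTC")
#' es <- epochSeries("P1", "A1", t0 + 60 * (0:5), matrix(1L, 6, 3), 60L)
#' epochSeconds(es)
#' @export
epochSeries <- function(participantId, assessmentId, time, counts,
                        epochSeconds = 60L) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  colnames(counts) <- c("x", "y", "z")
  new("EpochSeries",
      participantId = as.character(participantId),
      assessmentId = as.character(assessmentId),
      epochSeconds = as.integer(epochSeconds),
      time = as.POSIXct(time, tz = "UTC"),
      counts = counts)
}

#' @rdname EpochSeries-class
#' @aliases participantId,EpochSeries-method
setMethod("participantId", "EpochSeries", function(x) x@participantId)
#' @rdname EpochSeries-class
setMethod("assessmentId", "EpochSeries", function(x) x@assessmentId)
#' @rdname EpochSeries-class
setMethod("epochSeconds", "EpochSeries", function(x) x@epochSeconds)
#' @rdname EpochSeries-class
setMethod("epochCounts", "EpochSeries", function(x) x@counts)
#' @rdname EpochSeries-class
setMethod("epochTime", "EpochSeries", function(x) x@time)

setMethod("show", "EpochSeries", function(object) {
  n <- nrow(object@counts)
  cat(sprintf("EpochSeries: participant %s, assessment %s\n",
              object@participantId, object@assessmentId))
  cat(sprintf("  %d epochs of %d s", n, object@epochSeconds))
  if (n > 0L)
    cat(sprintf(", %s .. %s UTC",
                format(object@time[1L], "%Y-%m-%d %H:%M"),
                format(object@time[n], "%Y-%m-%d %H:%M")))
  cat("\n")
})

#' Read an epoch-count CSV
#'
#' Reads a timestamped per-epoch count file, validates it, and returns one
#' [EpochSeries] per (participant, assessment) pair found. Arbitrary header
#' names (e.g. `Axis1`/`Axis2`/`Axis3` from device exports) are supported
#' through `columnMap`.
#'
#' Validation is strict: a missing mapped column is a schema error; a
#' duplicated, out-of-order or gapped timestamp, or a negative count, is a
#' data-integrity error naming the first offending row. Gaps are never
#' silently zero-filled here — zero-padding is the explicit job of day
#' segmentation.
#'
#' @param path CSV file path.
#' @param columnMap named character vector mapping the roles
#'   `timestamp`, `participant`, `assessment`, `x`, `y`, `z` to the file's
#'   column names.
#' @param epochSeconds epoch length of the file, in seconds.
#' @return an [EpochSeries], or a named list of them when the file holds
#'   several (participant, assessment) pairs.
#' @export
readEpochCsv <- function(path,
                         columnMap = c(timestamp = "timestamp",
                                       participant = "participant_id",
                                       assessment = "assessment_id",
                                       x = "x", y = "y", z = "z"),
                         epochSeconds = 60L) {
  if (!file.exists(path)) wd_schema_error(sprintf("file not found: %s", path))
  need <- c("timestamp", "participant", "assessment", "x", "y", "z")
  if (!all(need %in% names(columnMap)))
    wd_config_error(sprintf("columnMap lacks roles: %s",
                            paste(setdiff(need, names(columnMap)), collapse = ", ")))
  hdr <- names(data.table::fread(path, nrows = 0L))
  missing <- setdiff(unname(columnMap[need]), hdr)
  if (length(missing))
    wd_schema_error(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  dt <- data.table::fread(path, colClasses = list(character = columnMap[["timestamp"]]))
  ts <- as.POSIXct(dt[[columnMap[["timestamp"]]]],
                   tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(ts))
    wd_integrity_error(sprintf("unparseable timestamp at row %d",
                               which(is.na(ts))[1L]))
  key <- paste(dt[[columnMap[["participant"]]]], dt[[columnMap[["assessment"]]]],
               sep = ":")
  out <- lapply(split(seq_len(nrow(dt)), key), function(idx) {
    idx <- idx[order(ts[idx])]
    cts <- cbind(x = dt[[columnMap[["x"]]]][idx],
                 y = dt[[columnMap[["y"]]]][idx],
                 z = dt[[columnMap[["z"]]]][idx])
    .validate_rows(ts[idx], cts, epochSeconds)
    epochSeries(dt[[columnMap[["participant"]]]][idx[1L]],
                dt[[columnMap[["assessment"]]]][idx[1L]],
                ts[idx], cts, epochSeconds)
  })
  if (length(out) == 1L) out[[1L]] else out
}

.validate_rows <- function(ts, cts, epochSeconds) {
  if (any(cts < 0)) {
    bad <- which(rowSums(cts < 0) > 0)[1L]
    wd_integrity_error(sprintf("negative count at row %d (%s)",
                               bad, format(ts[bad], "%Y-%m-%d %H:%M:%S")))
  }
  if (length(ts) > 1L) {
    d <- diff(as.numeric(ts))
    if (any(d == 0))
      wd_integrity_error(sprintf("duplicated timestamp at row %d (%s)",
                                 which(d == 0)[1L] + 1L,
                                 format(ts[which(d == 0)[1L] + 1L], "%Y-%m-%d %H:%M:%S")))
    if (any(abs(d - epochSeconds) > 1e-6)) {
      bad <- which(abs(d - epochSeconds) > 1e-6)[1L] + 1L
      wd_integrity_error(sprintf("gapped or irregular timestamps at row %d (%s)",
                                 bad, format(ts[bad], "%Y-%m-%d %H:%M:%S")))
    }
  }
  invisible(TRUE)
}

#' Write one or more EpochSeries to a CSV
#'
#' Inverse of [readEpochCsv()] with the default column map; timestamps are
#' written as ISO-8601 (UTC).
#'
#' @param x an [EpochSeries] or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEpochCsv <- function(x, path) {
  if (is(x, "EpochSeries")) x <- list(x)
  tabs <- lapply(x, function(es) {
    data.table::data.table(
      timestamp = format(es@time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      participant_id = es@participantId,
      assessment_id = es@assessmentId,
      x = es@counts[, "x"], y = es@counts[, "y"], z = es@counts[, "z"])
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' @rdname collapseToMinute
setMethod("collapseToMinute", "EpochSeries", function(x) {
  es <- x@epochSeconds
  if (60L %% es != 0L)
    wd_config_error(sprintf("epochSeconds = %d does not divide 60 s; cannot collapse", es))
  if (es == 60L) return(x)
  minute <- as.numeric(x@time) %/% 60 * 60
  cts <- rowsum(x@counts, group = minute, reorder = TRUE)
  epochSeries(x@participantId, x@assessmentId,
              as.POSIXct(as.numeric(rownames(cts)), origin = "1970-01-01", tz = "UTC"),
              cts, 60L)
})
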