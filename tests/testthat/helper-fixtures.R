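# Programmatic fixtures: hand-built DayArrays with known totals.

# A 1440 x 3 count matrix with `active` minutes of equal per-minute VM `vm`
# placed from minute `from` (0-based), all on the x axis.
day_counts <- function(active, vm, from = 200L) {
  m <- matrix(0L, 1440L, 3L)
  if (active > 0L) m[from + seq_len(active), 1L] <- as.integer(vm)
  m
}

# Build a DayArray from a list of 1440 x 3 matrices plus labels.
make_day_array <- function(counts, labels, participant = "P001",
                           assessment = "A1",
                           startDate = as.Date("2020-01-06"),
                           padded = NULL) {
  n <- length(counts)
  counts <- unname(counts)
  x <- vapply(counts, function(m) m[, 1L], integer(1440L))
  y <- vapply(counts, function(m) m[, 2L], integer(1440L))
  z <- vapply(counts, function(m) m[, 3L], integer(1440L))
  if (is.null(padded)) padded <- matrix(FALSE, 1440L, n)
  dates <- startDate + seq_len(n) - 1L
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = x, y = y, z = z, padded = padded),
    rowData = S4Vectors::DataFrame(minute = 0:1439),
    colData = S4Vectors::DataFrame(
      participantId = rep(participant, n),
      assessmentId = rep(assessment, n),
      date = dates, label = as.integer(labels), adherent = rep(NA, n),
      row.names = paste(participant, assessment, format(dates), sep = ":")))
  new("DayArray", se)
}

# A small perfectly separable labeled DayArray: delivery days near-zero,
# wear days strongly active. `perClass` days of each, one participant per
# `perParticipant` days for grouped splitting.
separable_day_array <- function(perClass = 20L, seed = 1L,
                                perParticipant = 2L) {
  set.seed(seed)
  counts <- c(
    lapply(seq_len(perClass), function(i) {
      m <- matrix(0L, 1440L, 3L)
      hit <- sample(1440L, 5L)
      m[hit, 1L] <- as.integer(sample(50:200, 5L))
      m
    }),
    lapply(seq_len(perClass), function(i) {
      m <- matrix(0L, 1440L, 3L)
      act <- 500L + sample(0:200, 1L)
      m[sample(1440L, act), ] <- as.integer(sample(100:900, 3L * act,
                                                   replace = TRUE))
      m
    }))
  labels <- rep(c(1L, 0L), each = perClass)
  da <- make_day_array(counts, labels)
  n <- length(counts)
  pid <- sprintf("P%03d", rep(seq_len(ceiling(n / perParticipant)),
                              each = perParticipant)[seq_len(n)])
  SummarizedExperiment::colData(da)$participantId <- pid
  colnames(da) <- paste(pid, "A1", format(SummarizedExperiment::colData(da)$date),
                        sep = ":")
  da
}

# EpochSeries covering [from, to) minutes of consecutive days at 60-s
# epochs with constant counts.
flat_series <- function(startMin = 0L, nMinutes = 1440L, counts = c(1L, 1L, 1L),
                        participant = "P1", assessment = "A1",
                        startDate = as.Date("2020-01-06")) {
  t0 <- as.POSIXct(paste(startDate, "00:00:00"), tz = "UTC") + 60 * startMin
  epochSeries(participant, assessment, t0 + 60 * (seq_len(nMinutes) - 1L),
              matrix(rep(counts, each = nMinutes), ncol = 3L), 60L)
}
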