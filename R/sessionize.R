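# Detection-stream sessionization: per-second RFID readings -> visits.

#' Merge per-second detections into visits
#'
#' Within each (tag, feeder) stream, consecutive readings less than
#' `gap_threshold` seconds apart belong to the same visit; a gap of
#' `gap_threshold` or more starts a new visit (strict `<` rule, so readings
#' exactly 21 s apart are two visits under the default). Duration counts
#' inclusive seconds: a single reading is a 1-s visit. Exact duplicate
#' (timestamp, tag, feeder) records are dropped with a warning. A visit
#' spanning midnight is assigned to the calendar day of its start.
#'
#' @param records Detection data.frame with columns `timestamp` (POSIXct or
#'   numeric seconds), `tag_id`, `feeder_id`; any row order.
#' @param gap_threshold Merge threshold in seconds (default 21, >= 1).
#' @return A data.frame of visits sorted by (tag, feeder, start):
#'   `tag_id`, `feeder_id`, `start` (POSIXct, UTC), `duration_s`,
#'   `n_readings`, `date`.
#' @examples
#' recs <- data.frame(
#'   timestamp = as.POSIXct("2009-06-01 06:00:00", tz = "UTC") + c(0, 1, 2, 30),
#'   tag_id = "T001", feeder_id = "F01")
#' detections_to_visits(recs)
#' @export
detections_to_visits <- function(records, gap_threshold = 21) {
  stopifnot(gap_threshold >= 1)
  .assert_cols(records, c("timestamp", "tag_id", "feeder_id"),
               "detection table")
  if (nrow(records) == 0L)
    return(data.frame(tag_id = character(), feeder_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      duration_s = integer(), n_readings = integer(),
                      date = as.Date(character())))
  ts <- as.numeric(records$timestamp)
  if (anyNA(ts)) stop("unparseable timestamp(s) at row(s): ",
                      paste(utils::head(which(is.na(ts)), 5), collapse = ", "),
                      call. = FALSE)
  o <- order(records$tag_id, records$feeder_id, ts)
  tag <- records$tag_id[o]; feeder <- records$feeder_id[o]; ts <- ts[o]
  dup <- c(FALSE, tag[-1] == tag[-length(tag)] &
             feeder[-1] == feeder[-length(feeder)] & diff(ts) == 0)
  if (any(dup)) {
    warning(sum(dup), " duplicate detection record(s) dropped")
    tag <- tag[!dup]; feeder <- feeder[!dup]; ts <- ts[!dup]
  }
  n <- length(ts)
  new_visit <- c(TRUE, tag[-1] != tag[-n] | feeder[-1] != feeder[-n] |
                   diff(ts) >= gap_threshold)
  id <- cumsum(new_visit)
  first <- ts[new_visit]
  last <- ts[c(new_visit[-1], TRUE)]
  out <- data.frame(
    tag_id = tag[new_visit], feeder_id = feeder[new_visit],
    start = as.POSIXct(first, origin = "1970-01-01", tz = "UTC"),
    duration_s = as.integer(last - first + 1),
    n_readings = as.integer(tabulate(id)),
    stringsAsFactors = FALSE)
  out$date <- as.Date(out$start, tz = "UTC")
  out <- out[order(out$tag_id, out$feeder_id, out$start), ]
  rownames(out) <- NULL
  out
}

.ts_fmt <- "%Y-%m-%dT%H:%M:%S"

#' Read a detection stream from delimited text
#'
#' Expects a CSV with header `timestamp` (ISO-8601, 1-s resolution),
#' `tag_id`, `feeder_id`.
#'
#' @param path File path.
#' @return Detection data.frame with POSIXct `timestamp` (UTC).
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  .assert_cols(d, c("timestamp", "tag_id", "feeder_id"), path)
  if (nrow(d)) {
    ts <- as.POSIXct(d$timestamp, format = .ts_fmt, tz = "UTC")
    bad <- which(is.na(ts) & !is.na(d$timestamp))
    if (length(bad))
      stop(sprintf("unparseable timestamp at line(s) %s of %s",
                   paste(utils::head(bad + 1L, 5), collapse = ", "), path),
           call. = FALSE)
    d$timestamp <- ts
  } else {
    d$timestamp <- as.POSIXct(character(), tz = "UTC")
  }
  d[c("timestamp", "tag_id", "feeder_id")]
}

#' Write a detection stream as delimited text
#'
#' @param detections Detection data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  .assert_cols(detections, c("timestamp", "tag_id", "feeder_id"),
               "detection table")
  d <- detections
  d$timestamp <- format(d$timestamp, .ts_fmt, tz = "UTC")
  utils::write.csv(d[c("timestamp", "tag_id", "feeder_id")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a visit table
#'
#' The on-disk format is CSV with header `tag_id`, `feeder_id`, `start`
#' (ISO-8601), `duration_s`, `n_readings`, `date`; the round trip is
#' lossless.
#'
#' @param visits Visit data.frame from [detections_to_visits()].
#' @param path File path.
#' @return `path` invisibly for the writer; the visit data.frame for the
#'   reader.
#' @export
write_visits <- function(visits, path) {
  .assert_cols(visits, c("tag_id", "feeder_id", "start", "duration_s"),
               "visit table")
  v <- visits
  v$start <- format(v$start, .ts_fmt, tz = "UTC")
  if (is.null(v$n_readings)) v$n_readings <- NA_integer_
  if (is.null(v$date)) v$date <- as.Date(as.POSIXct(visits$start, tz = "UTC"))
  utils::write.csv(v[c("tag_id", "feeder_id", "start", "duration_s",
                       "n_readings", "date")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_visits
#' @export
read_visits <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert_cols(v, c("tag_id", "feeder_id", "start", "duration_s"), path)
  v$start <- as.POSIXct(v$start, format = .ts_fmt, tz = "UTC")
  if (!is.null(v$date)) v$date <- as.Date(v$date)
  else v$date <- as.Date(v$start, tz = "UTC")
  v
}
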