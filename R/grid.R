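#' Build the feeder grid
#'
#' Lays out the 45-feeder study grid: two rows of 12 feeders followed by
#' three rows of 7, spaced 100 m apart, spanning a habitat gradient of
#' 8 hayfield, 6 fallow and 31 forest feeders. All hayfield and fallow
#' feeders sit in canopy openings; exactly 14 of the 31 forest feeders do.
#' Lateral visibility (the distance at which a marker at the feeder remains
#' visible to an approaching observer) is drawn uniformly from per-habitat
#' ranges.
#'
#' @param seed Integer seed controlling which forest feeders fall in
#'   openings and the lateral-visibility draws.
#' @param visibility_forest,visibility_open Length-2 numeric ranges (metres)
#'   for lateral visibility in forest and in open (hayfield/fallow) habitat.
#' @return A data.frame with one row per feeder: `feeder_id`, `x`, `y`
#'   (metres), `row`, `habitat` (hayfield/fallow/forest), `openness`
#'   (open/closed) and `lateral_visibility` (metres).
#' @examples
#' g <- make_grid(seed = 1)
#' table(g$habitat)
#' @export
make_grid <- function(seed = 1L,
                      visibility_forest = c(1, 15),
                      visibility_open = c(10, 30)) {
  stopifnot(length(visibility_forest) == 2, length(visibility_open) == 2,
            all(visibility_forest >= 0), all(visibility_open >= 0))
  row_sizes <- c(12L, 12L, 7L, 7L, 7L)
  n <- sum(row_sizes)
  row <- rep(seq_along(row_sizes), row_sizes)
  col <- unlist(lapply(row_sizes, seq_len))
  grid <- data.frame(
    feeder_id = sprintf("F%02d", seq_len(n)),
    x = (col - 1) * 100,
    y = (row - 1) * 100,
    row = row,
    stringsAsFactors = FALSE
  )
  # habitat gradient along the rows: open farmland first, forest behind
  habitat <- character(n)
  habitat[row == 1] <- c(rep("hayfield", 8), rep("fallow", 4))
  habitat[row == 2] <- c(rep("fallow", 2), rep("forest", 10))
  habitat[row >= 3] <- "forest"
  grid$habitat <- habitat

  withr_seed(seed, {
    openness <- ifelse(habitat %in% c("hayfield", "fallow"), "open", "closed")
    forest_idx <- which(habitat == "forest")
    openness[sample(forest_idx, 14L)] <- "open"
    grid$openness <- openness
    lv <- numeric(n)
    is_forest <- habitat == "forest"
    lv[is_forest] <- stats::runif(sum(is_forest), visibility_forest[1],
                                  visibility_forest[2])
    lv[!is_forest] <- stats::runif(sum(!is_forest), visibility_open[1],
                                   visibility_open[2])
    grid$lateral_visibility <- round(lv, 1)
  })
  grid
}

#' Build a weekly sucrose treatment schedule
#'
#' In the manipulation year each of three consecutive 3-week blocks assigns
#' the high (35%) sucrose treatment to 15 of the 45 feeders per week, under
#' the constraint that every feeder is high exactly once per block; the rest
#' stay at the baseline 20% concentration. In non-manipulation years every
#' feeder-week is low.
#'
#' @param year Calendar year of the schedule.
#' @param seed Integer seed for the random block assignments.
#' @param grid Feeder grid from [make_grid()] (only `feeder_id` is used).
#' @param treatment_years Years in which the manipulation ran.
#' @param start Date the manipulation starts (first day of week 1); defaults
#'   to 10 June of `year`.
#' @return A data.frame with columns `year`, `block` (1-3), `week` (1-9),
#'   `feeder_id`, `sucrose` (low/high), `week_start`, `week_end`.
#' @examples
#' sch <- make_treatment_schedule(2009, seed = 1)
#' with(sch, table(week, sucrose))
#' @export
make_treatment_schedule <- function(year, seed = 1L, grid = make_grid(),
                                    treatment_years = 2009L,
                                    start = as.Date(sprintf("%d-06-10", year))) {
  feeders <- grid$feeder_id
  nf <- length(feeders)
  stopifnot(nf %% 3 == 0)
  per_week <- nf %/% 3
  sched <- expand.grid(week = 1:9, feeder_id = feeders,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sched$year <- year
  sched$block <- (sched$week - 1L) %/% 3L + 1L
  sched$sucrose <- "low"
  if (year %in% treatment_years) {
    withr_seed(seed, {
      for (b in 1:3) {
        # random partition of the feeders into the three weeks of the block
        grp <- rep(1:3, each = per_week)[order(stats::runif(nf))]
        for (w in 1:3) {
          hi <- feeders[grp == w]
          sel <- sched$block == b & sched$week == (b - 1L) * 3L + w &
            sched$feeder_id %in% hi
          sched$sucrose[sel] <- "high"
        }
      }
    })
  }
  sched$week_start <- start + (sched$week - 1L) * 7L
  sched$week_end <- sched$week_start + 6L
  sched[order(sched$week, sched$feeder_id),
        c("year", "block", "week", "feeder_id", "sucrose",
          "week_start", "week_end")]
}

#' Look up the sucrose treatment for feeder-dates
#'
#' Dates outside the scheduled weeks (or years with no schedule) are the
#' baseline low concentration.
#'
#' @param feeder_id,date Vectors of equal length.
#' @param schedule Schedule from [make_treatment_schedule()]; may combine
#'   several years.
#' @return Character vector of "low"/"high".
#' @export
sucrose_at <- function(feeder_id, date, schedule) {
  date <- as.Date(date)
  out <- rep("low", length(feeder_id))
  if (is.null(schedule) || nrow(schedule) == 0) return(out)
  hi <- schedule[schedule$sucrose == "high", , drop = FALSE]
  for (i in seq_len(nrow(hi))) {
    sel <- feeder_id == hi$feeder_id[i] & date >= hi$week_start[i] &
      date <= hi$week_end[i]
    out[sel] <- "high"
  }
  out
}
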