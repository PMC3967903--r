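# Space-use indices, control covariates and the bird-feeder-day analysis
# table with its eligibility filters.

#' Count visits per bird, feeder and day
#'
#' @param visits Visit table with `tag_id`, `feeder_id`, `date`.
#' @return A data.frame `tag_id`, `feeder_id`, `date`, `n` (visit count).
#' @export
count_visits <- function(visits) {
  .assert_cols(visits, c("tag_id", "feeder_id", "date"), "visit table")
  if (!nrow(visits))
    return(data.frame(tag_id = character(), feeder_id = character(),
                      date = as.Date(character()), n = integer()))
  key <- .key(visits$tag_id, visits$feeder_id, as.character(visits$date))
  agg <- table(key)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(tag_id = vapply(parts, `[`, "", 1),
                    feeder_id = vapply(parts, `[`, "", 2),
                    date = as.Date(vapply(parts, `[`, "", 3)),
                    n = as.integer(agg), stringsAsFactors = FALSE)
  out[order(out$tag_id, out$date, out$feeder_id), ]
}

#' Daily spatial concentration
#'
#' For every (bird, feeder, day) with at least one visit, the fraction of
#' the bird's visits that day made at that feeder:
#' `v[i,f,d] / sum_f' v[i,f',d]`. Shares sum to 1 over feeders within each
#' bird-day.
#'
#' @param visits Visit table (or a `count_visits()` table with column `n`).
#' @return A data.frame `tag_id`, `date`, `feeder_id`, `n`, `day_total`,
#'   `concentration`.
#' @export
spatial_concentration <- function(visits) {
  cnt <- if ("n" %in% names(visits)) visits else count_visits(visits)
  if (!nrow(cnt)) {
    cnt$day_total <- integer(); cnt$concentration <- numeric()
    return(cnt)
  }
  cnt$day_total <- stats::ave(cnt$n, .key(cnt$tag_id, cnt$date), FUN = sum)
  cnt$concentration <- cnt$n / cnt$day_total
  cnt
}

#' Seasonal spatial concentration
#'
#' The same share computed over the entire period an individual was
#' followed: `V[i,f] / V[i]`, within year.
#'
#' @param visits Visit table (or counts).
#' @return A data.frame `tag_id`, `year`, `feeder_id`, `n`,
#'   `season_total`, `concentration`.
#' @export
seasonal_concentration <- function(visits) {
  cnt <- if ("n" %in% names(visits)) visits else count_visits(visits)
  if (!nrow(cnt))
    return(data.frame(tag_id = character(), year = integer(),
                      feeder_id = character(), n = integer(),
                      season_total = integer(), concentration = numeric()))
  cnt$year <- as.integer(format(cnt$date, "%Y"))
  key <- .key(cnt$tag_id, cnt$year, cnt$feeder_id)
  n <- rowsum(cnt$n, key)
  parts <- strsplit(rownames(n), "\r", fixed = TRUE)
  out <- data.frame(tag_id = vapply(parts, `[`, "", 1),
                    year = as.integer(vapply(parts, `[`, "", 2)),
                    feeder_id = vapply(parts, `[`, "", 3),
                    n = as.integer(n), stringsAsFactors = FALSE)
  out$season_total <- stats::ave(out$n, .key(out$tag_id, out$year),
                                 FUN = sum)
  out$concentration <- out$n / out$season_total
  out[order(out$tag_id, out$year, out$feeder_id), ]
}

#' Spatial stability
#'
#' Pearson correlation, per individual and year, between daily spatial
#' concentration and seasonal spatial concentration, paired over every
#' (feeder, day) combination where the feeder is one the individual visited
#' at least once that season (daily concentration 0 on days it skipped the
#' feeder). Requires at least 3 distinct days followed; with fewer days, or
#' when either vector has zero variance (e.g. a bird using a single feeder
#' all season), the value is `NA` and the row is flagged.
#'
#' @param visits Visit table (or counts).
#' @return A data.frame `tag_id`, `year`, `stability`, `n_days_followed`,
#'   `defined` (logical).
#' @export
spatial_stability <- function(visits) {
  cnt <- if ("n" %in% names(visits)) visits else count_visits(visits)
  if (!nrow(cnt))
    return(data.frame(tag_id = character(), year = integer(),
                      stability = numeric(), n_days_followed = integer(),
                      defined = logical()))
  cnt$year <- as.integer(format(cnt$date, "%Y"))
  res <- lapply(split(cnt, .key(cnt$tag_id, cnt$year)), function(d) {
    days <- sort(unique(d$date))
    feeders <- sort(unique(d$feeder_id))
    nd <- length(days)
    out <- data.frame(tag_id = d$tag_id[1], year = d$year[1],
                      stability = NA_real_, n_days_followed = nd,
                      defined = FALSE, stringsAsFactors = FALSE)
    if (nd < 3) return(out)
    m <- matrix(0, nd, length(feeders), dimnames = list(NULL, feeders))
    m[cbind(match(d$date, days), match(d$feeder_id, feeders))] <- d$n
    daily <- m / rowSums(m)
    seasonal <- matrix(colSums(m) / sum(m), nd, length(feeders),
                       byrow = TRUE)
    if (stats::sd(daily) == 0 || stats::sd(seasonal) == 0) return(out)
    out$stability <- stats::cor(as.vector(daily), as.vector(seasonal))
    out$defined <- TRUE
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$tag_id, out$year), ]
}

#' Daily grid usage
#'
#' Mean daily number of visits across the individuals that used the grid
#' (made at least one visit) that day; a day-level index of overall
#' reliance on the feeders.
#'
#' @param visits Visit table (or counts).
#' @return A data.frame `date`, `grid_usage`, `n_birds`.
#' @export
grid_usage <- function(visits) {
  cnt <- if ("n" %in% names(visits)) visits else count_visits(visits)
  if (!nrow(cnt))
    return(data.frame(date = as.Date(character()), grid_usage = numeric(),
                      n_birds = integer()))
  bd <- rowsum(cnt$n, .key(cnt$tag_id, as.character(cnt$date)))
  parts <- strsplit(rownames(bd), "\r", fixed = TRUE)
  date <- as.Date(vapply(parts, `[`, "", 2))
  tot <- as.numeric(bd)
  out <- data.frame(date = sort(unique(date)))
  out$grid_usage <- as.numeric(tapply(tot, date, mean)[as.character(out$date)])
  out$n_birds <- as.integer(tapply(tot, date, length)[as.character(out$date)])
  out
}

#' Season feeder ranks by distinct visitors
#'
#' Ranks feeders, within year, by the number of distinct individuals (of
#' the competitor sex, adults only when metadata are supplied) detected at
#' the feeder at least once during the season. Rank 1 is the feeder with
#' the most individuals; ties get average ranks; feeders never visited rank
#' last.
#'
#' @param visits Visit table (or counts).
#' @param feeders Feeder metadata (only `feeder_id` used) so that
#'   never-visited feeders are ranked; `NULL` restricts to visited feeders.
#' @param birds Individual metadata with `tag_id`, `sex`, `age_class`, used
#'   to restrict to adult individuals of `competitor_sex`; `NULL` uses all.
#' @param competitor_sex `"M"` or `"F"` (used only with `birds`).
#' @return A data.frame `feeder_id`, `year`, `n_individuals`, `rank`.
#' @export
feeder_rank <- function(visits, feeders = NULL, birds = NULL,
                        competitor_sex = "M") {
  cnt <- if ("n" %in% names(visits)) visits else count_visits(visits)
  if (!is.null(birds)) {
    keep <- birds$tag_id[birds$sex == competitor_sex &
                           birds$age_class == "adult"]
    cnt <- cnt[cnt$tag_id %in% keep, , drop = FALSE]
  }
  cnt$year <- as.integer(format(cnt$date, "%Y"))
  years <- if (nrow(cnt)) sort(unique(cnt$year)) else integer()
  all_f <- if (!is.null(feeders)) feeders$feeder_id else
    sort(unique(cnt$feeder_id))
  res <- lapply(years, function(y) {
    d <- cnt[cnt$year == y, , drop = FALSE]
    nind <- vapply(all_f, function(f)
      length(unique(d$tag_id[d$feeder_id == f])), integer(1))
    data.frame(feeder_id = all_f, year = y, n_individuals = nind,
               rank = rank(-nind, ties.method = "average"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  if (!length(res))
    return(data.frame(feeder_id = character(), year = integer(),
                      n_individuals = integer(), rank = numeric()))
  do.call(rbind, res)
}

#' Assemble the bird-feeder-day analysis table
#'
#' Builds one row per (focal individual, feeder, day) for modelling the
#' number of visits by competitors (NVC). Focal individuals are adults of
#' `focal_sex` detected on at least `min_days` distinct days in the season;
#' NVC sums the visits made that day at that feeder by *other* adults of
#' `competitor_sex` (all adults count as competitors regardless of days
#' followed; juveniles never do). Feeder-days where the focal individual is
#' the only one detected carry no information about exclusion and are
#' dropped. Covariates are joined from the metadata and the treatment
#' schedule; dates without a scheduled high week are low sucrose.
#'
#' @param visits Visit table from [detections_to_visits()].
#' @param birds Individual metadata: `tag_id`, `sex`, `age_class`.
#' @param feeders Feeder metadata: `feeder_id`, `openness`,
#'   `lateral_visibility` (and optionally `habitat`).
#' @param schedule Treatment schedule from [make_treatment_schedule()], or
#'   `NULL` for all-low.
#' @param focal_sex,competitor_sex Sex combination under analysis
#'   (defaults M vs M).
#' @param min_days Minimum distinct days followed to qualify as focal.
#' @return A data.frame with columns `tag_id` (focal), `feeder_id`, `date`,
#'   `year`, `nvc`, `spatial_concentration`, `spatial_stability`,
#'   `daily_visits`, `n_competitors`, `grid_usage`, `feeder_rank`,
#'   `sucrose`, `openness`, `lateral_visibility`, `focal_sex`,
#'   `competitor_sex`. Attribute `filter_counts` reconciles candidate rows
#'   with rows dropped by each eligibility filter.
#' @export
assemble_analysis_table <- function(visits, birds, feeders, schedule = NULL,
                                    focal_sex = "M", competitor_sex = "M",
                                    min_days = 3L) {
  .assert_cols(birds, c("tag_id", "sex", "age_class"), "bird metadata")
  .assert_cols(feeders, c("feeder_id", "openness", "lateral_visibility"),
               "feeder metadata")
  unknown_t <- setdiff(unique(visits$tag_id), birds$tag_id)
  if (length(unknown_t))
    stop("visits contain tag(s) absent from metadata: ",
         paste(utils::head(unknown_t, 10), collapse = ", "), call. = FALSE)
  unknown_f <- setdiff(unique(visits$feeder_id), feeders$feeder_id)
  if (length(unknown_f))
    stop("visits contain feeder(s) absent from metadata: ",
         paste(utils::head(unknown_f, 10), collapse = ", "), call. = FALSE)

  adults <- birds$tag_id[birds$age_class == "adult"]
  cnt_all <- count_visits(visits)
  cnt <- cnt_all[cnt_all$tag_id %in% adults, , drop = FALSE]
  cnt$year <- as.integer(format(cnt$date, "%Y"))
  sex_of <- birds$sex[match(cnt$tag_id, birds$tag_id)]

  # focal candidates: adult, focal sex, followed >= min_days in the season
  days_followed <- tapply(as.character(cnt$date),
                          .key(cnt$tag_id, cnt$year),
                          function(x) length(unique(x)))
  cnt$days_followed <- as.integer(days_followed[.key(cnt$tag_id, cnt$year)])
  is_focal_sex <- sex_of == focal_sex
  candidates <- cnt[is_focal_sex, , drop = FALSE]
  n_candidates <- nrow(candidates)
  eligible <- candidates[candidates$days_followed >= min_days, , drop = FALSE]
  n_dropped_days <- n_candidates - nrow(eligible)

  # NVC and competitor counts from adult competitor-sex visits
  comp <- cnt[sex_of == competitor_sex, , drop = FALSE]
  fd_key <- .key(comp$feeder_id, as.character(comp$date))
  fd_total <- rowsum(comp$n, fd_key)
  fd_nind <- tapply(comp$tag_id, fd_key, function(x) length(unique(x)))
  ekey <- .key(eligible$feeder_id, as.character(eligible$date))
  own <- if (focal_sex == competitor_sex) eligible$n else 0L
  tot <- fd_total[match(ekey, rownames(fd_total))]
  tot[is.na(tot)] <- 0
  eligible$nvc <- as.integer(tot - own)
  nind <- as.integer(fd_nind[ekey])
  nind[is.na(nind)] <- 0L
  eligible$n_competitors <- nind -
    as.integer(focal_sex == competitor_sex)  # distinct others, excl. focal

  keep <- eligible$nvc >= 1
  n_dropped_singleton <- sum(!keep)
  out <- eligible[keep, , drop = FALSE]

  # covariates
  bd_tot <- rowsum(cnt$n, .key(cnt$tag_id, as.character(cnt$date)))
  okey <- .key(out$tag_id, as.character(out$date))
  out$daily_visits <- as.integer(bd_tot[match(okey, rownames(bd_tot))])
  out$spatial_concentration <- out$n / out$daily_visits
  st <- spatial_stability(cnt)
  out$spatial_stability <- st$stability[
    match(.key(out$tag_id, out$year), .key(st$tag_id, st$year))]
  gu <- grid_usage(cnt)
  out$grid_usage <- gu$grid_usage[match(out$date, gu$date)]
  fr <- feeder_rank(cnt, feeders = feeders, birds = birds,
                    competitor_sex = competitor_sex)
  out$feeder_rank <- fr$rank[match(.key(out$feeder_id, out$year),
                                   .key(fr$feeder_id, fr$year))]
  out$sucrose <- sucrose_at(out$feeder_id, out$date, schedule)
  fm <- match(out$feeder_id, feeders$feeder_id)
  out$openness <- feeders$openness[fm]
  out$lateral_visibility <- feeders$lateral_visibility[fm]
  out$focal_sex <- focal_sex
  out$competitor_sex <- competitor_sex

  undefined_stab <- sum(is.na(out$spatial_stability))
  res <- out[c("tag_id", "feeder_id", "date", "year", "nvc",
               "spatial_concentration", "spatial_stability", "daily_visits",
               "n_competitors", "grid_usage", "feeder_rank", "sucrose",
               "openness", "lateral_visibility", "focal_sex",
               "competitor_sex")]
  rownames(res) <- NULL
  attr(res, "filter_counts") <- list(
    candidate_rows = n_candidates,
    dropped_under_min_days = n_dropped_days,
    dropped_singleton_feeder_day = n_dropped_singleton,
    rows_with_undefined_stability = undefined_stab,
    kept = nrow(res))
  res
}
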