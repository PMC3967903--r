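counts_df <- function(...) {
  d <- data.frame(...)
  d$date <- as.Date(d$date)
  d
}

test_that("daily spatial concentration is the within-day visit share", {
  cnt <- counts_df(tag_id = "T1", feeder_id = c("A", "B"),
                   date = "2009-06-01", n = c(9L, 1L))
  sc <- spatial_concentration(cnt)
  expect_equal(sc$concentration[sc$feeder_id == "A"], 0.9)
  expect_equal(sc$concentration[sc$feeder_id == "B"], 0.1)

  one <- spatial_concentration(counts_df(tag_id = "T1", feeder_id = "A",
                                         date = "2009-06-01", n = 4L))
  expect_equal(one$concentration, 1)

  even <- spatial_concentration(counts_df(tag_id = "T1",
                                          feeder_id = c("A", "B"),
                                          date = "2009-06-01", n = c(2L, 2L)))
  expect_equal(even$concentration, c(0.5, 0.5))
})

test_that("concentration shares sum to one over feeders for every bird-day", {
  w <- small_world(seed = 41, n_individuals = 8, n_days = 8)
  sc <- spatial_concentration(count_visits(w$visits))
  sums <- tapply(sc$concentration, paste(sc$tag_id, sc$date), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("seasonal concentration is the within-season share", {
  cnt <- counts_df(tag_id = "T1", feeder_id = c("A", "B", "A"),
                   date = c("2009-06-01", "2009-06-01", "2009-06-02"),
                   n = c(20L, 10L, 10L))
  se <- seasonal_concentration(cnt)
  expect_equal(se$concentration[se$feeder_id == "A"], 0.75)
  expect_equal(se$concentration[se$feeder_id == "B"], 0.25)
  expect_equal(sum(se$concentration), 1)
})

test_that("spatial stability matches a hand-computed Pearson correlation", {
  # 3 days, 2 feeders; daily shares (1,0), (0,1), (.5,.5);
  # counts give seasonal shares (2/3, 1/3)
  cnt <- counts_df(tag_id = "T1",
                   feeder_id = c("A", "B", "A", "B"),
                   date = c("2009-06-01", "2009-06-02", "2009-06-03",
                            "2009-06-03"),
                   n = c(3L, 1L, 1L, 1L))
  st <- spatial_stability(cnt)
  daily <- c(1, 0, 0, 1, 0.5, 0.5)          # (day, feeder) pairs
  seasonal <- rep(c(4 / 6, 2 / 6), 3)
  # independent oracle: Pearson r from first principles
  r_hand <- sum((daily - mean(daily)) * (seasonal - mean(seasonal))) /
    sqrt(sum((daily - mean(daily))^2) * sum((seasonal - mean(seasonal))^2))
  expect_equal(st$stability, r_hand)
  expect_equal(st$n_days_followed, 3L)
  expect_true(st$defined)
})

test_that("stability is 1 when daily patterns mirror the seasonal pattern", {
  cnt <- counts_df(tag_id = "T1",
                   feeder_id = rep(c("A", "B"), 3),
                   date = rep(c("2009-06-01", "2009-06-02", "2009-06-03"),
                              each = 2),
                   n = rep(c(3L, 1L), 3))
  expect_equal(spatial_stability(cnt)$stability, 1)
})

test_that("degenerate stability cases are flagged, not fabricated", {
  single <- counts_df(tag_id = "T1", feeder_id = "A",
                      date = c("2009-06-01", "2009-06-02", "2009-06-03"),
                      n = c(1L, 2L, 3L))
  st <- spatial_stability(single)
  expect_false(st$defined)
  expect_true(is.na(st$stability))

  short <- counts_df(tag_id = "T1", feeder_id = c("A", "B"),
                     date = c("2009-06-01", "2009-06-02"), n = c(1L, 2L))
  st2 <- spatial_stability(short)
  expect_false(st2$defined)
  expect_equal(st2$n_days_followed, 2L)
})

test_that("grid usage averages daily totals over active birds only", {
  cnt <- counts_df(tag_id = c("T1", "T1", "T2"),
                   feeder_id = c("A", "B", "A"),
                   date = "2009-06-01", n = c(6L, 4L, 20L))
  expect_equal(grid_usage(cnt)$grid_usage, 15)
  solo <- counts_df(tag_id = "T1", feeder_id = "A", date = "2009-06-02",
                    n = 7L)
  expect_equal(grid_usage(solo)$grid_usage, 7)
})

test_that("feeder ranks follow distinct-visitor counts with average ties", {
  cnt <- counts_df(
    tag_id = c("T1", "T2", "T3", "T4", "T5", "T1", "T2", "T3", "T1"),
    feeder_id = c(rep("F1", 5), rep("F2", 3), "F3"),
    date = "2009-06-01", n = 1L)
  fr <- feeder_rank(cnt)
  expect_equal(fr$rank[match(c("F1", "F2", "F3"), fr$feeder_id)],
               c(1, 2, 3))

  # tie between F2 and F3; never-visited F4 ranks last
  cnt2 <- counts_df(
    tag_id = c("T1", "T2", "T3", "T4", "T5", "T1", "T2", "T1", "T2"),
    feeder_id = c(rep("F1", 5), "F2", "F2", "F3", "F3"),
    date = "2009-06-01", n = 1L)
  feeders <- data.frame(feeder_id = c("F1", "F2", "F3", "F4"))
  fr2 <- feeder_rank(cnt2, feeders = feeders)
  expect_equal(fr2$rank[match(c("F1", "F2", "F3", "F4"), fr2$feeder_id)],
               c(1, 2.5, 2.5, 4))
  # a permutation of 1..n up to tie-averaging
  expect_equal(sum(fr2$rank), sum(seq_len(4)))
})

test_that("NVC sums visits of other competitor-sex adults", {
  birds <- data.frame(tag_id = c("I", "J", "K", "JUV"),
                      sex = "M", age_class = c("adult", "adult", "adult",
                                               "juvenile"))
  feeders <- data.frame(feeder_id = "F1", openness = "closed",
                        lateral_visibility = 5)
  cnt <- counts_df(tag_id = c("I", "J", "K", "JUV"), feeder_id = "F1",
                   date = rep(c("2009-06-01"), 4), n = c(10L, 5L, 2L, 50L))
  # give everyone 3 days of history so they qualify as focal
  pad <- counts_df(tag_id = rep(c("I", "J", "K"), each = 2),
                   feeder_id = "F1",
                   date = rep(c("2009-06-02", "2009-06-03"), 3), n = 1L)
  visits <- visits_from_counts(rbind(cnt, pad))
  tab <- assemble_analysis_table(visits, birds, feeders)
  r <- tab[tab$tag_id == "I" & tab$date == as.Date("2009-06-01"), ]
  expect_equal(r$nvc, 7L)            # juvenile's 50 visits excluded
  expect_equal(r$n_competitors, 2L)  # J and K, focal excluded
  expect_equal(r$daily_visits, 10L)
})

test_that("singleton feeder-days are excluded and NVC is symmetric for pairs", {
  birds <- data.frame(tag_id = c("I", "J"), sex = "M", age_class = "adult")
  feeders <- data.frame(feeder_id = c("F1", "F2"), openness = "closed",
                        lateral_visibility = 5)
  cnt <- counts_df(
    tag_id = c("I", "J", "I", "I", "J", "I", "J"),
    feeder_id = c("F1", "F1", "F2", "F1", "F1", "F1", "F1"),
    date = c("2009-06-01", "2009-06-01", "2009-06-01",
             "2009-06-02", "2009-06-02", "2009-06-03", "2009-06-03"),
    n = c(4L, 9L, 3L, 2L, 2L, 1L, 1L))
  tab <- assemble_analysis_table(visits_from_counts(cnt), birds, feeders)
  # I alone at F2 on day 1: no row
  expect_false(any(tab$feeder_id == "F2"))
  # two-bird feeder-day: my NVC is your count and vice versa
  d1 <- tab[tab$date == as.Date("2009-06-01"), ]
  expect_equal(d1$nvc[d1$tag_id == "I"], 9L)
  expect_equal(d1$nvc[d1$tag_id == "J"], 4L)
  fc <- attr(tab, "filter_counts")
  expect_equal(fc$candidate_rows,
               fc$kept + fc$dropped_under_min_days +
                 fc$dropped_singleton_feeder_day)
})

test_that("focal eligibility needs 3 days followed; competitors do not", {
  birds <- data.frame(tag_id = c("REG", "CASUAL"), sex = "M",
                      age_class = "adult")
  feeders <- data.frame(feeder_id = "F1", openness = "open",
                        lateral_visibility = 20)
  cnt <- counts_df(tag_id = c("REG", "CASUAL", "REG", "REG"),
                   feeder_id = "F1",
                   date = c("2009-06-01", "2009-06-01", "2009-06-02",
                            "2009-06-03"),
                   n = c(5L, 3L, 1L, 1L))
  tab <- assemble_analysis_table(visits_from_counts(cnt), birds, feeders)
  # CASUAL (1 day) is never focal but its visits count as NVC
  expect_false("CASUAL" %in% tab$tag_id)
  expect_equal(tab$nvc[tab$tag_id == "REG" &
                         tab$date == as.Date("2009-06-01")], 3L)
})

test_that("NVC on a full simulation equals an independent recomputation", {
  w <- small_world(seed = 42, n_individuals = 12, n_days = 12)
  birds <- w$pop[c("tag_id", "sex", "age_class")]
  tab <- assemble_analysis_table(w$visits, birds, w$grid, w$schedule)
  cnt <- count_visits(w$visits)
  adults_m <- birds$tag_id[birds$age_class == "adult" & birds$sex == "M"]
  for (i in sample.int(nrow(tab), min(25, nrow(tab)))) {
    r <- tab[i, ]
    others <- cnt[cnt$feeder_id == r$feeder_id & cnt$date == r$date &
                    cnt$tag_id != r$tag_id & cnt$tag_id %in% adults_m, ]
    expect_equal(r$nvc, sum(others$n))
    expect_gte(r$n_competitors, 1L)
  }
})

test_that("unknown tags or feeders in visits raise a join error", {
  birds <- data.frame(tag_id = "I", sex = "M", age_class = "adult")
  feeders <- data.frame(feeder_id = "F1", openness = "closed",
                        lateral_visibility = 5)
  v <- visits_from_counts(counts_df(tag_id = "GHOST", feeder_id = "F1",
                                    date = "2009-06-01", n = 1L))
  expect_error(assemble_analysis_table(v, birds, feeders), "GHOST")
  v2 <- visits_from_counts(counts_df(tag_id = "I", feeder_id = "F9",
                                     date = "2009-06-01", n = 1L))
  expect_error(assemble_analysis_table(v2, birds, feeders), "F9")
})
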