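# visit segmentation, direction assignment, directional counts, q

test_that("visits split on gaps exceeding 24 h and partition detections", {
  t0 <- UTC("2017-06-01")
  d <- data.frame(receiver_id = "I1", timestamp = t0 + c(0, 10, 40) * 3600)
  v <- segment_visits(d)
  expect_length(v, 2L)
  expect_equal(nrow(v[[1]]), 2L)
  expect_equal(nrow(v[[2]]), 1L)
  # a gap of exactly 24 h stays within one visit
  d <- data.frame(receiver_id = "I1", timestamp = t0 + c(0, 24) * 3600)
  expect_length(segment_visits(d), 1L)
  expect_length(segment_visits(d[0, ]), 0L)
  # partition property under random gaps
  set.seed(4)
  for (rep in 1:10) {
    ts <- t0 + sort(cumsum(runif(8, 0, 48 * 3600)))
    d <- data.frame(receiver_id = "I1", timestamp = ts)
    v <- segment_visits(d)
    got <- sort(as.numeric(do.call(rbind, v)$timestamp))
    expect_equal(got, sort(as.numeric(ts)))
  }
})

test_that("direction follows inner/outer order and corruption unassigns", {
  reg <- toy_registry()
  t0 <- UTC("2017-06-01")
  vis <- function(rid, hrs) data.frame(receiver_id = rid,
                                       timestamp = t0 + hrs * 3600)
  expect_equal(assign_direction(vis(c("I1", "O1"), c(0, 1)), reg),
               "sound_to_gulf")
  expect_equal(assign_direction(vis(c("O1", "I1"), c(0, 1)), reg),
               "gulf_to_sound")
  # coincident first detections across lines
  expect_equal(assign_direction(vis(c("I1", "O1", "O2"), c(0, 0, 1)), reg),
               "unassigned")
  # same line first and last
  expect_equal(assign_direction(vis(c("I1", "O1", "I2"), c(0, 1, 2)), reg),
               "unassigned")
  # inner receiver lacking an outer complement
  expect_equal(assign_direction(vis(c("NC1", "O1"), c(0, 1)), reg),
               "unassigned")
  # receivers from a different array are rejected
  expect_error(assign_direction(vis(c("S1", "O1"), c(0, 1)), reg),
               "single entrance")
  # duplicated detection rows do not change the assignment
  v <- vis(c("I1", "O1"), c(0, 1))
  expect_equal(assign_direction(rbind(v, v), reg),
               assign_direction(v, reg))
  # configurable coincidence tolerance
  v <- vis(c("I1", "O1", "O2"), c(0, 0.0005, 1))
  expect_equal(assign_direction(v, reg), "sound_to_gulf")
  expect_equal(assign_direction(v, reg, tolerance_s = 5), "unassigned")
})

test_that("passages are tabulated by entrance, class and season", {
  g <- build_grid("2017-04-01", "2019-03-31")
  dep <- as_deployments_for_test(weight = c(80, 140))
  cl <- covariate_classing(dep, "weight")
  mk <- function(tag, when, dir)
    data.frame(tag_id = tag, entrance = "hinchinbrook",
               entry_time = UTC(when), exit_time = UTC(when),
               season = g$season_of_occ[occasion_of(g, UTC(when))],
               direction = dir, stringsAsFactors = FALSE)
  p <- rbind(mk("T1", "2017-06-01", "sound_to_gulf"),
             mk("T1", "2017-06-20", "sound_to_gulf"),
             mk("T1", "2017-07-01", "gulf_to_sound"),
             mk("T2", "2017-09-15", "sound_to_gulf"),
             mk("T2", "2017-10-01", "unassigned"))
  cnt <- tabulate_counts(p, cl, g)
  expect_equal(cnt$d8["hinchinbrook", "y0", 1], 2)
  expect_equal(cnt$d4["hinchinbrook", "y0", 1], 1)
  # passage with exit in September is binned to the fall/winter season
  expect_equal(cnt$d8["hinchinbrook", "y1", 2], 1)
  # unassigned contributes nothing
  expect_equal(sum(cnt$d4) + sum(cnt$d8), 4)
  # all-unassigned gives all-zero counts
  p$direction <- "unassigned"
  cnt0 <- tabulate_counts(p, cl, g)
  expect_true(all(cnt0$d4 == 0) && all(cnt0$d8 == 0))
})

test_that("stay/leave ratio counts consecutive-occasion pairs", {
  g <- toy_grid(weeks = 10)
  pres <- data.frame(tag_id = "A", group = "hinchinbrook",
                     occasion = c(3L, 4L, 5L),
                     last_detection = occasion_start(g, 3))
  # present weeks 3,4,5 then gone: 2 stays, 1 leave
  expect_equal(estimate_q(pres, "hinchinbrook", grid = g), 2)
  pres2 <- rbind(pres,
                 data.frame(tag_id = "B", group = "hinchinbrook",
                            occasion = c(2L, 6L),
                            last_detection = occasion_start(g, 2)))
  # B adds 0 stays and 2 leaves
  expect_equal(estimate_q(pres2, "hinchinbrook", grid = g), 2 / 3)
  # no fish present: zero denominator
  expect_error(estimate_q(pres[0, ], "hinchinbrook", grid = g),
               "zero denominator")
  expect_warning(
    q <- estimate_q(pres[0, ], "hinchinbrook", grid = g, fallback = 0.5),
    "fallback")
  expect_equal(q, 0.5)
})

test_that("stay pseudo-counts are q * (d4 + d8), kept fractional", {
  g <- build_grid("2017-04-01", "2019-03-31")
  cl <- covariate_classing(as_deployments_for_test(100), "none")
  p <- data.frame(tag_id = "T1", entrance = "hinchinbrook",
                  entry_time = UTC("2017-06-01"),
                  exit_time = UTC("2017-06-01"), season = 1L,
                  direction = "sound_to_gulf")[0, ]
  cnt <- tabulate_counts(p, cl, g)
  cnt$d4["hinchinbrook", 1, 1] <- 3
  cnt$d8["hinchinbrook", 1, 1] <- 5
  cnt$d4["strait", 1, 2] <- 1
  cnt$d8["strait", 1, 2] <- 2
  cnt <- stay_pseudocount(cnt, c(hinchinbrook = 0.5, strait = 0.3,
                                 passages = 0.7))
  expect_equal(cnt$drr["hinchinbrook", 1, 1], 4.0)
  expect_equal(cnt$drr["strait", 1, 2], 0.9)
  expect_equal(cnt$drr["passages", 1, 1], 0)
  expect_error(stay_pseudocount(cnt, c(hinchinbrook = -1, strait = 0,
                                       passages = 0)), "nonnegative")
})

test_that("extract_passages seasons passages by exit time and writes CSV", {
  reg <- toy_registry()
  g <- build_grid("2017-04-01", "2019-03-31")
  t0 <- UTC("2017-08-30 12:00:00") # exit drifts into September
  d <- make_detections(rep("A", 3), c("I1", "O1", "O1"),
                       c(t0, t0 + 20 * 3600, t0 + 42 * 3600))
  p <- extract_passages(d, reg, g)
  expect_equal(nrow(p), 1L)
  expect_equal(p$direction, "sound_to_gulf")
  expect_equal(p$season,
               g$season_of_occ[occasion_of(g, t0 + 42 * 3600)])
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_passages(p, tmp)
  expect_equal(read.csv(tmp)$direction, "sound_to_gulf")
})
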