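# occasion grid, presence rule, observation matrices

test_that("the default two-year weekly grid has 105 occasions and 4 seasons", {
  g <- build_grid("2017-04-01", "2019-03-31")
  expect_equal(g$f, 105L)
  expect_equal(g$n_season, 4L)
  # second season starts at the first occasion whose start date is >= Sep 1
  first_b2 <- g$seasons$first[2]
  expect_true(occasion_start(g, first_b2) >= UTC("2017-09-01"))
  expect_true(occasion_start(g, first_b2 - 1L) < UTC("2017-09-01"))
  # seasons partition 1..f
  expect_equal(unname(unlist(Map(seq, g$seasons$first, g$seasons$last))),
               1:105)
})

test_that("single-season and misordered season configs behave", {
  g <- build_grid("2017-04-01", "2017-12-31", season_starts = character(0))
  expect_equal(g$n_season, 1L)
  expect_error(build_grid("2017-04-01", "2018-03-31",
                          season_starts = c("2017-11-01", "2017-09-01")),
               "increasing")
})

test_that("occasion lookup inverts occasion start times", {
  g <- build_grid("2017-04-01", "2019-03-31")
  j <- c(1L, 2L, 50L, 105L)
  expect_equal(occasion_of(g, occasion_start(g, j)), j)
  # half-open: the last instant before a boundary belongs to the previous one
  expect_equal(occasion_of(g, occasion_start(g, 10L) - 1), 9L)
})

test_that("transmitter life uses floor in occasions", {
  expect_equal(transmitter_life_occasions(246), 35L)
  expect_equal(transmitter_life_occasions(755), 107L)
  expect_equal(transmitter_life_occasions(7), 1L)
  expect_error(transmitter_life_occasions(0), "positive")
})

test_that("presence requires two detections within 24 h at one array", {
  g <- toy_grid(weeks = 4)
  reg <- toy_registry()
  t0 <- occasion_start(g, 2) + 10 * 3600
  # two detections 23 h apart: present
  p <- assign_presence(make_detections("A", c("S1", "S2"),
                                       t0 + c(0, 23 * 3600)), reg, g)
  expect_equal(nrow(p), 1L)
  expect_equal(p$group, "spawn")
  expect_equal(p$occasion, 2L)
  # single detection: absent
  p <- assign_presence(make_detections("A", "S1", t0), reg, g)
  expect_equal(nrow(p), 0L)
  # two detections 25 h apart: absent
  p <- assign_presence(make_detections("A", c("S1", "S1"),
                                       t0 + c(0, 25 * 3600)), reg, g)
  expect_equal(nrow(p), 0L)
  # unknown receiver
  expect_error(assign_presence(make_detections("A", "XX", t0), reg, g),
               "XX")
})

test_that("clusters spanning an occasion boundary mark both occasions", {
  g <- toy_grid(weeks = 4)
  reg <- toy_registry()
  tb <- occasion_start(g, 3) # boundary between occasions 2 and 3
  p <- assign_presence(make_detections("A", c("S1", "S1"),
                                       tb + c(-3600, 3600)), reg, g)
  expect_setequal(p$occasion, c(2L, 3L))
})

test_that("presence is monotone: adding detections never removes presence", {
  g <- toy_grid(weeks = 6)
  reg <- toy_registry()
  set.seed(71)
  base_t <- occasion_start(g, 1)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    d <- make_detections("A", sample(c("S1", "S2", "I1", "O1"), n, TRUE),
                         base_t + sort(runif(n, 0, 35 * 86400)))
    p1 <- assign_presence(d, reg, g)
    extra <- make_detections("A", "S1",
                             base_t + runif(3, 0, 35 * 86400))
    p2 <- assign_presence(rbind(d, extra), reg, g)
    k1 <- paste(p1$group, p1$occasion)
    k2 <- paste(p2$group, p2$occasion)
    expect_true(all(k1 %in% k2))
  }
})

test_that("observation matrices code presence and resolve multi-array weeks", {
  g <- toy_grid(weeks = 12)
  reg <- toy_registry()
  dep <- as_deployments_for_test(weight = c(100, 120))
  dep$release_time <- occasion_start(g, 1) + 86400
  dep$transmitter_life_days <- 70 # 10 occasions
  t10 <- occasion_start(g, 10) + 12 * 3600
  d <- make_detections(rep("T1", 2), c("I1", "I1"), t10 + c(0, 3600))
  p <- assign_presence(d, reg, g)
  obs <- build_observation_matrix(p, dep, g)
  expect_equal(obs$release_occ, c(1L, 1L))
  expect_equal(obs$last_occ, c(11L, 11L))
  expect_equal(unname(obs$X["T1", 10]), 4L) # hinchinbrook code
  expect_true(all(obs$X["T1", c(2:9, 11)] == 1L))
  expect_true(all(obs$X["T2", 2:11] == 1L)) # never detected
  expect_true(all(obs$X[, 12] == 0L)) # outside active window

  # spawn and entrance in the same week: latest qualifying detection wins
  t5 <- occasion_start(g, 5) + 12 * 3600
  d2 <- make_detections(rep("T1", 4), c("S1", "S1", "I1", "I1"),
                        t5 + c(0, 1800, 7200, 10800))
  p2 <- assign_presence(d2, reg, g)
  expect_warning(obs2 <- build_observation_matrix(p2, dep, g),
                 "several arrays")
  expect_equal(unname(obs2$X["T1", 5]), 4L) # entrance cluster ends later
})

test_that("fish released after the grid end are excluded with a warning", {
  g <- toy_grid(weeks = 4)
  dep <- as_deployments_for_test(weight = c(100, 120))
  dep$release_time <- c(occasion_start(g, 1) + 86400,
                        occasion_start(g, 4) + 40 * 86400)
  p <- assign_presence(make_detections(character(0), character(0),
                                       UTC(character(0))),
                       toy_registry(), g)
  expect_warning(obs <- build_observation_matrix(p, dep, g), "excluding")
  expect_equal(obs$tag_id, "T1")
})

test_that("observation validation flags impossible consecutive pairs", {
  g <- toy_grid(weeks = 8)
  # 2,1,4: feasible (spawn -> sound -> hinchinbrook)
  obs <- toy_obs(list(c(2L, 1L, 4L)), g)
  v <- validate_observations(obs)
  expect_equal(nrow(v$violations), 0L)
  # 4,1,2: feasible (hinchinbrook -> sound -> spawn)
  obs <- toy_obs(list(c(4L, 1L, 2L)), g)
  expect_equal(nrow(validate_observations(obs)$violations), 0L)
  # 2,4 consecutive: impossible (spawn cannot reach an entrance in one step)
  obs <- toy_obs(list(c(2L, 4L)), g)
  expect_error(validate_observations(obs, mode = "strict"), "T1")
  v <- validate_observations(obs, mode = "report")
  expect_equal(v$violations$occasion, 2L)
  expect_message(rep <- validate_observations(obs, mode = "repair"),
                 "repaired")
  expect_equal(unname(rep$obs$X[1, 2]), 1L)
  expect_equal(nrow(validate_observations(rep$obs)$violations), 0L)
})

test_that("observation matrices serialize to CSV", {
  g <- toy_grid(weeks = 4)
  obs <- toy_obs(list(c(1L, 2L), c(4L, 1L, 1L)), g)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, tmp)
  df <- read.csv(tmp)
  expect_equal(nrow(df), 2L)
  expect_equal(df$occ2, c(1L, 4L))
  expect_equal(df$occ4[2], 1L)
  expect_equal(df$occ4[1], 0L)
})
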