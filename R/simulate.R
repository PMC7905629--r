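# ---- synthetic-data generator -----------------------------------------------

#' Default receiver registry for simulation
#'
#' A registry shaped like the study system: one spawning-grounds array, one
#' interior array, and three entrances with paired inner/outer receiver
#' lines. Hinchinbrook and the Strait carry a partial outer line, so some of
#' their inner receivers lack a complementary outer receiver
#' (`has_complement = FALSE`); the Passages lines are fully paired.
#'
#' @return A receiver registry data frame (`asmove_receivers`).
#' @export
default_registry <- function() {
  mk <- function(id, array_name, role, entrance_id = NA, line = "none",
                 has_complement = TRUE)
    data.frame(receiver_id = id, array_name = array_name, role = role,
               entrance_id = entrance_id, line = line,
               has_complement = has_complement, stringsAsFactors = FALSE)
  df <- rbind(
    mk(sprintf("SP%02d", 1:6), "spawn-east", "spawn"),
    mk(sprintf("IN%02d", 1:5), "interior", "interior"),
    mk(sprintf("HIN-I%02d", 1:6), "hinchinbrook-inner", "entrance",
       "hinchinbrook", "inner"),
    mk(sprintf("HIN-I%02d", 7:8), "hinchinbrook-inner", "entrance",
       "hinchinbrook", "inner", FALSE),
    mk(sprintf("HIN-O%02d", 1:6), "hinchinbrook-outer", "entrance",
       "hinchinbrook", "outer"),
    mk(sprintf("STR-I%02d", 1:5), "strait-inner", "entrance", "strait",
       "inner"),
    mk(sprintf("STR-I%02d", 6:7), "strait-inner", "entrance", "strait",
       "inner", FALSE),
    mk(sprintf("STR-O%02d", 1:5), "strait-outer", "entrance", "strait",
       "outer"),
    mk(sprintf("PAS-I%02d", 1:7), "passages-inner", "entrance", "passages",
       "inner"),
    mk(sprintf("PAS-O%02d", 1:7), "passages-outer", "entrance", "passages",
       "outer"))
  df <- validate_receivers(df)
  class(df) <- c("asmove_receivers", "data.frame")
  df
}

#' Seasonal true parameters for simulation
#'
#' The generator's default movement and survival probabilities. Entrance
#' movement simplexes and the Sound/Gulf entry rates follow the magnitudes
#' reported for the study system (a seasonal oscillation at Hinchinbrook:
#' Sound-to-Gulf crossings dominate in spring/summer, Gulf-to-Sound in
#' fall/winter); weekly Sound mortality is 0.16, 0.01, 0.09, 0.03 across the
#' four seasons. Seasons alternate spring/summer (odd k) and fall/winter
#' (even k). With two classes, the heavier class is more likely to move from
#' the Sound to the Strait in spring/summer and less likely to return to the
#' spawning grounds in fall/winter.
#'
#' @param n_class 1 or 2.
#' @param n_season number of seasons (default 4).
#' @return An [asmove_params] object.
#' @export
default_true_params <- function(n_class = 2L, n_season = 4L) {
  spring <- function(k) k %% 2L == 1L
  psi <- list()
  pick <- function(sp, fa, k) if (spring(k)) sp else fa
  mk_block <- function(vals_by_class) {
    nd <- length(vals_by_class[[1]][[1]])
    b <- array(NA_real_, dim = c(n_class, n_season, nd))
    for (y in seq_len(n_class)) {
      vc <- vals_by_class[[min(y, length(vals_by_class))]]
      for (k in seq_len(n_season))
        b[y, k, ] <- pick(vc$spring, vc$fall, k)
    }
    b
  }
  psi[["2"]] <- mk_block(list(list(spring = c(0.70, 0.30),
                                   fall = c(0.90, 0.10))))
  psi[["3"]] <- mk_block(list(list(spring = c(0.50, 0.50),
                                   fall = c(0.50, 0.50))))
  psi[["4"]] <- mk_block(list(
    list(spring = c(0.10, 0.02, 0.69, 0.09, 0.05, 0.05),   # class 0
         fall = c(0.20, 0.02, 0.71, 0.02, 0.03, 0.02)),
    list(spring = c(0.08, 0.02, 0.66, 0.09, 0.10, 0.05),   # class 1
         fall = c(0.10, 0.02, 0.81, 0.02, 0.03, 0.02))))
  # entrance simplexes over (4, r, 8); seasonal medians of the study system
  hin <- list(s1 = c(0.24, 0.37, 0.39), s2 = c(0.42, 0.24, 0.34),
              s3 = c(0.27, 0.34, 0.39), s4 = c(0.59, 0.22, 0.19))
  str <- list(s1 = c(0.18, 0.45, 0.37), s2 = c(0.23, 0.56, 0.21),
              s3 = c(0.36, 0.52, 0.12), s4 = c(0.13, 0.48, 0.39))
  pas <- list(s1 = c(0.22, 0.43, 0.35), s2 = c(0.25, 0.43, 0.32),
              s3 = c(0.21, 0.50, 0.29), s4 = c(0.31, 0.36, 0.33))
  mk_ent <- function(tab) {
    b <- array(NA_real_, dim = c(n_class, n_season, 3))
    for (y in seq_len(n_class))
      for (k in seq_len(n_season))
        b[y, k, ] <- tab[[min(k, 4L)]]
    b
  }
  psi[["5"]] <- mk_ent(hin)
  psi[["6"]] <- mk_ent(str)
  psi[["7"]] <- mk_ent(pas)
  psi[["8"]] <- mk_block(list(list(spring = c(0.02, 0.02, 0.02, 0.94),
                                   fall = c(0.02, 0.07, 0.03, 0.88))))
  S <- array(NA_real_, dim = c(n_class, n_season, 2),
             dimnames = list(NULL, NULL, c("4", "8")))
  mort4 <- c(0.16, 0.01, 0.09, 0.03)
  mort8 <- c(0.12, 0.02, 0.08, 0.04)
  for (k in seq_len(n_season)) {
    kk <- min(k, 4L)
    S[, k, "4"] <- 1 - mort4[kk]
    S[, k, "8"] <- 1 - mort8[kk]
  }
  asmove_params(psi, S)
}

#' Simulation scenario
#'
#' Collects the generator's conditions: release design (124 fish in April of
#' year 1, 202 in April of year 2 by default), transmitter lives (246 d for
#' 60 fish, 759 d for the rest), covariate distributions, fine-scale
#' entrance-detection geometry and corruption rates.
#'
#' @param n_fish total number of fish.
#' @param cohort_fraction fraction released in the first April (default
#'   124/326).
#' @param start,end study window (defaults: two years from 2017-04-01).
#' @param occasion_days occasion length in days.
#' @param n_v8 number of short-life (246 d, 2.0 g) transmitters; the rest are
#'   759 d, 3.6 g.
#' @param true_params optional [asmove_params]; default
#'   [default_true_params()].
#' @param n_class classes for the default true parameters.
#' @param coincident_rate probability that a crossing's first detections
#'   coincide across lines (default 0.05).
#' @param missing_complement_rate probability that a crossing is routed via
#'   an unpaired inner receiver where the entrance has one (default 0.10).
#' @param lag_hours inner/outer lag within a crossing (default 1 h).
#' @return A list of class `asmove_scenario`.
#' @export
simulation_scenario <- function(n_fish = 326L, cohort_fraction = 124 / 326,
                                start = "2017-04-01", end = "2019-03-31",
                                occasion_days = 7, n_v8 = 60L,
                                true_params = NULL, n_class = 2L,
                                coincident_rate = 0.05,
                                missing_complement_rate = 0.10,
                                lag_hours = 1) {
  stopifnot(n_fish >= 1, coincident_rate >= 0, coincident_rate <= 1,
            missing_complement_rate >= 0, missing_complement_rate <= 1)
  structure(list(n_fish = as.integer(n_fish),
                 cohort_fraction = cohort_fraction, start = start, end = end,
                 occasion_days = occasion_days,
                 n_v8 = min(as.integer(n_v8), as.integer(n_fish)),
                 true_params = true_params, n_class = as.integer(n_class),
                 coincident_rate = coincident_rate,
                 missing_complement_rate = missing_complement_rate,
                 lag_hours = lag_hours),
            class = "asmove_scenario")
}

#' Simulate the tag deployment table
#'
#' Weights, lengths, sex, tag weights and release times for the scenario's
#' fish. Lengths are normal (210 +/- 12 mm standard length), condition
#' normal (1.15e-5 +/- 8e-7 g mm^-3), weight derived as
#' `condition * length^3`; releases fall in the first three weeks of April
#' of each cohort year.
#'
#' @param scenario a [simulation_scenario()].
#' @return A deployment table (`asmove_deployments`).
#' @export
simulate_covariates <- function(scenario) {
  n <- scenario$n_fish
  n1 <- round(n * scenario$cohort_fraction)
  y0 <- as.integer(substr(scenario$start, 1, 4))
  cohort_year <- c(rep(y0, n1), rep(y0 + 1L, n - n1))
  rel_day <- sample(0:20, n, replace = TRUE)
  rel_sec <- runif(n, 8 * 3600, 18 * 3600)
  release <- as.POSIXct(sprintf("%d-04-01", cohort_year), tz = "UTC") +
    rel_day * 86400 + rel_sec
  length_mm <- rnorm(n, 210, 12)
  condition <- rnorm(n, 1.15e-5, 8e-7)
  weight <- condition * length_mm^3
  v8 <- rep(FALSE, n)
  v8[sample.int(n, scenario$n_v8)] <- TRUE
  dep <- data.frame(
    tag_id = sprintf("F%03d", seq_len(n)),
    release_time = release,
    transmitter_life_days = ifelse(v8, 246, 759),
    weight_g = round(weight, 1),
    length_mm = round(length_mm),
    sex = sample(c("F", "M"), n, replace = TRUE),
    tag_weight_g = ifelse(v8, 2.0, 3.6),
    stringsAsFactors = FALSE)
  as_deployments(dep)
}

# core latent-path simulation on precomputed windows; returns obs + paths
simulate_paths_core <- function(params, grid, rel, last, cls, tag_id) {
  n <- length(rel)
  f <- grid$f
  paths <- matrix(0L, n, f, dimnames = list(tag_id, NULL))
  X <- matrix(0L, n, f, dimnames = list(tag_id, NULL))
  trans <- transition_array(params)
  z <- integer(n)
  for (i in seq_len(n)) if (rel[i] >= 1 && rel[i] <= f) paths[i, rel[i]] <- 2L
  z[] <- 2L
  active_any <- any(last > rel)
  if (active_any) {
    for (j in (min(rel) + 1L):max(last)) {
      act <- which(rel < j & last >= j)
      for (i in act) {
        k <- grid$season_of_occ[j - 1L]
        p <- trans[z[i], , cls[i], k]
        z[i] <- sample.int(8L, 1L, prob = p)
        paths[i, j] <- z[i]
        X[i, j] <- EMISSION_MAP[z[i]]
      }
      # reset fish whose window starts later than current j (not yet active)
      not_started <- which(rel >= j)
      z[not_started] <- 2L
    }
  }
  obs <- structure(list(X = X, release_occ = rel, last_occ = last,
                        tag_id = tag_id, grid = grid),
                   class = "asmove_obs")
  list(obs = obs, paths = paths)
}

#' Simulate latent paths and the observation matrix
#'
#' Every fish starts in the spawning-grounds state at its release occasion;
#' states evolve by the true seasonal transition matrices; observations
#' follow deterministically from the emission map, truncated at
#' `min(c_i + l_i, f)`.
#'
#' @param params true [asmove_params].
#' @param grid occasion grid.
#' @param deployments deployment table.
#' @param classing optional classing (class-specific dynamics).
#' @return List with `obs` (an `asmove_obs`) and `paths` (fish x occasion
#'   latent state matrix).
#' @export
simulate_paths <- function(params, grid, deployments, classing = NULL) {
  rel <- occasion_of(grid, deployments$release_time)
  if (any(rel < 1L | rel > grid$f))
    stop("release outside the occasion grid")
  l_occ <- transmitter_life_occasions(deployments$transmitter_life_days,
                                      grid$occasion_days)
  last <- pmin(rel + l_occ, grid$f)
  cls <- if (is.null(classing)) rep(1L, nrow(deployments)) else
    as.integer(classing$y[deployments$tag_id]) + 1L
  simulate_paths_core(params, grid, rel, last, cls, deployments$tag_id)
}

# receivers of one entrance by line, split by complement status
entrance_receiver_sets <- function(receivers) {
  out <- list()
  for (e in names(ENTRANCE_STATES)) {
    rr <- receivers[receivers$role == "entrance" &
                      receivers$entrance_id == e, ]
    out[[e]] <- list(
      inner = rr$receiver_id[rr$line == "inner" & rr$has_complement],
      inner_nc = rr$receiver_id[rr$line == "inner" & !rr$has_complement],
      outer = rr$receiver_id[rr$line == "outer"])
  }
  out
}

#' Simulate the fine-scale detection stream
#'
#' Emits timestamped detections consistent with the latent paths: every
#' occupied array occasion produces a qualifying cluster (two detections
#' within 24 h, inside the occasion), and every entrance crossing produces
#' inner-then-outer (Sound to Gulf) or outer-then-inner (Gulf to Sound)
#' detections separated by the configured lag. Crossings are corrupted at
#' the configured rates: coincident first timestamps across lines, or
#' routing through an inner receiver that lacks an outer complement (where
#' the entrance has such a receiver).
#'
#' @param sim output of [simulate_paths()].
#' @param receivers receiver registry.
#' @param scenario a [simulation_scenario()] (corruption rates, lag).
#' @return List with `detections` (an `asmove_detections` data frame) and
#'   `truth` (one row per entrance visit: `tag_id`, `entrance`, `occasion`,
#'   `direction` = sound_to_gulf / gulf_to_sound / none, `corrupted`,
#'   `corruption` = none / coincident / missing_complement).
#' @export
simulate_entrance_detections <- function(sim, receivers, scenario) {
  grid <- sim$obs$grid
  sets <- entrance_receiver_sets(receivers)
  spawn_ids <- receivers$receiver_id[receivers$role == "spawn"]
  int_ids <- receivers$receiver_id[receivers$role == "interior"]
  lag <- scenario$lag_hours * 3600
  d_tag <- list(); d_rid <- list(); d_time <- list(); nd <- 0L
  tru <- list(); nt <- 0L
  add_det <- function(tag, rid, t) {
    nd <<- nd + 1L
    d_tag[[nd]] <<- tag
    d_rid[[nd]] <<- rid
    d_time[[nd]] <<- round(as.numeric(t))
  }
  cluster_base <- function(j) # inside the occasion, clear of its boundaries
    occasion_start(grid, j) + runif(1, 6, 138) * 3600
  n <- nrow(sim$paths)
  for (i in seq_len(n)) {
    tag <- sim$obs$tag_id[i]
    rel <- sim$obs$release_occ[i]; last <- sim$obs$last_occ[i]
    if (last <= rel) next
    zz <- sim$paths[i, ]
    for (j in (rel + 1L):last) {
      z <- zz[j]
      if (z == 2L || z == 3L) {
        rid <- sample(if (z == 2L) spawn_ids else int_ids, 1L)
        b <- cluster_base(j)
        add_det(tag, rid, b)
        add_det(tag, rid, b + 1800)
      }
    }
    # entrance runs
    ent_occ <- which(zz %in% ENTRANCE_STATES & seq_along(zz) > rel &
                       seq_along(zz) <= last)
    if (!length(ent_occ)) next
    runs <- split(ent_occ, cumsum(c(1L, diff(ent_occ) != 1L)))
    for (run in runs) {
      t1 <- run[1]; t2 <- run[length(run)]
      state <- zz[t1]
      e <- names(ENTRANCE_STATES)[match(state, ENTRANCE_STATES)]
      prev <- zz[t1 - 1L]
      nxt <- if (t2 + 1L <= last) zz[t2 + 1L] else NA_integer_
      entry_side <- if (prev == 8L) "outer" else "inner"
      exit_side <- if (is.na(nxt)) entry_side else
        if (nxt == 8L) "outer" else if (nxt == 4L) "inner" else entry_side
      for (t in run) {
        first_line <- entry_side # dwell weeks sit on the arrival side
        last_line <- if (t == t2) exit_side else entry_side
        crossing <- t == t2 && !is.na(nxt) && first_line != last_line
        b <- cluster_base(t)
        direction <- "none"; corruption <- "none"
        if (!crossing) {
          rid <- sample(sets[[e]][[first_line]], 1L)
          add_det(tag, rid, b)
          add_det(tag, rid, b + 1800)
        } else {
          direction <- if (first_line == "inner") "sound_to_gulf" else
            "gulf_to_sound"
          rid1 <- sample(sets[[e]][[first_line]], 1L)
          rid2 <- sample(sets[[e]][[last_line]], 1L)
          u <- runif(1)
          if (u < scenario$coincident_rate) {
            corruption <- "coincident"
            add_det(tag, rid1, b)
            add_det(tag, rid2, b) # same-second detection on the other line
            add_det(tag, rid2, b + lag)
          } else if (u < scenario$coincident_rate +
                       scenario$missing_complement_rate &&
                     length(sets[[e]]$inner_nc)) {
            corruption <- "missing_complement"
            nc <- sample(sets[[e]]$inner_nc, 1L)
            if (first_line == "inner") {
              add_det(tag, nc, b)
              add_det(tag, rid2, b + lag)
            } else {
              add_det(tag, rid1, b)
              add_det(tag, nc, b + lag)
            }
          } else {
            add_det(tag, rid1, b)
            add_det(tag, rid2, b + lag)
          }
        }
        nt <- nt + 1L
        tru[[nt]] <- c(tag, e, t, direction, corruption)
      }
    }
  }
  detections <- if (nd)
    data.frame(tag_id = unlist(d_tag), receiver_id = unlist(d_rid),
               timestamp = as.POSIXct(unlist(d_time), tz = "UTC",
                                      origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  else
    data.frame(tag_id = character(), receiver_id = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"))
  detections <- detections[order(detections$timestamp, detections$tag_id), ]
  rownames(detections) <- NULL
  truth <- if (nt) {
    m <- do.call(rbind, tru)
    data.frame(tag_id = m[, 1], entrance = m[, 2],
               occasion = as.integer(m[, 3]), direction = m[, 4],
               corrupted = m[, 5] != "none", corruption = m[, 5],
               stringsAsFactors = FALSE)
  } else
    data.frame(tag_id = character(), entrance = character(),
               occasion = integer(), direction = character(),
               corrupted = logical(), corruption = character())
  list(detections = as_detections(detections), truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs the full generative model: covariates and release schedule, latent
#' weekly paths under the true seasonal parameters, and the fine-scale
#' detection stream, on the default two-year weekly grid.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed (all generator randomness flows from it).
#' @return List with `detections`, `receivers`, `deployments`, `grid`,
#'   `classing`, `params` (truth), `obs`, `paths`, `truth` (per-visit
#'   direction truth table).
#' @export
simulate_dataset <- function(scenario = simulation_scenario(), seed = 1L) {
  set.seed(seed)
  receivers <- default_registry()
  deployments <- simulate_covariates(scenario)
  grid <- build_grid(scenario$start, scenario$end,
                     occasion_days = scenario$occasion_days)
  classing <- covariate_classing(deployments,
                                 if (scenario$n_class == 2L) "weight" else
                                   "none")
  params <- scenario$true_params
  if (is.null(params))
    params <- default_true_params(classing$n_class, grid$n_season)
  if (params$n_season != grid$n_season)
    stop("true parameters and grid disagree on seasons")
  sim <- simulate_paths(params, grid, deployments, classing)
  fine <- simulate_entrance_detections(sim, receivers, scenario)
  list(detections = fine$detections, receivers = receivers,
       deployments = deployments, grid = grid, classing = classing,
       params = params, obs = sim$obs, paths = sim$paths,
       truth = fine$truth)
}
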