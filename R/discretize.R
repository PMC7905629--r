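# ---- occasion grid and weekly observation matrices --------------------------

#' Build the detection-occasion grid
#'
#' Occasions are contiguous half-open intervals `[start, start + length)`
#' counted from 1 at the study start. Each occasion belongs to exactly one
#' season bin, decided by the calendar date of the occasion's start instant.
#'
#' @param start study start date (`Date` or ISO string); start of occasion 1.
#' @param end study end date; the final occasion `f` is the one containing it.
#' @param occasion_days occasion length in days (default 7, weekly).
#' @param season_starts ordered vector of season-boundary dates; the first
#'   season begins at `start`, each subsequent season at the listed date.
#'   Defaults to the two-year April/September alternation beginning at
#'   `start`.
#' @param season_labels optional labels, length `length(season_starts) + 1`.
#' @return An object of class `occasion_grid`: list with `origin` (POSIXct),
#'   `occasion_days`, `f`, `seasons` (data frame label/first/last occasion),
#'   `season_of_occ` (integer vector of length `f`), `n_season`.
#' @export
#' @examples
#' g <- build_grid("2017-04-01", "2019-03-31")
#' g$f # 105 weekly occasions
build_grid <- function(start, end, occasion_days = 7,
                       season_starts = NULL, season_labels = NULL) {
  origin <- parse_iso8601(as.character(start))
  stop_t <- parse_iso8601(as.character(end))
  if (is.na(origin) || is.na(stop_t)) stop("unparseable start/end date")
  if (stop_t <= origin) stop("end date must be after start date")
  f <- occasion_of_time(stop_t, origin, occasion_days)
  if (is.null(season_starts)) {
    y0 <- as.integer(format(origin, "%Y", tz = "UTC"))
    cand <- as.POSIXct(c(sprintf("%d-09-01", y0), sprintf("%d-04-01", y0 + 1),
                         sprintf("%d-09-01", y0 + 1)), tz = "UTC")
    season_starts <- cand[cand > origin & cand <= stop_t]
  } else {
    season_starts <- parse_iso8601(as.character(season_starts))
    if (any(is.na(season_starts))) stop("unparseable season boundary")
  }
  bounds <- c(origin, season_starts)
  if (is.unsorted(as.numeric(bounds), strictly = TRUE))
    stop("season boundaries must be strictly increasing and after start")
  if (length(season_starts) && max(as.numeric(season_starts)) > as.numeric(stop_t))
    stop("season boundary beyond study end")
  n_season <- length(bounds)
  if (is.null(season_labels)) season_labels <- paste0("B", seq_len(n_season))
  if (length(season_labels) != n_season)
    stop("need ", n_season, " season labels")
  occ_start <- origin + (seq_len(f) - 1) * occasion_days * 86400
  season_of_occ <- findInterval(as.numeric(occ_start), as.numeric(bounds))
  if (is.unsorted(season_of_occ)) stop("season assignment not monotone")
  seasons <- data.frame(label = season_labels,
                        first = vapply(seq_len(n_season), function(k)
                          min(which(season_of_occ == k)), 1L),
                        last = vapply(seq_len(n_season), function(k)
                          max(which(season_of_occ == k)), 1L))
  structure(list(origin = origin, occasion_days = occasion_days, f = f,
                 seasons = seasons, season_of_occ = season_of_occ,
                 n_season = n_season),
            class = "occasion_grid")
}

occasion_of_time <- function(t, origin, occasion_days) {
  as.integer(floor(as.numeric(difftime(t, origin, units = "days")) /
                     occasion_days)) + 1L
}

#' Occasion index containing an instant
#' @param grid an [build_grid()] object.
#' @param t POSIXct instant(s).
#' @return Integer occasion indices (may fall outside `1..f` for instants
#'   outside the study window).
#' @export
occasion_of <- function(grid, t) occasion_of_time(t, grid$origin,
                                                  grid$occasion_days)

#' Start instant of an occasion
#' @param grid an [build_grid()] object.
#' @param j occasion index.
#' @return POSIXct start of the half-open occasion interval.
#' @export
occasion_start <- function(grid, j) grid$origin + (j - 1) * grid$occasion_days * 86400

#' Transmitter life in whole occasions
#'
#' Uses floor: a partly covered occasion cannot guarantee an active
#' transmitter, so it is censored.
#'
#' @param l_days battery life in days (> 0).
#' @param occasion_days occasion length in days.
#' @return Integer number of occasions.
#' @export
#' @examples
#' transmitter_life_occasions(246) # 35
transmitter_life_occasions <- function(l_days, occasion_days = 7) {
  if (any(l_days <= 0)) stop("transmitter life must be positive")
  as.integer(floor(l_days / occasion_days))
}

# map a receiver row to its array group (the state-level aggregation)
receiver_group <- function(receivers) {
  ifelse(receivers$role == "entrance", receivers$entrance_id, receivers$role)
}

#' Score weekly array presence from raw detections
#'
#' A fish is present at an array group in an occasion iff at least one of its
#' detections there in that occasion belongs to a qualifying cluster: a
#' maximal run of detections at that group with inter-detection gaps of at
#' most 24 h, containing two or more detections. Clusters spanning an
#' occasion boundary mark presence in every occasion they touch.
#'
#' @param detections a detection log ([read_detections()]).
#' @param receivers a receiver registry ([read_receivers()]).
#' @param grid an occasion grid ([build_grid()]).
#' @param window_hours qualifying-cluster gap in hours (default 24).
#' @return Data frame of class `asmove_presence` with columns `tag_id`,
#'   `occasion`, `group` (spawn/interior/hinchinbrook/strait/passages) and
#'   `last_detection` (latest qualifying detection of that group in that
#'   occasion, used for multi-array tie-breaking).
#' @export
assign_presence <- function(detections, receivers, grid, window_hours = 24) {
  unknown <- setdiff(unique(detections$receiver_id), receivers$receiver_id)
  if (length(unknown))
    stop("unknown receiver id(s): ", paste(unknown, collapse = ", "))
  grp <- setNames(receiver_group(receivers), receivers$receiver_id)
  d <- data.frame(tag_id = detections$tag_id,
                  group = unname(grp[detections$receiver_id]),
                  timestamp = detections$timestamp)
  d <- d[order(d$tag_id, d$group, d$timestamp), ]
  out <- list(); n_out <- 0L
  for (key in split(seq_len(nrow(d)), list(d$tag_id, d$group), drop = TRUE)) {
    ts <- d$timestamp[key]
    gaps <- diff(as.numeric(ts))
    cluster <- cumsum(c(0, gaps > window_hours * 3600))
    for (cl in split(seq_along(ts), cluster)) {
      if (length(cl) < 2L) next
      occ <- occasion_of(grid, ts[cl])
      for (j in unique(occ)) {
        if (j < 1L || j > grid$f) next
        n_out <- n_out + 1L
        out[[n_out]] <- data.frame(tag_id = d$tag_id[key[1]],
                                   group = d$group[key[1]], occasion = j,
                                   last_detection = max(ts[cl][occ == j]))
      }
    }
  }
  if (!n_out) {
    res <- data.frame(tag_id = character(), group = character(),
                      occasion = integer(),
                      last_detection = as.POSIXct(character(), tz = "UTC"))
  } else {
    res <- do.call(rbind, out)
    # a group can contribute several clusters to one occasion; keep the latest
    res <- res[order(res$tag_id, res$group, res$occasion,
                     res$last_detection), ]
    keep <- !duplicated(res[, c("tag_id", "group", "occasion")],
                        fromLast = TRUE)
    res <- res[keep, ]
    rownames(res) <- NULL
  }
  class(res) <- c("asmove_presence", "data.frame")
  res
}

GROUP_OBS_CODE <- c(spawn = 2L, interior = 3L, hinchinbrook = 4L,
                    strait = 5L, passages = 6L)

#' Build the weekly observation matrix
#'
#' For each fish, observations run over the active window
#' `N_i = {c_i + 1, ..., c_i + l_i}` intersected with `1..f`, where `c_i` is
#' the occasion containing the release instant and `l_i` the transmitter life
#' in occasions. Code 1 means no array presence; otherwise the code of the
#' present array. When two arrays register presence in one occasion, the
#' array whose last qualifying detection is latest wins (it carries the
#' direction of travel into the next occasion); ties are logged as warnings.
#'
#' @param presence output of [assign_presence()].
#' @param deployments a deployment table.
#' @param grid an occasion grid.
#' @return An object of class `asmove_obs`: list with integer matrix `X`
#'   (fish x occasion, 0 outside the active window, codes 1..6 inside),
#'   `release_occ`, `last_occ`, `tag_id`, `grid`.
#' @export
build_observation_matrix <- function(presence, deployments, grid) {
  rel <- occasion_of(grid, deployments$release_time)
  keep <- rel <= grid$f & rel >= 1L
  if (any(!keep))
    warning("excluding ", sum(!keep), " fish released outside the grid: ",
            paste(deployments$tag_id[!keep], collapse = ", "))
  dep <- deployments[keep, , drop = FALSE]
  rel <- rel[keep]
  l_occ <- transmitter_life_occasions(dep$transmitter_life_days,
                                      grid$occasion_days)
  last <- pmin(rel + l_occ, grid$f)
  n <- nrow(dep)
  X <- matrix(0L, n, grid$f, dimnames = list(dep$tag_id, NULL))
  for (i in seq_len(n))
    if (last[i] > rel[i]) X[i, (rel[i] + 1L):last[i]] <- 1L
  if (nrow(presence)) {
    pr <- presence[order(presence$tag_id, presence$occasion,
                         presence$last_detection), ]
    idx <- match(pr$tag_id, dep$tag_id)
    for (q in seq_len(nrow(pr))) {
      i <- idx[q]
      if (is.na(i)) next
      j <- pr$occasion[q]
      if (j <= rel[i] || j > last[i]) next
      cur <- X[i, j]
      new <- GROUP_OBS_CODE[[pr$group[q]]]
      if (cur > 1L && cur != new)
        warning(sprintf("fish %s occasion %d present at several arrays; %s wins",
                        dep$tag_id[i], j, pr$group[q]))
      X[i, j] <- new # rows sorted by last_detection: latest wins
    }
  }
  structure(list(X = X, release_occ = rel, last_occ = last,
                 tag_id = dep$tag_id, grid = grid),
            class = "asmove_obs")
}

#' Empty observation set
#'
#' An observation object with no fish on the given grid; fitting it samples
#' from the joint prior (useful for prior-recovery checks).
#'
#' @param grid an occasion grid.
#' @return An `asmove_obs` with zero fish.
#' @export
empty_observations <- function(grid) {
  structure(list(X = matrix(0L, 0, grid$f), release_occ = integer(0),
                 last_occ = integer(0), tag_id = character(0), grid = grid),
            class = "asmove_obs")
}

#' @export
print.asmove_obs <- function(x, ...) {
  cat("Weekly observation matrix:", nrow(x$X), "fish x", x$grid$f,
      "occasions\n")
  act <- x$X > 0
  cat("  active fish-occasions:", sum(act), "; detections:",
      sum(x$X > 1), "\n")
  invisible(x)
}

# one-step observation-level reachability: can code x2 follow code x1?
obs_transition_possible <- function() {
  A <- allowed_transitions()
  M <- matrix(FALSE, 6, 6)
  for (x1 in 1:6)
    for (x2 in 1:6)
      M[x1, x2] <- any(A[feasible_states(x1), feasible_states(x2)])
  M
}

#' Validate an observation matrix against the movement graph
#'
#' Flags every consecutive observed pair that is impossible under the allowed
#' one-step transitions (for example spawn followed immediately by an
#' entrance array with no intervening occasion). In `strict` mode any
#' violation is an error; in `repair` mode the earlier member of each
#' impossible pair is recoded to 1 (no detection) and reported.
#'
#' @param obs an [build_observation_matrix()] object.
#' @param mode `"strict"` (default), `"report"`, or `"repair"`.
#' @return Invisibly (strict/report) or visibly (repair), a list with
#'   `violations` (data frame tag_id/occasion/from/to) and, for repair mode,
#'   the repaired `obs`.
#' @export
validate_observations <- function(obs, mode = c("strict", "report", "repair")) {
  mode <- match.arg(mode)
  ok <- obs_transition_possible()
  v <- list(); nv <- 0L
  X <- obs$X
  for (i in seq_len(nrow(X))) {
    jj <- which(X[i, ] > 0L)
    if (length(jj) < 2L) next
    for (q in seq_len(length(jj) - 1L)) {
      if (jj[q + 1L] != jj[q] + 1L) next
      x1 <- X[i, jj[q]]; x2 <- X[i, jj[q] + 1L]
      if (!ok[x1, x2]) {
        nv <- nv + 1L
        v[[nv]] <- data.frame(tag_id = obs$tag_id[i], occasion = jj[q],
                              from = x1, to = x2)
      }
    }
  }
  violations <- if (nv) do.call(rbind, v) else
    data.frame(tag_id = character(), occasion = integer(),
               from = integer(), to = integer())
  if (nv && mode == "strict")
    stop("impossible consecutive observations for fish ",
         paste(unique(violations$tag_id), collapse = ", "),
         " (occasions ", paste(violations$occasion, collapse = ", "), ")")
  if (mode == "repair" && nv) {
    for (q in seq_len(nv)) {
      i <- match(violations$tag_id[q], obs$tag_id)
      obs$X[i, violations$occasion[q]] <- 1L
    }
    message("repaired ", nv, " impossible observation(s)")
    return(list(violations = violations, obs = obs))
  }
  invisible(list(violations = violations, obs = obs))
}

#' Write an observation matrix to CSV
#'
#' One row per fish, columns `tag_id`, `release_occ`, then occasions `occ1..occf`
#' with 0 for inactive cells and codes 1..6 inside the active window.
#'
#' @param obs an observation object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  df <- data.frame(tag_id = obs$tag_id, release_occ = obs$release_occ,
                   obs$X, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("occ", seq_len(ncol(obs$X)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
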