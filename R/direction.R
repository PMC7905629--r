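# ---- passage direction at two-line entrance arrays --------------------------

#' Segment one fish's entrance detections into visits
#'
#' A visit is a maximal run of detections with inter-detection gaps of at
#' most `gap_hours`; a fish is considered to have left the array once it is
#' undetected for longer than that (strict exceedance, so a gap of exactly
#' 24 h stays within one visit).
#'
#' @param detections data frame with `timestamp` (POSIXct) and `receiver_id`,
#'   all at one entrance for one fish; any order.
#' @param gap_hours visit-closing gap in hours (default 24).
#' @return List of visits; each a data frame of the detections in time order.
#' @export
#' @examples
#' t0 <- as.POSIXct("2017-06-01", tz = "UTC")
#' d <- data.frame(receiver_id = "r1", timestamp = t0 + c(0, 10, 40) * 3600)
#' length(segment_visits(d)) # 2
segment_visits <- function(detections, gap_hours = 24) {
  if (!nrow(detections)) return(list())
  d <- detections[order(detections$timestamp), , drop = FALSE]
  gaps <- diff(as.numeric(d$timestamp))
  run <- cumsum(c(0, gaps > gap_hours * 3600))
  lapply(split(seq_len(nrow(d)), run), function(ix) d[ix, , drop = FALSE])
}

#' Assign a passage direction to a visit
#'
#' A fish moves from the Sound to the Gulf when its first detections of the
#' visit all fall on the entrance's inner receiver line and its last
#' detections all on the outer line; the reverse pattern is a Gulf-to-Sound
#' passage. Direction is left unassigned when the first (or last) detections
#' coincide across the two lines within `tolerance_s` seconds, when the visit
#' touches an inner-line receiver that lacks a complementary outer-line
#' receiver, or when the first and last lines are equal (no crossing).
#'
#' @param visit one visit as returned by [segment_visits()].
#' @param receivers receiver registry.
#' @param tolerance_s coincidence tolerance in seconds (default 0: same
#'   second).
#' @return `"sound_to_gulf"`, `"gulf_to_sound"`, or `"unassigned"`.
#' @export
assign_direction <- function(visit, receivers, tolerance_s = 0) {
  stopifnot(nrow(visit) >= 1L)
  idx <- match(visit$receiver_id, receivers$receiver_id)
  if (anyNA(idx))
    stop("unknown receiver id(s): ",
         paste(visit$receiver_id[is.na(idx)], collapse = ", "))
  rec <- receivers[idx, , drop = FALSE]
  if (any(rec$role != "entrance") || length(unique(rec$entrance_id)) != 1L)
    stop("visit must contain detections at a single entrance array")
  if (any(rec$line == "inner" & !rec$has_complement)) return("unassigned")
  ts <- as.numeric(visit$timestamp)
  firsts <- rec$line[ts <= min(ts) + tolerance_s]
  lasts <- rec$line[ts >= max(ts) - tolerance_s]
  if (length(unique(firsts)) > 1L || length(unique(lasts)) > 1L)
    return("unassigned") # coincident across lines
  first_line <- firsts[1]; last_line <- lasts[1]
  if (first_line == last_line) return("unassigned")
  if (first_line == "inner") "sound_to_gulf" else "gulf_to_sound"
}

#' Extract all entrance passages from a detection log
#'
#' Runs [segment_visits()] and [assign_direction()] per fish and entrance.
#' Each visit is one passage event; a fish crossing an entrance twice
#' contributes two events.
#'
#' @param detections a detection log.
#' @param receivers a receiver registry.
#' @param grid an occasion grid (for the season of the exit time).
#' @param gap_hours visit-closing gap in hours.
#' @param tolerance_s coincidence tolerance in seconds.
#' @return Data frame of class `asmove_passages` with columns `tag_id`,
#'   `entrance`, `entry_time`, `exit_time`, `season` (season of the occasion
#'   containing the exit time, NA outside the grid), `direction`.
#' @export
extract_passages <- function(detections, receivers, grid, gap_hours = 24,
                             tolerance_s = 0) {
  unknown <- setdiff(unique(detections$receiver_id), receivers$receiver_id)
  if (length(unknown))
    stop("unknown receiver id(s): ", paste(unknown, collapse = ", "))
  idx <- match(detections$receiver_id, receivers$receiver_id)
  ent <- receivers$entrance_id[idx]
  d <- detections[receivers$role[idx] == "entrance", , drop = FALSE]
  d$entrance <- ent[receivers$role[idx] == "entrance"]
  rows <- list(); nr <- 0L
  if (nrow(d)) {
    for (part in split(d, list(d$tag_id, d$entrance), drop = TRUE)) {
      visits <- segment_visits(part, gap_hours = gap_hours)
      for (v in visits) {
        nr <- nr + 1L
        exit_t <- max(v$timestamp)
        occ <- occasion_of(grid, exit_t)
        season <- if (occ >= 1L && occ <= grid$f)
          grid$season_of_occ[occ] else NA_integer_
        rows[[nr]] <- data.frame(
          tag_id = part$tag_id[1], entrance = part$entrance[1],
          entry_time = min(v$timestamp), exit_time = exit_t, season = season,
          direction = assign_direction(v, receivers,
                                       tolerance_s = tolerance_s),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (nr) do.call(rbind, rows) else
    data.frame(tag_id = character(), entrance = character(),
               entry_time = as.POSIXct(character(), tz = "UTC"),
               exit_time = as.POSIXct(character(), tz = "UTC"),
               season = integer(), direction = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$tag_id, res$entrance, res$entry_time), ]
  rownames(res) <- NULL
  class(res) <- c("asmove_passages", "data.frame")
  res
}

#' Write passages to CSV
#' @param passages output of [extract_passages()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_passages <- function(passages, path) {
  out <- data.frame(tag_id = passages$tag_id, entrance = passages$entrance,
                    entry_time = format_iso8601(passages$entry_time),
                    exit_time = format_iso8601(passages$exit_time),
                    season = passages$season, direction = passages$direction)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tabulate directional passage counts
#'
#' Counts per entrance r, fish class y and season k: `d4` (Gulf-to-Sound
#' passages, destination state 4) and `d8` (Sound-to-Gulf, destination 8).
#' Unassigned passages and passages whose exit falls outside the season grid
#' contribute nothing.
#'
#' @param passages output of [extract_passages()].
#' @param classing a [covariate_classing()] object.
#' @param grid an occasion grid.
#' @return An object of class `asmove_counts`: list of arrays `d4`, `d8`
#'   (entrance x class x season) plus metadata; `q` and `drr` are attached by
#'   [estimate_q()] / [stay_pseudocount()].
#' @export
tabulate_counts <- function(passages, classing, grid) {
  ents <- names(ENTRANCE_STATES)
  Y <- classing$n_class; K <- grid$n_season
  dm <- list(entrance = ents, class = paste0("y", seq_len(Y) - 1L),
             season = grid$seasons$label)
  d4 <- array(0, dim = c(3, Y, K), dimnames = dm)
  d8 <- array(0, dim = c(3, Y, K), dimnames = dm)
  use <- passages$direction %in% c("sound_to_gulf", "gulf_to_sound") &
    !is.na(passages$season)
  p <- passages[use, , drop = FALSE]
  if (nrow(p)) {
    y <- classing$y[p$tag_id]
    if (anyNA(y)) stop("passage fish missing from classing: ",
                       paste(unique(p$tag_id[is.na(y)]), collapse = ", "))
    for (q in seq_len(nrow(p))) {
      r <- match(p$entrance[q], ents)
      if (p$direction[q] == "gulf_to_sound")
        d4[r, y[q] + 1L, p$season[q]] <- d4[r, y[q] + 1L, p$season[q]] + 1
      else
        d8[r, y[q] + 1L, p$season[q]] <- d8[r, y[q] + 1L, p$season[q]] + 1
    }
  }
  structure(list(d4 = d4, d8 = d8, drr = NULL, q = NULL,
                 n_class = Y, n_season = K),
            class = "asmove_counts")
}

#' Stay/leave ratio at an entrance array
#'
#' `q_r` is the number of fish-occasion pairs present at entrance r in
#' consecutive occasions (stays) divided by the number of pairs present at
#' one occasion but absent at the next (leaves), pooled over fish, occasions,
#' classes and seasons. Pairs whose following occasion lies outside a fish's
#' active window are not counted.
#'
#' @param presence output of [assign_presence()].
#' @param entrance `"hinchinbrook"`, `"strait"` or `"passages"`.
#' @param obs optional observation object supplying each fish's active
#'   window; without it every following occasion up to `f` is assumed active.
#' @param grid occasion grid (required when `obs` is missing).
#' @param fallback optional value returned (with a warning) when no fish ever
#'   leaves; by default a zero denominator is an error.
#' @return The scalar ratio `q_r`.
#' @export
estimate_q <- function(presence, entrance, obs = NULL, grid = NULL,
                       fallback = NULL) {
  if (is.null(grid)) grid <- obs$grid
  if (is.null(grid)) stop("need obs or grid")
  pr <- presence[presence$group == entrance, , drop = FALSE]
  stays <- 0L; leaves <- 0L
  if (nrow(pr)) {
    for (id in unique(pr$tag_id)) {
      occ <- sort(pr$occasion[pr$tag_id == id])
      last_ok <- if (!is.null(obs)) {
        i <- match(id, obs$tag_id)
        if (is.na(i)) grid$f else obs$last_occ[i]
      } else grid$f
      occ <- occ[occ < last_ok] # occasion j with j+1 inside the window
      stays <- stays + sum((occ + 1L) %in% occ)
      leaves <- leaves + sum(!(occ + 1L) %in% occ)
    }
  }
  if (leaves == 0L) {
    if (!is.null(fallback)) {
      warning("no departures observed at ", entrance,
              "; using fallback q = ", fallback)
      return(fallback)
    }
    stop("zero denominator estimating q at ", entrance,
         ": no departures observed; supply a fallback value")
  }
  stays / leaves
}

#' Derived stay pseudo-counts
#'
#' `drr = q_r * (d4 + d8)` per entrance, class and season; kept fractional.
#' Attaches `q` and `drr` to the counts object.
#'
#' @param counts output of [tabulate_counts()].
#' @param q named numeric vector of stay/leave ratios, names
#'   `hinchinbrook`, `strait`, `passages` (a scalar is recycled).
#' @return The counts object with `drr` and `q` filled in.
#' @export
#' @examples
#' # q = 0.5, d4 = 3, d8 = 5 gives drr = 4
stay_pseudocount <- function(counts, q) {
  ents <- names(ENTRANCE_STATES)
  if (length(q) == 1L && is.null(names(q))) q <- setNames(rep(q, 3), ents)
  if (!all(ents %in% names(q))) stop("q must be named by entrance")
  if (any(q < 0)) stop("q must be nonnegative")
  drr <- counts$d4
  for (r in seq_along(ents))
    drr[r, , ] <- q[[ents[r]]] * (counts$d4[r, , ] + counts$d8[r, , ])
  counts$drr <- drr
  counts$q <- q[ents]
  counts
}

#' Write directional counts to JSON
#' @param counts a completed counts object (after [stay_pseudocount()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  ents <- names(ENTRANCE_STATES)
  nested <- list()
  for (r in seq_along(ents)) {
    cl <- list()
    for (y in seq_len(counts$n_class)) {
      se <- list()
      for (k in seq_len(counts$n_season))
        se[[as.character(k)]] <- list(d4 = counts$d4[r, y, k],
                                      d8 = counts$d8[r, y, k],
                                      drr = counts$drr[r, y, k])
      cl[[paste0("y", y - 1L)]] <- se
    }
    nested[[ents[r]]] <- cl
  }
  jsonlite::write_json(list(counts = nested, q = as.list(counts$q)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
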