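# ---- raw input tables: detections, receivers, deployments -------------------

# Parse ISO-8601 timestamps to POSIXct, normalized to UTC. Accepts a trailing
# "Z", a numeric offset (+hh:mm / +hhmm), a "T" or space separator, and bare
# dates. Returns NA for unparseable entries.
parse_iso8601 <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.POSIXct(NA), length(x))
  x2 <- sub("T", " ", x, fixed = TRUE)
  zulu <- grepl("Z$", x2)
  x2[zulu] <- sub("Z$", "", x2[zulu])
  has_off <- grepl("[+-][0-9]{2}:?[0-9]{2}$", x2)
  if (any(has_off)) {
    xo <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x2[has_off])
    out[has_off] <- as.POSIXct(xo, tz = "UTC", format = "%Y-%m-%d %H:%M:%S%z")
  }
  plain <- !has_off
  if (any(plain)) {
    p <- x2[plain]
    v <- as.POSIXct(p, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    bare <- is.na(v) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", p)
    v[bare] <- as.POSIXct(p[bare], tz = "UTC", format = "%Y-%m-%d")
    out[plain] <- v
  }
  attr(out, "tzone") <- "UTC"
  out
}

format_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "))
}

#' Read a detection log
#'
#' Expects a CSV with columns `tag_id,receiver_id,timestamp` (ISO-8601).
#' Timestamps are normalized to UTC on read.
#'
#' @param path path to the CSV file.
#' @return A data frame of class `asmove_detections` with columns `tag_id`,
#'   `receiver_id`, `timestamp` (POSIXct, UTC), in file order.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("tag_id", "receiver_id", "timestamp"), "detections")
  ts <- parse_iso8601(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable timestamp(s) at line ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  as_detections(data.frame(tag_id = as.character(df$tag_id),
                           receiver_id = as.character(df$receiver_id),
                           timestamp = ts, stringsAsFactors = FALSE))
}

as_detections <- function(df) {
  class(df) <- c("asmove_detections", "data.frame")
  df
}

#' Write a detection log
#' @param detections data frame as returned by [read_detections()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- data.frame(tag_id = detections$tag_id,
                    receiver_id = detections$receiver_id,
                    timestamp = format_iso8601(detections$timestamp))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_receivers <- function(df) {
  if (anyDuplicated(df$receiver_id))
    stop("duplicate receiver_id: ",
         paste(unique(df$receiver_id[duplicated(df$receiver_id)]),
               collapse = ", "))
  if (!all(df$role %in% c("spawn", "interior", "entrance")))
    stop("receiver role must be one of spawn, interior, entrance")
  if (!all(df$line %in% c("inner", "outer", "none")))
    stop("receiver line must be one of inner, outer, none")
  ent <- df$role == "entrance"
  if (any(ent & (is.na(df$entrance_id) | df$entrance_id == "")))
    stop("entrance receiver(s) without entrance_id: ",
         paste(df$receiver_id[ent & (is.na(df$entrance_id) |
                                       df$entrance_id == "")], collapse = ", "))
  if (any(ent & !df$line %in% c("inner", "outer")))
    stop("entrance receiver(s) without an inner/outer line: ",
         paste(df$receiver_id[ent & !df$line %in% c("inner", "outer")],
               collapse = ", "))
  if (any(!ent & df$line != "none"))
    stop("non-entrance receiver(s) with a line assignment: ",
         paste(df$receiver_id[!ent & df$line != "none"], collapse = ", "))
  if (any(ent & !df$entrance_id %in% names(ENTRANCE_STATES)))
    stop("entrance_id must be one of ",
         paste(names(ENTRANCE_STATES), collapse = ", "))
  df
}

#' Read a receiver registry
#'
#' Expects a CSV with columns
#' `receiver_id,array_name,role,entrance_id,line,has_complement`. Roles are
#' `spawn`, `interior` or `entrance`; entrance receivers must carry an
#' `entrance_id` (`hinchinbrook`, `strait`, `passages`) and a `line`
#' (`inner`/`outer`); all other receivers have `line = none`.
#' `has_complement = FALSE` marks inner-line receivers that lack a
#' complementary outer-line receiver, at which passage direction cannot be
#' assigned.
#'
#' @param path path to the CSV file.
#' @return A data frame of class `asmove_receivers`, one row per receiver.
#' @export
read_receivers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  require_columns(df, c("receiver_id", "array_name", "role", "entrance_id",
                        "line", "has_complement"), "receivers")
  df$receiver_id <- as.character(df$receiver_id)
  df$line[is.na(df$line)] <- "none"
  df$has_complement <- as.logical(df$has_complement)
  df$has_complement[is.na(df$has_complement)] <- TRUE
  df <- validate_receivers(df)
  class(df) <- c("asmove_receivers", "data.frame")
  df
}

#' Write a receiver registry
#' @param receivers data frame as returned by [read_receivers()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_receivers <- function(receivers, path) {
  out <- as.data.frame(receivers)[, c("receiver_id", "array_name", "role",
                                      "entrance_id", "line", "has_complement")]
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a tag deployment table
#'
#' Expects a CSV with columns
#' `tag_id,release_time,transmitter_life_days,weight_g,length_mm,sex,tag_weight_g`.
#' Derives the body-condition index `condition = weight_g / length_mm^3`
#' (g mm^-3) and `tag_burden = tag_weight_g / weight_g`.
#'
#' @param path path to the CSV file.
#' @return A data frame of class `asmove_deployments` with the derived
#'   covariates appended.
#' @export
read_deployments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("tag_id", "release_time", "transmitter_life_days",
                        "weight_g", "length_mm", "sex", "tag_weight_g"),
                  "deployments")
  ts <- parse_iso8601(df$release_time)
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable release_time at line ",
         paste(bad + 1L, collapse = ", "))
  bad <- which(!(df$weight_g > 0) | !(df$length_mm > 0) |
                 df$tag_weight_g < 0)
  if (length(bad))
    stop("nonpositive weight/length or negative tag weight at line ",
         paste(bad + 1L, collapse = ", "))
  out <- data.frame(tag_id = as.character(df$tag_id), release_time = ts,
                    transmitter_life_days = as.numeric(df$transmitter_life_days),
                    weight_g = df$weight_g, length_mm = df$length_mm,
                    sex = as.character(df$sex), tag_weight_g = df$tag_weight_g,
                    stringsAsFactors = FALSE)
  as_deployments(out)
}

as_deployments <- function(df) {
  df$condition <- df$weight_g / df$length_mm^3
  df$tag_burden <- df$tag_weight_g / df$weight_g
  class(df) <- c("asmove_deployments", "data.frame")
  df
}

#' Write a tag deployment table
#' @param deployments data frame as returned by [read_deployments()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_deployments <- function(deployments, path) {
  out <- data.frame(tag_id = deployments$tag_id,
                    release_time = format_iso8601(deployments$release_time),
                    transmitter_life_days = deployments$transmitter_life_days,
                    weight_g = deployments$weight_g,
                    length_mm = deployments$length_mm,
                    sex = deployments$sex,
                    tag_weight_g = deployments$tag_weight_g)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Releases per calendar year
#' @param deployments a deployment table.
#' @return Named integer vector of release counts by year.
#' @export
release_cohorts <- function(deployments) {
  yr <- format(deployments$release_time, "%Y", tz = "UTC")
  table_out <- table(yr)
  setNames(as.integer(table_out), names(table_out))
}

#' Median-split covariate classing
#'
#' Splits the tagged fish into two classes at the median of the chosen
#' covariate: `y = 0` for fish at or below the median, `y = 1` above it.
#' `sex` is classed by its own two levels (F = 0, M = 1); `variable = "none"`
#' puts every fish in class 0, giving the unconstrained model.
#'
#' @param deployments a deployment table.
#' @param variable one of `"length"`, `"weight"`, `"condition"`, `"sex"`,
#'   `"tag_burden"`, `"none"`.
#' @return An object of class `asmove_classing`: list with `variable`,
#'   `breakpoint`, per-fish indicator `y` (named by tag), `n_class`.
#' @export
#' @examples
#' d <- simulate_covariates(simulation_scenario(n_fish = 20))
#' covariate_classing(d, "weight")
covariate_classing <- function(deployments,
                               variable = c("none", "length", "weight",
                                            "condition", "sex", "tag_burden")) {
  variable <- match.arg(variable)
  ids <- deployments$tag_id
  if (variable == "none") {
    y <- setNames(rep(0L, length(ids)), ids)
    bp <- NA_real_
  } else if (variable == "sex") {
    sx <- toupper(substr(deployments$sex, 1, 1))
    if (any(!sx %in% c("F", "M")))
      stop("sex classing requires every fish sexed F or M")
    y <- setNames(as.integer(sx == "M"), ids)
    bp <- NA_real_
  } else {
    col <- switch(variable, length = "length_mm", weight = "weight_g",
                  condition = "condition", tag_burden = "tag_burden")
    v <- deployments[[col]]
    bp <- median(v)
    y <- setNames(as.integer(v > bp), ids)
  }
  structure(list(variable = variable, breakpoint = bp, y = y,
                 n_class = if (variable == "none") 1L else 2L),
            class = "asmove_classing")
}
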