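# shared fixtures and independent oracles

UTC <- function(x) as.POSIXct(x, tz = "UTC")

# a short toy grid: weekly occasions, two seasons
toy_grid <- function(weeks = 6, seasons = 1) {
  start <- "2017-04-01"
  end <- format(UTC(start) + (weeks * 7 - 1) * 86400, "%Y-%m-%d")
  ss <- if (seasons == 2)
    format(UTC(start) + floor(weeks / 2) * 7 * 86400, "%Y-%m-%d")
  else character(0)
  build_grid(start, end, season_starts = ss)
}

# hand-build an observation object from a list of code vectors; each fish's
# codes start at occasion rel + 1
toy_obs <- function(codes, grid, rel = NULL) {
  n <- length(codes)
  if (is.null(rel)) rel <- rep(1L, n)
  X <- matrix(0L, n, grid$f, dimnames = list(paste0("T", seq_len(n)), NULL))
  last <- integer(n)
  for (i in seq_len(n)) {
    L <- length(codes[[i]])
    stopifnot(rel[i] + L <= grid$f)
    if (L) X[i, rel[i] + seq_len(L)] <- as.integer(codes[[i]])
    last[i] <- rel[i] + L
  }
  structure(list(X = X, release_occ = rel, last_occ = last,
                 tag_id = rownames(X), grid = grid),
            class = "asmove_obs")
}

# all latent paths consistent with one fish's codes, with probabilities
# (independent enumeration oracle; no forward recursion)
enum_fish <- function(codes, rel, grid, params, y = 1L) {
  L <- length(codes)
  sets <- lapply(codes, feasible_states)
  paths <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE)
  paths <- as.matrix(paths[, rev(seq_len(L)), drop = FALSE])
  Tms <- lapply(seq_len(grid$n_season), function(k)
    build_transition(params, y, k))
  probs <- apply(paths, 1, function(z) {
    zfull <- c(2L, z)
    p <- 1
    for (t in seq_len(L)) {
      k <- grid$season_of_occ[rel + t - 1L]
      p <- p * Tms[[k]][zfull[t], zfull[t + 1L]]
    }
    p
  })
  list(paths = paths, probs = probs)
}

# brute-force marginal log-likelihood by exhaustive path enumeration
oracle_loglik <- function(obs, params, classing = NULL) {
  cls <- if (is.null(classing)) rep(1L, length(obs$tag_id)) else
    as.integer(classing$y[obs$tag_id]) + 1L
  ll <- 0
  for (i in seq_along(obs$tag_id)) {
    jj <- (obs$release_occ[i] + 1L):obs$last_occ[i]
    codes <- obs$X[i, jj]
    en <- enum_fish(codes, obs$release_occ[i], obs$grid, params, cls[i])
    ll <- ll + log(sum(en$probs))
  }
  ll
}

# independent log Dirichlet density (written separately from the package)
ref_ldirichlet <- function(x, a) {
  lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(x))
}

# a small receiver registry: one entrance with paired lines plus an unpaired
# inner receiver, and a spawn array
toy_registry <- function() {
  df <- data.frame(
    receiver_id = c("S1", "S2", "I1", "O1", "I2", "O2", "NC1"),
    array_name = c("spawn", "spawn", rep("hin", 5)),
    role = c("spawn", "spawn", rep("entrance", 5)),
    entrance_id = c(NA, NA, rep("hinchinbrook", 5)),
    line = c("none", "none", "inner", "outer", "inner", "outer", "inner"),
    has_complement = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  class(df) <- c("asmove_receivers", "data.frame")
  df
}

make_detections <- function(tag, rid, times) {
  d <- data.frame(tag_id = tag, receiver_id = rid, timestamp = times,
                  stringsAsFactors = FALSE)
  class(d) <- c("asmove_detections", "data.frame")
  d
}

# deterministic single-class parameters on a given grid size for toy tests
flat_params <- function(n_class = 1L, n_season = 1L) {
  draw_prior_params(build_priors(n_class = n_class, n_season = n_season))
}

# an empty directional-count object on the default grid
make_counts <- function(n_class = 1L, n_season = 4L) {
  g <- build_grid("2017-04-01", "2019-03-31")
  dep <- as_deployments_for_test(c(80, 140))
  cl <- covariate_classing(dep, if (n_class == 2L) "weight" else "none")
  p <- data.frame(tag_id = character(), entrance = character(),
                  entry_time = UTC(character()), exit_time = UTC(character()),
                  season = integer(), direction = character())
  tabulate_counts(p, cl, g)
}

# quick-run pipeline config pointing at a simulated dataset directory
default_asmove_config_for_test <- function(dir) {
  cfg <- read_run_config(NULL)
  cfg$detections <- file.path(dir, "detections.csv")
  cfg$receivers <- file.path(dir, "receivers.csv")
  cfg$deployments <- file.path(dir, "deployments.csv")
  cfg$output_dir <- dir
  cfg$covariate <- "weight"
  cfg$chains <- 2L
  cfg$iterations <- 100L
  cfg$burnin <- 20L
  cfg$thin <- 4L
  cfg$q_fallback <- 0.5
  cfg
}

# minimal deployment table for classing tests
as_deployments_for_test <- function(weight, sex = rep("F", length(weight)),
                                    length_mm = rep(200, length(weight)),
                                    tag_weight = rep(3.6, length(weight))) {
  df <- data.frame(tag_id = paste0("T", seq_along(weight)),
                   release_time = UTC("2017-04-03"),
                   transmitter_life_days = 759, weight_g = weight,
                   length_mm = length_mm, sex = sex,
                   tag_weight_g = tag_weight, stringsAsFactors = FALSE)
  df$condition <- df$weight_g / df$length_mm^3
  df$tag_burden <- df$tag_weight_g / df$weight_g
  class(df) <- c("asmove_deployments", "data.frame")
  df
}
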