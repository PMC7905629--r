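# ---- model parameter container ----------------------------------------------

#' Construct an Arnason-Schwarz parameter set
#'
#' Movement simplexes `psi` and survival probabilities `S` per covariate class
#' and season. Survival is free only in the Sound-away state (4) and the Gulf
#' (8); fish within reception range of an array are assumed not to expire
#' there, so survival is fixed at 1 for states 2, 3, 5, 6, 7. The transition
#' probability factors as phi = S * psi, with the remaining mass 1 - S going
#' to the absorbing expired state.
#'
#' @param psi named list over origins `"2".."8"`; each element an array of
#'   dimension `c(n_class, n_season, n_dest)` whose last margin follows the
#'   destination order of [DEST_SETS] for that origin, each simplex summing
#'   to 1.
#' @param S numeric array `c(n_class, n_season, 2)`, survival for origins 4
#'   and 8 (third margin named `"4"`, `"8"`), values in (0, 1].
#' @return An object of class `asmove_params`.
#' @export
asmove_params <- function(psi, S) {
  if (!setequal(names(psi), names(DEST_SETS)))
    stop("psi must have one block per origin 2..8")
  dims <- dim(psi[["2"]])
  n_class <- dims[1]; n_season <- dims[2]
  for (r in names(DEST_SETS)) {
    b <- psi[[r]]
    nd <- length(DEST_SETS[[r]])
    if (!identical(dim(b)[1:2], c(n_class, n_season)) || dim(b)[3] != nd)
      stop("psi block for origin ", r, " has wrong dimensions")
    if (any(b < 0)) stop("negative movement probability in origin ", r)
    sums <- apply(b, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-8))
      stop("psi block for origin ", r, " is off the simplex")
  }
  if (!identical(dim(S), c(n_class, n_season, 2L)))
    stop("S must have dimension c(n_class, n_season, 2)")
  if (any(S <= 0 | S > 1)) stop("survival probabilities must lie in (0, 1]")
  dimnames(S)[[3]] <- c("4", "8")
  structure(list(n_class = n_class, n_season = n_season, psi = psi, S = S),
            class = "asmove_params")
}

#' Build the 8 x 8 seasonal transition matrix
#'
#' Row r holds phi^{rs} = S^r psi^{rs} for one covariate class and season;
#' column 1 receives the mortality mass 1 - S^r for origins 4 and 8 and the
#' expired state is absorbing. Rows are exactly stochastic.
#'
#' @param params an [asmove_params] object.
#' @param y class index (1-based).
#' @param k season index (1-based).
#' @return An 8 x 8 row-stochastic matrix.
#' @export
#' @examples
#' p <- draw_prior_params(build_priors(n_class = 1, n_season = 1))
#' rowSums(build_transition(p, 1, 1))
build_transition <- function(params, y = 1L, k = 1L) {
  stopifnot(inherits(params, "asmove_params"))
  if (y < 1 || y > params$n_class) stop("class index out of range")
  if (k < 1 || k > params$n_season) stop("season index out of range")
  Tm <- matrix(0, 8, 8, dimnames = list(STATE_NAMES, STATE_NAMES))
  Tm[1, 1] <- 1
  for (r in names(DEST_SETS)) {
    ri <- as.integer(r)
    psi <- params$psi[[r]][y, k, ]
    Sr <- if (ri %in% MORTAL_STATES) params$S[y, k, as.character(ri)] else 1
    Tm[ri, DEST_SETS[[r]]] <- Sr * psi
    if (ri %in% MORTAL_STATES) Tm[ri, 1] <- 1 - Sr
  }
  Tm
}

# stack transition matrices into the (8, 8, n_class, n_season) array the
# compiled routines consume
transition_array <- function(params) {
  A <- array(0, dim = c(8, 8, params$n_class, params$n_season))
  for (y in seq_len(params$n_class))
    for (k in seq_len(params$n_season))
      A[, , y, k] <- build_transition(params, y, k)
  A
}

# flatten parameters into a named vector; the inverse layout drives draw
# storage in the sampler
param_names <- function(n_class, n_season) {
  nm <- character(0)
  for (r in names(DEST_SETS))
    for (s in DEST_SETS[[r]])
      for (y in seq_len(n_class) - 1L)
        for (k in seq_len(n_season))
          nm <- c(nm, sprintf("psi[%s>%d|%d,%d]", r, s, y, k))
  for (r in MORTAL_STATES)
    for (y in seq_len(n_class) - 1L)
      for (k in seq_len(n_season))
        nm <- c(nm, sprintf("S[%d|%d,%d]", r, y, k))
  nm
}

params_to_vector <- function(params) {
  v <- numeric(0)
  for (r in names(DEST_SETS)) {
    b <- params$psi[[r]]
    for (d in seq_along(DEST_SETS[[r]]))
      for (y in seq_len(params$n_class))
        for (k in seq_len(params$n_season))
          v <- c(v, b[y, k, d])
  }
  for (r in as.character(MORTAL_STATES))
    for (y in seq_len(params$n_class))
      for (k in seq_len(params$n_season))
        v <- c(v, params$S[y, k, r])
  setNames(v, param_names(params$n_class, params$n_season))
}

vector_to_params <- function(v, n_class, n_season, renormalize = FALSE) {
  psi <- list(); i <- 0L
  for (r in names(DEST_SETS)) {
    nd <- length(DEST_SETS[[r]])
    b <- array(NA_real_, dim = c(n_class, n_season, nd))
    for (d in seq_len(nd))
      for (y in seq_len(n_class))
        for (k in seq_len(n_season)) {
          i <- i + 1L; b[y, k, d] <- v[i]
        }
    if (renormalize) # e.g. elementwise medians are not exactly on the simplex
      for (y in seq_len(n_class))
        for (k in seq_len(n_season))
          b[y, k, ] <- b[y, k, ] / sum(b[y, k, ])
    psi[[r]] <- b
  }
  S <- array(NA_real_, dim = c(n_class, n_season, 2L),
             dimnames = list(NULL, NULL, c("4", "8")))
  for (r in c("4", "8"))
    for (y in seq_len(n_class))
      for (k in seq_len(n_season)) {
        i <- i + 1L; S[y, k, r] <- v[i]
      }
  asmove_params(psi, S)
}
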