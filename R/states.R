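#' @useDynLib asmove, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rbeta rgamma rbinom runif rnorm setNames
#' @importFrom utils read.csv write.csv head
NULL

# ---- state and observation spaces -------------------------------------------
#
# States:       1 expired, 2 spawning-grounds array, 3 interior array,
#               4 Sound away from receivers, 5 Hinchinbrook, 6 Strait,
#               7 Passages, 8 Gulf of Alaska.
# Observations: 1 no detection, 2 spawn, 3 interior, 4 hinchinbrook,
#               5 strait, 6 passages.

STATE_NAMES <- c("expired", "spawn", "interior", "sound",
                 "hinchinbrook", "strait", "passages", "gulf")

ENTRANCE_STATES <- c(hinchinbrook = 5L, strait = 6L, passages = 7L)

# movement destinations per origin (the support of each psi simplex);
# mortality (destination 1) is additional for origins 4 and 8
DEST_SETS <- list(
  `2` = c(2L, 4L),
  `3` = c(3L, 4L),
  `4` = c(2L, 3L, 4L, 5L, 6L, 7L),
  `5` = c(4L, 5L, 8L),
  `6` = c(4L, 6L, 8L),
  `7` = c(4L, 7L, 8L),
  `8` = c(5L, 6L, 7L, 8L)
)

MORTAL_STATES <- c(4L, 8L)

# deterministic emission: state -> observation code
EMISSION_MAP <- c(1L, 2L, 3L, 1L, 4L, 5L, 6L, 1L)

#' States compatible with an observation code
#'
#' The emission process is deterministic: a fish at an array is always
#' detected there, and an undetected fish is either expired, in the Sound
#' away from receivers, or in the Gulf.
#'
#' @param x observation code in 1..6.
#' @return Integer vector of compatible states.
#' @export
#' @examples
#' feasible_states(1) # c(1, 4, 8)
feasible_states <- function(x) {
  if (length(x) != 1L || is.na(x) || !x %in% 1:6)
    stop("observation code must be a single integer in 1..6")
  which(EMISSION_MAP == as.integer(x))
}

#' The fixed 6 x 8 emission matrix
#'
#' Entry (t, r) is P(X = t | Z = r); every state column has exactly one 1.
#'
#' @return A 6 x 8 zero/one matrix.
#' @export
emission_matrix <- function() {
  E <- matrix(0, 6, 8, dimnames = list(paste0("obs", 1:6), STATE_NAMES))
  for (r in 1:8) E[EMISSION_MAP[r], r] <- 1
  E
}

# 8 x 8 logical matrix of allowed one-step transitions (phi support)
allowed_transitions <- function() {
  A <- matrix(FALSE, 8, 8, dimnames = list(STATE_NAMES, STATE_NAMES))
  A[1, 1] <- TRUE
  for (r in names(DEST_SETS)) A[as.integer(r), DEST_SETS[[r]]] <- TRUE
  A[MORTAL_STATES, 1] <- TRUE
  A
}
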