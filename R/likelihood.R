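# ---- marginal likelihood (forward algorithm) and covariate contrasts --------

# class index (1-based) per fish in an observation object
class_index <- function(obs, classing) {
  if (is.null(classing)) return(rep(1L, length(obs$tag_id)))
  y <- classing$y[obs$tag_id]
  if (anyNA(y)) stop("fish missing from classing: ",
                     paste(obs$tag_id[is.na(y)], collapse = ", "))
  as.integer(y) + 1L
}

#' Marginal log-likelihood of the observation histories
#'
#' Sums, over fish, the log probability of each weekly observation sequence
#' with the latent states marginalized by the forward algorithm. Every fish
#' starts in the spawning-grounds state at its release occasion; emission is
#' deterministic, so each forward step restricts support to the states
#' compatible with the observation code. The recursion is renormalized at
#' every step, so underflow cannot occur.
#'
#' @param obs an observation object ([build_observation_matrix()]).
#' @param params an [asmove_params] object.
#' @param classing optional [covariate_classing()]; omitted means one class.
#' @param on_impossible `"error"` (default) to stop when a fish's sequence
#'   has probability zero under `params`, or `"neg_inf"` to return `-Inf`
#'   with a diagnostic attribute naming the fish.
#' @return Scalar log-likelihood (0 for an empty fish set).
#' @export
log_likelihood <- function(obs, params, classing = NULL,
                           on_impossible = c("error", "neg_inf")) {
  on_impossible <- match.arg(on_impossible)
  stopifnot(inherits(obs, "asmove_obs"), inherits(params, "asmove_params"))
  if (!nrow(obs$X)) return(0)
  cls <- class_index(obs, classing)
  if (max(cls) > params$n_class) stop("classing has more classes than params")
  ll <- cpp_forward_loglik(obs$X, obs$release_occ, obs$last_occ, cls,
                           obs$grid$season_of_occ, transition_array(params),
                           params$n_class, params$n_season)
  bad <- !is.finite(ll)
  if (any(bad)) {
    if (on_impossible == "error")
      stop("observation sequence has probability zero for fish ",
           paste(obs$tag_id[bad], collapse = ", "))
    out <- -Inf
    attr(out, "impossible_fish") <- obs$tag_id[bad]
    return(out)
  }
  sum(ll)
}

#' Covariate-effect contrasts from a two-class fit
#'
#' For every movement component and survival probability, computes per draw
#' the logit-scale contrast `beta1 = logit(p[y=1]) - logit(p[y=0])`, the
#' posterior analogue of the slope in `logit(p) = beta0 + beta1 * y`. A
#' component is flagged significant when the equal-tailed 90% interval
#' excludes 0.
#'
#' @param fit an [asmove()] fit with two classes.
#' @param prob interval mass (default 0.9).
#' @return Data frame with one row per (component, season): `parameter`,
#'   `median`, `lower`, `upper`, `significant`.
#' @export
covariate_effect <- function(fit, prob = 0.9) {
  stopifnot(inherits(fit, "asmove_fit"))
  if (fit$n_class < 2L)
    stop("covariate contrasts require a two-class (constrained) fit")
  draws <- do.call(rbind, fit$draws)
  nm <- colnames(draws)
  base <- grep("\\|0,", nm, value = TRUE)
  base <- setdiff(base, "deviance")
  lo <- (1 - prob) / 2
  out <- lapply(base, function(p0) {
    p1 <- sub("\\|0,", "|1,", p0)
    b1 <- stats::qlogis(pmin(pmax(draws[, p1], 1e-12), 1 - 1e-12)) -
      stats::qlogis(pmin(pmax(draws[, p0], 1e-12), 1 - 1e-12))
    qs <- unname(quantile(b1, c(lo, 0.5, 1 - lo)))
    data.frame(parameter = sub("\\|0,", "|", p0), median = qs[2],
               lower = qs[1], upper = qs[3],
               significant = qs[1] > 0 | qs[3] < 0)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
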