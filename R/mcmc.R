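# ---- Gibbs sampler with FFBS data augmentation ------------------------------

#' One FFBS draw of the latent state paths
#'
#' Draws every fish's latent path from its exact conditional distribution
#' given the observations and the current parameters (forward filtering,
#' backward sampling). Paths respect the structural zeros of the transition
#' graph and the deterministic emission at every occasion.
#'
#' @param obs observation object.
#' @param params an [asmove_params] object.
#' @param classing optional classing.
#' @return Integer matrix (fish x occasion) of states 1..8, 0 outside each
#'   fish's window; the release occasion holds state 2.
#' @export
ffbs_draw <- function(obs, params, classing = NULL) {
  stopifnot(inherits(obs, "asmove_obs"))
  cls <- class_index(obs, classing)
  cpp_ffbs(obs$X, obs$release_occ, obs$last_occ, cls,
           obs$grid$season_of_occ, transition_array(params),
           params$n_class, params$n_season)
}

# Conjugate posterior hyperparameters given complete-data transition counts.
# counts: (8, 8, n_class, n_season) array. Survivor transitions from origins
# 4/8 update both the Beta (survival) and the Dirichlet (movement among
# survivors); deaths (destination 1) update only the Beta.
posterior_hyper <- function(counts, priors) {
  post <- priors
  for (r in names(DEST_SETS)) {
    ri <- as.integer(r)
    for (y in seq_len(priors$n_class))
      for (k in seq_len(priors$n_season))
        post$alpha[[r]][y, k, ] <- priors$alpha[[r]][y, k, ] +
          counts[ri, DEST_SETS[[r]], y, k]
  }
  for (r in c("4", "8")) {
    ri <- as.integer(r)
    for (y in seq_len(priors$n_class))
      for (k in seq_len(priors$n_season)) {
        deaths <- counts[ri, 1, y, k]
        survivors <- sum(counts[ri, DEST_SETS[[r]], y, k])
        post$surv$a[y, k, r] <- priors$surv$a[y, k, r] + survivors
        post$surv$b[y, k, r] <- priors$surv$b[y, k, r] + deaths
      }
  }
  post
}

#' Conjugate parameter update given complete latent paths
#'
#' With complete paths the likelihood factors into independent multinomial
#' blocks, so each movement simplex is drawn from Dirichlet(alpha + counts)
#' and each survival probability from Beta(a + survivors, b + deaths).
#' Blocks with no transitions fall back to their prior.
#'
#' @param counts transition-count array `(8, 8, n_class, n_season)` as
#'   returned by [count_transitions()].
#' @param priors an [build_priors()] object.
#' @return A draw of [asmove_params]; the conjugate posterior
#'   hyperparameters are attached as attribute `"posterior"`.
#' @export
gibbs_update <- function(counts, priors) {
  post <- posterior_hyper(counts, priors)
  draw <- draw_prior_params(post)
  attr(draw, "posterior") <- post
  draw
}

#' Complete-data transition counts from latent paths
#' @param paths integer path matrix from [ffbs_draw()] (or simulated truth).
#' @param obs the matching observation object.
#' @param classing optional classing.
#' @param n_class,n_season parameter dimensions.
#' @return Integer array `(8, 8, n_class, n_season)`.
#' @export
count_transitions <- function(paths, obs, classing = NULL,
                              n_class = if (is.null(classing)) 1L else
                                classing$n_class,
                              n_season = obs$grid$n_season) {
  cls <- class_index(obs, classing)
  cpp_count_transitions(paths, obs$release_occ, obs$last_occ, cls,
                        obs$grid$season_of_occ, n_class, n_season)
}

#' Fit the directional Arnason-Schwarz model
#'
#' Posterior inference for seasonal movement and survival probabilities by
#' Gibbs sampling: each sweep alternates an exact FFBS draw of every latent
#' path with conjugate Dirichlet/Beta parameter updates. Chains are
#' independently seeded from `seed`; recorded draws are post burn-in and
#' thinned, and each records the marginal deviance -2 log p(x | theta).
#'
#' @param obs observation object ([build_observation_matrix()] or
#'   [simulate_paths()]).
#' @param priors joint prior ([build_priors()]); its class/season dimensions
#'   set the parameter structure.
#' @param classing optional [covariate_classing()] (two-class constrained
#'   model); omit for the unconstrained model.
#' @param chains number of chains (default 4).
#' @param iterations Gibbs sweeps per chain (default 200000).
#' @param burnin sweeps discarded per chain (default 10000).
#' @param thin thinning interval (default 25).
#' @param seed integer root seed; per-chain streams are spawned from it.
#' @param init optional list of per-chain initial [asmove_params]; default
#'   draws from the prior.
#' @return An object of class `asmove_fit` with elements `draws` (list per
#'   chain of draw x parameter matrices, last column `deviance`), `priors`,
#'   `obs`, `classing`, `config`.
#' @export
#' @examples
#' \donttest{
#' sc <- simulation_scenario(n_fish = 40)
#' sim <- simulate_dataset(sc, seed = 1)
#' fit <- asmove(sim$obs, build_priors(n_class = 1, n_season = 4),
#'               chains = 2, iterations = 300, burnin = 100, thin = 5,
#'               seed = 1)
#' summary(fit)
#' }
asmove <- function(obs, priors, classing = NULL, chains = 4L,
                   iterations = 200000L, burnin = 10000L, thin = 25L,
                   seed = 1L, init = NULL) {
  stopifnot(inherits(obs, "asmove_obs"), inherits(priors, "asmove_priors"))
  if (burnin >= iterations) stop("burn-in must be shorter than the run")
  if (thin < 1L) stop("thinning interval must be >= 1")
  if (!is.null(classing) && classing$n_class != priors$n_class)
    stop("classing and priors disagree on the number of classes")
  if (obs$grid$n_season != priors$n_season)
    stop("grid and priors disagree on the number of seasons")
  n_class <- priors$n_class
  n_season <- priors$n_season
  cls <- class_index(obs, classing)
  season <- obs$grid$season_of_occ
  nm <- c(param_names(n_class, n_season), "deviance")
  n_rec <- floor((iterations - burnin) / thin)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  draws <- vector("list", chains)
  have_fish <- nrow(obs$X) > 0L
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    params <- if (!is.null(init)) init[[ch]] else draw_prior_params(priors)
    rec <- matrix(NA_real_, n_rec, length(nm), dimnames = list(NULL, nm))
    r_i <- 0L
    for (it in seq_len(iterations)) {
      if (have_fish) {
        tr <- transition_array(params)
        paths <- cpp_ffbs(obs$X, obs$release_occ, obs$last_occ, cls, season,
                          tr, n_class, n_season)
        counts <- cpp_count_transitions(paths, obs$release_occ, obs$last_occ,
                                        cls, season, n_class, n_season)
      } else {
        counts <- array(0L, dim = c(8, 8, n_class, n_season))
      }
      params <- gibbs_update(counts, priors)
      if (it > burnin && (it - burnin) %% thin == 0L) {
        r_i <- r_i + 1L
        dev <- if (have_fish)
          -2 * sum(cpp_forward_loglik(obs$X, obs$release_occ, obs$last_occ,
                                      cls, season, transition_array(params),
                                      n_class, n_season))
        else 0
        rec[r_i, ] <- c(params_to_vector(params), dev)
      }
    }
    draws[[ch]] <- rec[seq_len(r_i), , drop = FALSE]
  }
  structure(list(draws = draws, priors = priors, obs = obs,
                 classing = classing, n_class = n_class,
                 n_season = n_season,
                 config = list(chains = chains, iterations = iterations,
                               burnin = burnin, thin = thin, seed = seed,
                               chain_seeds = chain_seeds,
                               rng_kind = RNGkind()[1])),
            class = "asmove_fit")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non rank-normalized) PSRF: with m chains of n draws, within-chain
#' variance W and between-chain variance B, the pooled variance is
#' `(n-1)/n W + B/n` and R-hat its ratio to W, square-rooted. Degenerate
#' parameters (W = 0) report 1 with a warning.
#'
#' @param fit an `asmove_fit`, or a list of draw matrices (chains).
#' @return Named vector of R-hat values per parameter.
#' @export
gelman_rubin <- function(fit) {
  draws <- if (inherits(fit, "asmove_fit")) fit$draws else fit
  if (length(draws) < 2L) stop("R-hat needs at least two chains")
  n <- min(vapply(draws, nrow, 1L))
  if (n < 10L) stop("R-hat needs at least 10 draws per chain")
  draws <- lapply(draws, function(d) d[seq_len(n), , drop = FALSE])
  m <- length(draws)
  nm <- colnames(draws[[1]])
  rhat <- setNames(rep(NA_real_, length(nm)), nm)
  warned <- FALSE
  for (p in seq_along(nm)) {
    x <- vapply(draws, function(d) d[, p], numeric(n))
    means <- colMeans(x)
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(means)
    if (!is.finite(W) || W <= 0) {
      rhat[p] <- 1
      warned <- TRUE
      next
    }
    vhat <- (n - 1) / n * W + B / n
    rhat[p] <- sqrt(vhat / W)
  }
  if (warned)
    warning("degenerate (constant) parameter(s); R-hat reported as 1")
  rhat
}

# posterior-mean parameter vector with simplex blocks renormalized
posterior_mean_params <- function(fit) {
  pooled <- do.call(rbind, fit$draws)
  mv <- colMeans(pooled[, setdiff(colnames(pooled), "deviance"),
                        drop = FALSE])
  params <- vector_to_params(mv, fit$n_class, fit$n_season)
  for (r in names(DEST_SETS)) {
    b <- params$psi[[r]]
    for (y in seq_len(fit$n_class))
      for (k in seq_len(fit$n_season))
        b[y, k, ] <- b[y, k, ] / sum(b[y, k, ])
    params$psi[[r]] <- b
  }
  params
}

#' Deviance Information Criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean of the marginal deviance
#' and `pD = Dbar - D(thetabar)`, the deviance at the posterior-mean
#' parameters (simplex blocks are averaged then renormalized).
#'
#' @param fit an `asmove_fit`.
#' @return List with `DIC`, `Dbar`, `pD`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "asmove_fit"))
  dev <- unlist(lapply(fit$draws, function(d) d[, "deviance"]))
  if (any(!is.finite(dev))) stop("non-finite deviance draws")
  dbar <- mean(dev)
  dhat <- -2 * log_likelihood(fit$obs, posterior_mean_params(fit),
                              fit$classing, on_impossible = "neg_inf")
  pd <- dbar - dhat
  list(DIC = dbar + pd, Dbar = dbar, pD = pd)
}

#' Posterior summaries
#'
#' Medians and equal-tailed 90% intervals per parameter (pooled across
#' chains), with R-hat attached when the fit has two or more chains.
#'
#' @param object an `asmove_fit`.
#' @param prob interval mass (default 0.9).
#' @param ... unused.
#' @return Data frame of class `summary.asmove_fit` with columns
#'   `parameter`, `median`, `lower`, `upper`, `rhat`.
#' @export
summary.asmove_fit <- function(object, prob = 0.9, ...) {
  pooled <- do.call(rbind, object$draws)
  lo <- (1 - prob) / 2
  qs <- t(apply(pooled, 2, quantile, probs = c(lo, 0.5, 1 - lo),
                type = 7, names = FALSE))
  rhat <- if (length(object$draws) >= 2L && nrow(object$draws[[1]]) >= 10L)
    gelman_rubin(object) else rep(NA_real_, ncol(pooled))
  out <- data.frame(parameter = colnames(pooled), median = qs[, 2],
                    lower = qs[, 1], upper = qs[, 3], rhat = unname(rhat),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prob") <- prob
  class(out) <- c("summary.asmove_fit", "data.frame")
  out
}

#' @export
print.summary.asmove_fit <- function(x, ...) {
  cat("Posterior summaries (median, ",
      format(100 * attr(x, "prob")), "% equal-tailed interval):\n", sep = "")
  print.data.frame(head(as.data.frame(x), 20), digits = 3)
  if (nrow(x) > 20) cat("... ", nrow(x) - 20, " more parameters\n", sep = "")
  invisible(x)
}

#' @export
print.asmove_fit <- function(x, ...) {
  cat("Directional Arnason-Schwarz model fit\n")
  cat("  fish:", nrow(x$obs$X), " classes:", x$n_class,
      " seasons:", x$n_season, "\n")
  cat("  chains:", x$config$chains, " draws/chain:", nrow(x$draws[[1]]),
      " (", x$config$iterations, "sweeps, burn-in", x$config$burnin,
      ", thin", x$config$thin, ")\n")
  invisible(x)
}

#' Posterior medians
#' @param object an `asmove_fit`.
#' @param ... unused.
#' @return Named vector of posterior medians (deviance excluded).
#' @export
coef.asmove_fit <- function(object, ...) {
  pooled <- do.call(rbind, object$draws)
  m <- apply(pooled, 2, median)
  m[setdiff(names(m), "deviance")]
}

#' Trace plots
#' @param x an `asmove_fit`.
#' @param parameters character vector of parameter names (default: the first
#'   four entrance movement components present).
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.asmove_fit <- function(x, parameters = NULL, ...) {
  nm <- colnames(x$draws[[1]])
  if (is.null(parameters)) {
    parameters <- grep("^psi\\[5>", nm, value = TRUE)
    parameters <- head(parameters, 4)
  }
  op <- graphics::par(mfrow = c(length(parameters), 1),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (p in parameters) {
    tr <- vapply(x$draws, function(d) d[, p],
                 numeric(nrow(x$draws[[1]])))
    graphics::matplot(tr, type = "l", lty = 1, ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Draws new latent paths and observation matrices from the posterior-median
#' parameters, on the fitted grid and release schedule.
#'
#' @param object an `asmove_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return List of length `nsim` of [simulate_paths()] results.
#' @export
simulate.asmove_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  med <- coef(object)
  params <- vector_to_params(med, object$n_class, object$n_season,
                             renormalize = TRUE)
  cls <- class_index(object$obs, object$classing)
  replicate(nsim, simulate_paths_core(params, object$obs$grid,
                                      object$obs$release_occ,
                                      object$obs$last_occ, cls,
                                      object$obs$tag_id),
            simplify = FALSE)
}

#' Write posterior draws to long-format CSV
#' @param fit an `asmove_fit`.
#' @param path output CSV path (columns chain, draw, parameter, value).
#' @return `path`, invisibly.
#' @export
write_posterior <- function(fit, path) {
  rows <- lapply(seq_along(fit$draws), function(ch) {
    d <- fit$draws[[ch]]
    data.frame(chain = ch, draw = rep(seq_len(nrow(d)), ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.numeric(d))
  })
  # parameter labels contain commas, so fields must stay quoted
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a summary (with DIC and config echo) to JSON
#' @param fit an `asmove_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(fit, path) {
  s <- summary(fit)
  obj <- list(parameters = as.data.frame(s), dic = dic(fit),
              config = fit$config[c("chains", "iterations", "burnin",
                                    "thin", "seed", "rng_kind")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
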