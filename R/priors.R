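# ---- joint prior: empirical Dirichlet at entrances, flat elsewhere ----------

#' Informative entrance-array priors from directional counts
#'
#' For entrance origin r with destination order (Sound 4, stay r, Gulf 8) the
#' movement simplex gets concentration `(d4 + 1, drr + 1, d8 + 1)` per class
#' and season: the empirical-Bayes step that feeds the assigned passage
#' directions into the model. `drr` may be fractional; the Dirichlet is
#' well-defined for any positive reals. Cells with no passages reduce to the
#' flat Dirichlet(1,1,1).
#'
#' @param counts completed counts object (after [stay_pseudocount()]).
#' @return Named list over origins `"5","6","7"` of concentration arrays
#'   `c(n_class, n_season, 3)`.
#' @export
build_entrance_priors <- function(counts) {
  if (is.null(counts$drr))
    stop("counts lack drr; run stay_pseudocount() first")
  if (any(counts$d4 < 0) || any(counts$d8 < 0) || any(counts$drr < 0))
    stop("negative directional count")
  ents <- names(ENTRANCE_STATES)
  out <- list()
  for (r in seq_along(ents)) {
    a <- array(NA_real_, dim = c(counts$n_class, counts$n_season, 3))
    a[, , 1] <- counts$d4[r, , ] + 1  # destination 4 (Sound)
    a[, , 2] <- counts$drr[r, , ] + 1 # stay at the entrance
    a[, , 3] <- counts$d8[r, , ] + 1  # destination 8 (Gulf)
    out[[as.character(ENTRANCE_STATES[[ents[r]]])]] <- a
  }
  out
}

#' Non-informative priors for the remaining blocks
#'
#' Dirichlet(2, ...) on the movement simplexes away from the entrances and
#' Beta(2, 2) on the Sound and Gulf survival probabilities, identical across
#' classes and seasons: origin 2 over (2,4), origin 3 over (3,4), origin 4
#' over (2,3,4,5,6,7), origin 8 over (5,6,7,8).
#'
#' @param n_class number of covariate classes (1 or 2).
#' @param n_season number of seasons.
#' @return List with `alpha` (per-origin concentration arrays) and `surv`
#'   (Beta `a`, `b` arrays of dimension `c(n_class, n_season, 2)`).
#' @export
build_noninformative_priors <- function(n_class = 1L, n_season = 4L) {
  alpha <- list()
  for (r in names(DEST_SETS)) {
    nd <- length(DEST_SETS[[r]])
    conc <- if (r %in% c("5", "6", "7")) 1 else 2
    alpha[[r]] <- array(conc, dim = c(n_class, n_season, nd))
  }
  surv <- list(a = array(2, dim = c(n_class, n_season, 2),
                         dimnames = list(NULL, NULL, c("4", "8"))),
               b = array(2, dim = c(n_class, n_season, 2),
                         dimnames = list(NULL, NULL, c("4", "8"))))
  list(alpha = alpha, surv = surv)
}

#' Assemble the joint prior
#'
#' Combines the non-informative blocks with, when directional counts are
#' supplied, the informative entrance-array Dirichlet priors. Without counts
#' the entrance blocks stay at the flat Dirichlet(1,1,1).
#'
#' @param counts optional completed counts object.
#' @param n_class,n_season dimensions (taken from `counts` when given).
#' @return An object of class `asmove_priors`.
#' @export
build_priors <- function(counts = NULL, n_class = 1L, n_season = 4L) {
  if (!is.null(counts)) {
    n_class <- counts$n_class
    n_season <- counts$n_season
  }
  base <- build_noninformative_priors(n_class, n_season)
  if (!is.null(counts)) {
    ent <- build_entrance_priors(counts)
    for (r in names(ent)) base$alpha[[r]] <- ent[[r]]
  }
  structure(list(n_class = n_class, n_season = n_season,
                 alpha = base$alpha, surv = base$surv),
            class = "asmove_priors")
}

#' Joint log prior density
#'
#' Sum of log Dirichlet densities over every movement block and log Beta
#' densities over the Sound/Gulf survival probabilities.
#'
#' @param params an [asmove_params] object.
#' @param priors an [build_priors()] object of matching dimensions.
#' @return Scalar log density.
#' @export
prior_density <- function(params, priors) {
  stopifnot(inherits(params, "asmove_params"), inherits(priors, "asmove_priors"))
  if (params$n_class != priors$n_class || params$n_season != priors$n_season)
    stop("params and priors dimensions differ")
  ld <- 0
  for (r in names(DEST_SETS)) {
    for (y in seq_len(params$n_class))
      for (k in seq_len(params$n_season)) {
        x <- params$psi[[r]][y, k, ]
        if (abs(sum(x) - 1) > 1e-8 || any(x < 0))
          stop("psi block off the simplex for origin ", r)
        a <- priors$alpha[[r]][y, k, ]
        ld <- ld + lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(x))
      }
  }
  for (r in c("4", "8"))
    for (y in seq_len(params$n_class))
      for (k in seq_len(params$n_season))
        ld <- ld + stats::dbeta(params$S[y, k, r], priors$surv$a[y, k, r],
                                priors$surv$b[y, k, r], log = TRUE)
  ld
}

# one Dirichlet draw via gamma variates
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[ ] <- 1e-300
  g / sum(g)
}

#' Draw a parameter set from the prior
#' @param priors an [build_priors()] object.
#' @return An [asmove_params] draw.
#' @export
draw_prior_params <- function(priors) {
  psi <- list()
  for (r in names(DEST_SETS)) {
    nd <- length(DEST_SETS[[r]])
    b <- array(NA_real_, dim = c(priors$n_class, priors$n_season, nd))
    for (y in seq_len(priors$n_class))
      for (k in seq_len(priors$n_season))
        b[y, k, ] <- rdirichlet1(priors$alpha[[r]][y, k, ])
    psi[[r]] <- b
  }
  S <- array(NA_real_, dim = c(priors$n_class, priors$n_season, 2),
             dimnames = list(NULL, NULL, c("4", "8")))
  for (r in c("4", "8"))
    for (y in seq_len(priors$n_class))
      for (k in seq_len(priors$n_season))
        S[y, k, r] <- rbeta(1, priors$surv$a[y, k, r], priors$surv$b[y, k, r])
  asmove_params(psi, S)
}

#' Serialize priors to JSON
#' @param priors an [build_priors()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_priors <- function(priors, path) {
  obj <- list(n_class = priors$n_class, n_season = priors$n_season,
              alpha = lapply(priors$alpha, function(a)
                list(dim = dim(a), values = as.numeric(a))),
              surv = list(a = as.numeric(priors$surv$a),
                          b = as.numeric(priors$surv$b)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read priors from JSON
#' @param path path written by [write_priors()].
#' @return An `asmove_priors` object.
#' @export
read_priors <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_class <- obj$n_class; n_season <- obj$n_season
  alpha <- list()
  for (r in names(DEST_SETS))
    alpha[[r]] <- array(obj$alpha[[r]]$values, dim = obj$alpha[[r]]$dim)
  surv <- list(a = array(obj$surv$a, dim = c(n_class, n_season, 2),
                         dimnames = list(NULL, NULL, c("4", "8"))),
               b = array(obj$surv$b, dim = c(n_class, n_season, 2),
                         dimnames = list(NULL, NULL, c("4", "8"))))
  structure(list(n_class = n_class, n_season = n_season, alpha = alpha,
                 surv = surv), class = "asmove_priors")
}
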