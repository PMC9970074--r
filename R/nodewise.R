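# Node-wise Bayesian multilevel regressions: each skill on the other eight,
# with physician-varying intercept and slopes. The physician-specific
# coefficients later become the directed edge weights of the skills networks.

jags_model_nodewise <- function(varying) {
  common_priors <- "
  beta[1] ~ dnorm(int_mean, int_prec)
  for (k in 2:Kp) { beta[k] ~ dnorm(slope_mean[k-1], slope_prec[k-1]) }
  sigma ~ dt(0, pow(sigma_scale, -2), 3) T(0.0001,)
  tau <- pow(sigma, -2)
"
  if (varying == "correlated") {
    paste0("model {
  for (i in 1:N) {
    mu[i] <- inprod(b[phys[i], 1:Kp], X[i, 1:Kp])
    y[i] ~ dnorm(mu[i], tau)
  }
  for (p in 1:P) { b[p, 1:Kp] ~ dmnorm(beta[1:Kp], OmegaRE[1:Kp, 1:Kp]) }
  OmegaRE[1:Kp, 1:Kp] ~ dwish(Rmat[1:Kp, 1:Kp], Kp + 1)
", common_priors, "}\n")
  } else if (varying == "independent") {
    paste0("model {
  for (i in 1:N) {
    mu[i] <- inprod(b[phys[i], 1:Kp], X[i, 1:Kp])
    y[i] ~ dnorm(mu[i], tau)
  }
  for (p in 1:P) {
    for (k in 1:Kp) { b[p, k] ~ dnorm(beta[k], re_prec[k]) }
  }
  for (k in 1:Kp) {
    re_sd[k] ~ dt(0, pow(ranef_scale, -2), 3) T(0,)
    re_prec[k] <- pow(re_sd[k], -2)
  }
", common_priors, "}\n")
  } else { # none: plain Bayesian linear regression
    paste0("model {
  for (i in 1:N) {
    mu[i] <- inprod(beta[1:Kp], X[i, 1:Kp])
    y[i] ~ dnorm(mu[i], tau)
  }
", common_priors, "}\n")
  }
}

#' Fit one node-wise Bayesian multilevel regression
#'
#' Regresses the outcome skill on all other skills with Gaussian likelihood;
#' the intercept and the eight slopes vary by physician (random effects with,
#' by default, an unstructured covariance via a Wishart prior on their
#' precision). Physician-specific coefficient draws are the sampled
#' \code{b[p, ]}, i.e. population draw + physician deviation at every retained
#' iteration. With a single physician (or \code{varying = "none"}) the
#' grouping level is dropped and physician draws equal population draws.
#'
#' @param ratings Complete rating table (post-imputation).
#' @param outcome Outcome skill index (1-9).
#' @param priors A \code{\link{prior_spec}}.
#' @param mcmc An \code{\link{mcmc_config}}; its seed determines all chains.
#' @param varying Random-effect structure: \code{"correlated"} (unstructured
#'   covariance, default), \code{"independent"} (no correlations; more stable
#'   on very small data) or \code{"none"}.
#' @param center Grand-mean-center the predictors before fitting (default
#'   FALSE: predictors enter on the raw 0--5 scale).
#' @return An object of class \code{nodewise_fit} carrying population
#'   coefficient draws (\code{$beta}), physician-specific coefficient draws
#'   (\code{$b}, draws x physician x coefficient), residual-SD draws, per-chain
#'   draws for diagnostics (\code{$chains}) and split R-hat per parameter.
#' @seealso \code{\link{fit_all_nodes}}, \code{\link{check_convergence}}
#' @export
fit_nodewise <- function(ratings, outcome, priors = prior_spec(),
                         mcmc = mcmc_config(),
                         varying = c("correlated", "independent", "none"),
                         center = FALSE) {
  varying <- match.arg(varying)
  assert_ratings(ratings, require_complete = TRUE)
  K <- n_skills_of(ratings)
  if (outcome < 1 || outcome > K) stopf("outcome must be in 1..%d", K)

  ids <- unique(ratings$physician_id)
  P <- length(ids)
  if (P == 1L) varying <- "none"
  R <- rating_matrix(ratings)
  y <- R[, outcome]
  Xp <- R[, -outcome, drop = FALSE]
  predictors <- colnames(Xp)
  centers <- rep(0, ncol(Xp))
  if (center) {
    centers <- colMeans(Xp)
    Xp <- sweep(Xp, 2, centers)
  }
  X <- cbind(1, Xp)
  Kp <- ncol(X)

  slope_mean <- rep(priors$slope_mean, length.out = Kp - 1)
  slope_sd <- rep(priors$slope_sd, length.out = Kp - 1)
  dat <- list(N = nrow(X), Kp = Kp, X = X, y = as.vector(y),
              int_mean = priors$intercept_mean,
              int_prec = priors$intercept_sd^-2,
              slope_mean = slope_mean, slope_prec = slope_sd^-2,
              sigma_scale = priors$sigma_scale)
  if (varying != "none") {
    dat$P <- P
    dat$phys <- match(ratings$physician_id, ids)
    if (varying == "correlated") dat$Rmat <- diag(priors$ranef_scale, Kp)
    if (varying == "independent") dat$ranef_scale <- priors$ranef_scale
  }
  monitor <- c("beta", "sigma", if (varying != "none") "b")

  chains <- run_jags(jags_model_nodewise(varying), dat, monitor, mcmc,
                     seed = mcmc$seed)
  draws <- stack_chains(chains)

  beta <- draws[, paste0("beta[", seq_len(Kp), "]"), drop = FALSE]
  colnames(beta) <- c("(Intercept)", predictors)
  n_draws <- nrow(beta)
  b <- array(NA_real_, dim = c(n_draws, P, Kp),
             dimnames = list(NULL, ids, c("(Intercept)", predictors)))
  if (varying == "none") {
    for (p in seq_len(P)) b[, p, ] <- beta
  } else {
    for (p in seq_len(P)) {
      b[, p, ] <- draws[, paste0("b[", p, ",", seq_len(Kp), "]"), drop = FALSE]
    }
  }

  rhat <- data.frame(
    parameter = colnames(draws),
    rhat = vapply(colnames(draws), function(pn) {
      split_rhat(sapply(chains, function(ch) ch[, pn]))
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(
    outcome = as.integer(outcome),
    outcome_name = skill_cols(K)[outcome],
    predictors = predictors,
    physician_ids = ids,
    beta = beta,
    b = b,
    sigma = draws[, "sigma"],
    chains = chains,
    rhat = rhat,
    varying = varying,
    center = center,
    centers = centers,
    priors = priors,
    mcmc = mcmc,
    n_draws = n_draws
  ), class = "nodewise_fit")
}

#' @export
print.nodewise_fit <- function(x, ...) {
  cat(sprintf("Node-wise fit: %s ~ %d other skills | %d physicians (%s random effects)\n",
              x$outcome_name, length(x$predictors), length(x$physician_ids), x$varying))
  cat(sprintf("  %d retained draws, max R-hat %.4f\n",
              x$n_draws, max(x$rhat$rhat, na.rm = TRUE)))
  print(round(colMeans(x$beta), 3))
  invisible(x)
}

#' @export
coef.nodewise_fit <- function(object, ...) colMeans(object$beta)

#' @export
summary.nodewise_fit <- function(object, level = 0.95, ...) {
  a <- (1 - level) / 2
  q <- apply(object$beta, 2, quantile, probs = c(a, 1 - a))
  out <- data.frame(
    parameter = colnames(object$beta),
    mean = colMeans(object$beta),
    sd = apply(object$beta, 2, sd),
    ci_low = q[1, ], ci_high = q[2, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
  bet <- paste0("beta[", seq_along(out$parameter), "]")
  out$rhat <- object$rhat$rhat[match(bet, object$rhat$parameter)]
  out
}

#' Posterior means of physician-specific coefficients
#'
#' @param fit A \code{nodewise_fit}.
#' @return Matrix physicians x coefficients of posterior means.
#' @export
physician_coef <- function(fit) {
  stopifnot(inherits(fit, "nodewise_fit"))
  apply(fit$b, c(2, 3), mean)
}

#' Fit all nine node-wise regressions
#'
#' Applies \code{\link{fit_nodewise}} to every skill in turn; per-node seeds
#' are derived deterministically from the master seed in \code{mcmc}.
#'
#' @inheritParams fit_nodewise
#' @param progress Print a line per node.
#' @return An object of class \code{nodewise_set}: a list of
#'   \code{nodewise_fit}s (one per outcome skill) plus shared metadata.
#' @export
fit_all_nodes <- function(ratings, priors = prior_spec(), mcmc = mcmc_config(),
                          varying = c("correlated", "independent", "none"),
                          center = FALSE, progress = FALSE) {
  varying <- match.arg(varying)
  assert_ratings(ratings, require_complete = TRUE)
  K <- n_skills_of(ratings)
  fits <- vector("list", K)
  for (j in seq_len(K)) {
    mc_j <- mcmc
    mc_j$seed <- child_seed(mcmc$seed, j)
    if (progress) message(sprintf("fitting node %d/%d", j, K))
    fits[[j]] <- fit_nodewise(ratings, outcome = j, priors = priors,
                              mcmc = mc_j, varying = varying, center = center)
  }
  names(fits) <- skill_cols(K)
  structure(list(fits = fits, n_skills = K,
                 physician_ids = fits[[1]]$physician_ids,
                 priors = priors, mcmc = mcmc, varying = fits[[1]]$varying),
            class = "nodewise_set")
}

#' @export
print.nodewise_set <- function(x, ...) {
  mx <- max(vapply(x$fits, function(f) max(f$rhat$rhat, na.rm = TRUE), numeric(1)))
  cat(sprintf("Node-wise regression set: %d skills, %d physicians, %d draws per fit\n",
              x$n_skills, length(x$physician_ids), x$fits[[1]]$n_draws))
  cat(sprintf("  random effects: %s; max R-hat across fits: %.4f\n", x$varying, mx))
  invisible(x)
}

#' @export
summary.nodewise_set <- function(object, ...) {
  do.call(rbind, lapply(object$fits, function(f) {
    s <- summary(f)
    cbind(outcome = f$outcome_name, s)
  }))
}
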