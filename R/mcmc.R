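# MCMC configuration, prior specification and convergence diagnostics.

#' MCMC sampler configuration
#'
#' Bookkeeping for the JAGS runs: \code{iterations} are post-adaptation
#' iterations per chain, of which the first \code{burn_in} are discarded and
#' the rest thinned by \code{thinning}. Retained draws are
#' \code{n_chains * (iterations - burn_in) / thinning}; the default
#' (4 chains, 10,000 iterations, 5,000 burn-in, thinning 10) retains 2,000.
#'
#' @param n_chains Number of chains (>= 2 recommended so R-hat is defined).
#' @param iterations Post-adaptation iterations per chain.
#' @param burn_in Burn-in iterations per chain (must be < iterations).
#' @param thinning Thinning interval.
#' @param n_adapt JAGS adaptation iterations (not part of \code{iterations}).
#' @param seed Master integer seed; chain and per-node seeds derive from it.
#' @param min_retained Smallest acceptable retained posterior sample size.
#' @return An object of class \code{mcmc_config}.
#' @export
#' @examples
#' mcmc_config(n_chains = 2, iterations = 2000, burn_in = 500, thinning = 1)
mcmc_config <- function(n_chains = 4L, iterations = 10000L, burn_in = 5000L,
                        thinning = 10L, n_adapt = 500L, seed = 1L,
                        min_retained = 500L) {
  if (burn_in >= iterations) stopf("burn_in must be smaller than iterations")
  if (thinning < 1L) stopf("thinning must be >= 1")
  retained <- n_chains * floor((iterations - burn_in) / thinning)
  if (retained < min_retained) {
    stopf("configuration retains only %d draws (< %d)", retained, min_retained)
  }
  structure(list(n_chains = as.integer(n_chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_adapt = as.integer(n_adapt),
                 seed = as.integer(seed %% 2147483647),
                 retained = as.integer(retained)),
            class = "mcmc_config")
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf("MCMC config: %d chains x %d iterations (burn-in %d, thinning %d) -> %d retained draws, seed %d\n",
              x$n_chains, x$iterations, x$burn_in, x$thinning, x$retained, x$seed))
  invisible(x)
}

#' Prior specification for the regression models
#'
#' Weakly informative defaults: independent Gaussian priors on slopes and
#' intercept, a half-t-type prior on the residual scale and, for the
#' multilevel models, a Wishart prior on the random-effect precision matrix.
#' \code{slope_mean}/\code{slope_sd} may be scalars or per-coefficient
#' vectors (used by the confirmatory model's informative priors).
#'
#' @param slope_mean,slope_sd Gaussian prior on regression slopes. The default
#'   sd of 2.5 covers the plausible slope range for items on a 0--5 scale.
#' @param intercept_mean,intercept_sd Gaussian prior on the intercept.
#' @param sigma_scale Scale of the half-t(3) prior on the residual SD.
#' @param ranef_scale Diagonal value of the Wishart scale matrix for the
#'   random-effect precision.
#' @param autoscale Rescale prior SDs by the response/predictor SDs (as is
#'   common for regressions whose response lives on an arbitrary scale, e.g.
#'   competence scores on 0--100). Used by the prediction models.
#' @param provenance \code{"weakly_informative_default"} or \code{"file"}.
#' @return An object of class \code{prior_spec}.
#' @export
prior_spec <- function(slope_mean = 0, slope_sd = 2.5,
                       intercept_mean = 0, intercept_sd = 10,
                       sigma_scale = 2.5, ranef_scale = 1,
                       autoscale = FALSE,
                       provenance = "weakly_informative_default") {
  if (any(slope_sd <= 0) || intercept_sd <= 0 || sigma_scale <= 0 || ranef_scale <= 0) {
    stopf("all prior scale hyperparameters must be > 0")
  }
  structure(list(slope_mean = slope_mean, slope_sd = slope_sd,
                 intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 sigma_scale = sigma_scale, ranef_scale = ranef_scale,
                 autoscale = isTRUE(autoscale), provenance = provenance),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Prior spec (%s): slopes N(%s, %s^2), intercept N(%g, %g^2), sigma ~ half-t(3, %g)%s\n",
              x$provenance,
              paste(signif(x$slope_mean, 3), collapse = "/"),
              paste(signif(x$slope_sd, 3), collapse = "/"),
              x$intercept_mean, x$intercept_sd, x$sigma_scale,
              if (x$autoscale) ", autoscaled" else ""))
  invisible(x)
}

#' Read a prior-specification file
#'
#' YAML or JSON file mapping instruments to per-coefficient Gaussian prior
#' means and SDs, as used by the confirmatory prediction model (e.g. posterior
#' summaries from a previous study supplied as informative priors). Expected
#' layout:
#' \preformatted{
#' OPTION-12:
#'   intercept: {mean: 16.0, sd: 2.0}
#'   activation_skill_6: {mean: 40.0, sd: 20.0}
#'   ...
#' }
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return Named list (per instrument) of named lists of \code{mean}/\code{sd}
#'   pairs, with attribute \code{provenance = "file"}.
#' @export
read_prior_file <- function(path) {
  if (!file.exists(path)) stopf("prior file not found: %s", path)
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (ins in names(spec)) {
    for (cf in names(spec[[ins]])) {
      pr <- spec[[ins]][[cf]]
      if (is.null(pr$mean) || is.null(pr$sd) || pr$sd <= 0) {
        stopf("prior file entry %s/%s needs a mean and a positive sd", ins, cf)
      }
    }
  }
  attr(spec, "provenance") <- "file"
  spec
}

#' Split-half potential scale reduction factor (R-hat)
#'
#' Gelman-Rubin statistic computed on split chains: each chain is halved, and
#' the classic between/within-variance ratio is evaluated over the
#' \code{2 * n_chains} half-sequences. Values near 1 indicate convergence.
#'
#' @param draws Matrix of posterior draws, iterations x chains.
#' @return The split R-hat (scalar). Degenerate (zero-variance) parameters
#'   return 1.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c) {
    cbind(draws[seq_len(half), c], draws[(n - half + 1):n, c])
  }))
  m <- ncol(splits); nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (!is.finite(W) || W == 0) {
    return(if (B == 0 || !is.finite(B)) 1 else Inf)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Check MCMC convergence of a fitted model
#'
#' Computes split R-hat for every monitored parameter of a fit produced by
#' \code{\link{fit_nodewise}} or \code{\link{fit_prediction}} and flags
#' parameters exceeding the threshold.
#'
#' @param fit A \code{nodewise_fit} or \code{prediction_fit} (anything storing
#'   a per-chain draw array under \code{$chains}).
#' @param threshold Flagging threshold (default 1.01; a common choice is 1.1
#'   for expensive models).
#' @return Data frame of class \code{sdm_convergence}: \code{parameter},
#'   \code{rhat}, \code{flagged}.
#' @export
check_convergence <- function(fit, threshold = 1.01) {
  chains <- fit$chains
  if (is.null(chains)) stopf("fit carries no per-chain draws")
  if (length(chains) < 2L) stopf("convergence check requires >= 2 chains")
  pars <- colnames(chains[[1]])
  rh <- vapply(pars, function(p) {
    split_rhat(sapply(chains, function(ch) ch[, p]))
  }, numeric(1))
  out <- data.frame(parameter = pars, rhat = unname(rh),
                    flagged = unname(rh) > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("sdm_convergence", "data.frame")
  out
}

#' @export
print.sdm_convergence <- function(x, ...) {
  thr <- attr(x, "threshold")
  nf <- sum(x$flagged, na.rm = TRUE)
  cat(sprintf("Convergence: %d parameters, max R-hat %.4f, %d flagged (> %.3f)\n",
              nrow(x), max(x$rhat, na.rm = TRUE), nf, thr))
  if (nf > 0) print.data.frame(x[x$flagged, , drop = FALSE])
  invisible(x)
}

# --- shared JAGS runner ----------------------------------------------------

# Run a JAGS model and return a list of per-chain draw matrices
# (iterations x parameters), burn-in removed and thinned per the config.
run_jags <- function(model_string, data, monitor, mcmc, seed) {
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = child_seed(seed, 100 + ch))
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = TRUE)
  if (mcmc$burn_in > 0) stats::update(jm, n.iter = mcmc$burn_in, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitor,
                              n.iter = mcmc$iterations - mcmc$burn_in,
                              thin = mcmc$thinning, progress.bar = "none")
  lapply(samp, function(ch) {
    m <- as.matrix(ch)
    m
  })
}

# stack per-chain matrices into one draws matrix
stack_chains <- function(chains) do.call(rbind, chains)
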