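# Prediction of observer-rated competence from network parameters:
# predictor assembly, Bayesian linear regression via JAGS, the confirmatory
# model with informative priors, the two-stage exploratory procedure, and
# calibration output.

jags_model_prediction <- "model {
  for (i in 1:N) {
    mu[i] <- alpha + inprod(beta[1:Kp], X[i, 1:Kp])
    y[i] ~ dnorm(mu[i], tau)
  }
  alpha ~ dnorm(int_mean, int_prec)
  for (k in 1:Kp) { beta[k] ~ dnorm(slope_mean[k], slope_prec[k]) }
  sigma ~ dt(0, pow(sigma_scale, -2), 3) T(0.0001,)
  tau <- pow(sigma, -2)
}"

jags_model_intercept_only <- "model {
  for (i in 1:N) { y[i] ~ dnorm(alpha, tau) }
  alpha ~ dnorm(int_mean, int_prec)
  sigma ~ dt(0, pow(sigma_scale, -2), 3) T(0.0001,)
  tau <- pow(sigma, -2)
}"

predictor_name <- function(skill, type) sprintf("%s_skill_%d", type, skill)

#' Assemble a physician-by-parameter predictor table
#'
#' One row per physician; columns are the selected (skill, parameter-type)
#' pairs in deterministic skill-major, type-minor order, values copied from
#' the physician networks. Observer competence scores, when supplied, are
#' attached as one response column per instrument (NA for physicians without
#' scores on that instrument).
#'
#' @param networks List of \code{\link{build_physician_network}} results.
#' @param skills Integer vector of skill indices.
#' @param types Parameter types among \code{"activation"}, \code{"instrength"},
#'   \code{"outstrength"}.
#' @param scores Optional aggregated competence scores
#'   (\code{\link{aggregate_observer}} output).
#' @return Data frame with \code{physician_id}, predictor columns and (if
#'   \code{scores} given) per-instrument response columns; attributes
#'   \code{"predictors"} and \code{"instruments"} name them.
#' @export
assemble_predictors <- function(networks, skills = 1:9,
                                types = c("activation", "instrength", "outstrength"),
                                scores = NULL) {
  types <- match.arg(types, c("activation", "instrength", "outstrength"),
                     several.ok = TRUE)
  if (!length(networks)) stopf("no networks supplied")
  ids <- vapply(networks, function(n) n$physician_id, character(1))
  out <- data.frame(physician_id = ids, stringsAsFactors = FALSE)
  pred_cols <- character(0)
  for (s in skills) {
    for (tp in types) {
      cl <- predictor_name(s, tp)
      out[[cl]] <- vapply(networks, function(n) unname(n[[tp]][s]), numeric(1))
      pred_cols <- c(pred_cols, cl)
    }
  }
  instruments <- character(0)
  if (!is.null(scores)) {
    for (ins in unique(scores$instrument)) {
      sel <- scores$instrument == ins
      out[[ins]] <- scores$score[sel][match(ids, scores$physician_id[sel])]
      instruments <- c(instruments, ins)
    }
  }
  attr(out, "predictors") <- pred_cols
  attr(out, "instruments") <- instruments
  out
}

#' Bayesian linear regression of an observer measure on network parameters
#'
#' Gaussian-likelihood linear regression sampled by MCMC. Rows with a missing
#' response are dropped for this instrument's fit only. The multiple
#' correlation R is the posterior distribution of the correlation between the
#' draw-specific linear predictor and the observed responses (floored at 0);
#' R-squared is its square, draw by draw. Reported summaries are posterior
#' medians with 95\% equal-tailed credible intervals, and a coefficient is
#' flagged significant when its interval excludes zero.
#'
#' With \code{priors$autoscale = TRUE} (recommended for responses on the
#' 0--100 competence scale) the slope prior SD for predictor k becomes
#' \code{slope_sd * sd(y) / sd(x_k)} and the intercept prior is centred on
#' \code{mean(y)} with SD \code{intercept_sd * sd(y)}.
#'
#' @param table A predictor table from \code{\link{assemble_predictors}}
#'   including a response column named after the instrument.
#' @param instrument Response column to fit.
#' @param priors A \code{\link{prior_spec}}; \code{slope_mean}/\code{slope_sd}
#'   may be per-coefficient vectors (in predictor-column order).
#' @param mcmc An \code{\link{mcmc_config}}.
#' @return An object of class \code{prediction_fit}.
#' @export
fit_prediction <- function(table, instrument,
                           priors = prior_spec(autoscale = TRUE),
                           mcmc = mcmc_config()) {
  pred_cols <- attr(table, "predictors") %||%
    setdiff(names(table), c("physician_id", instrument))
  if (!instrument %in% names(table)) {
    stopf("no response column '%s' in the predictor table", instrument)
  }
  keep <- !is.na(table[[instrument]])
  tab <- table[keep, , drop = FALSE]
  y <- tab[[instrument]]
  X <- as.matrix(tab[, pred_cols, drop = FALSE])
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) {
    stopf("small-n: %d physicians with %s scores cannot support %d predictors (need >= %d)",
          n, instrument, p, p + 2)
  }
  if (p > 0) {
    # rank deficiency (constant or collinear parameter columns) is common in
    # sparse pruned networks: the posterior stays proper under the Gaussian
    # priors, so it is surfaced, not fatal
    D <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(D)
    if (qrX$rank < p + 1) {
      dropped <- setdiff(colnames(D), colnames(D)[qrX$pivot[seq_len(qrX$rank)]])
      warning(sprintf("rank-deficient design for %s; collinear columns: %s (coefficients identified by the prior only)",
                      instrument, paste(dropped, collapse = ", ")),
              call. = FALSE)
    }
  }

  sy <- sd(y); if (!is.finite(sy) || sy == 0) sy <- 1
  if (priors$autoscale) {
    sx <- apply(X, 2, sd)
    sx[!is.finite(sx) | sx == 0] <- 1
    slope_mean <- rep(priors$slope_mean, length.out = max(p, 1))
    slope_sd <- rep(priors$slope_sd, length.out = max(p, 1)) * sy / sx
    int_mean <- mean(y)
    int_sd <- priors$intercept_sd * sy
    sigma_scale <- priors$sigma_scale * sy
  } else {
    slope_mean <- rep(priors$slope_mean, length.out = max(p, 1))
    slope_sd <- rep(priors$slope_sd, length.out = max(p, 1))
    int_mean <- priors$intercept_mean
    int_sd <- priors$intercept_sd
    sigma_scale <- priors$sigma_scale
  }

  if (p == 0) {
    dat <- list(N = n, y = y, int_mean = int_mean, int_prec = int_sd^-2,
                sigma_scale = sigma_scale)
    chains <- run_jags(jags_model_intercept_only, dat, c("alpha", "sigma"),
                       mcmc, seed = mcmc$seed)
  } else {
    dat <- list(N = n, Kp = p, X = X, y = y,
                int_mean = int_mean, int_prec = int_sd^-2,
                slope_mean = slope_mean, slope_prec = slope_sd^-2,
                sigma_scale = sigma_scale)
    chains <- run_jags(jags_model_prediction, dat, c("alpha", "beta", "sigma"),
                       mcmc, seed = mcmc$seed)
  }
  draws <- stack_chains(chains)
  coef_draws <- cbind(`(Intercept)` = draws[, "alpha"])
  if (p > 0) {
    B <- draws[, paste0("beta[", seq_len(p), "]"), drop = FALSE]
    colnames(B) <- pred_cols
    coef_draws <- cbind(coef_draws, B)
  }

  # draw-wise linear predictor, multiple correlation R and R^2
  eta_draws <- if (p > 0) {
    coef_draws[, 1] + coef_draws[, -1, drop = FALSE] %*% t(X)
  } else {
    matrix(coef_draws[, 1], nrow(coef_draws), n)
  }
  R_draws <- apply(eta_draws, 1, function(e) {
    if (sd(e) == 0) return(0)
    max(0, cor(e, y))
  })
  R2_draws <- R_draws^2

  qs <- apply(coef_draws, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  coef_table <- data.frame(
    predictor = colnames(coef_draws),
    estimate = qs[2, ],
    ci_low = qs[1, ], ci_high = qs[3, ],
    significant = qs[1, ] > 0 | qs[3, ] < 0,
    row.names = NULL, stringsAsFactors = FALSE
  )

  rhat <- data.frame(
    parameter = colnames(draws),
    rhat = vapply(colnames(draws), function(pn) {
      split_rhat(sapply(chains, function(ch) ch[, pn]))
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(
    instrument = instrument,
    predictors = pred_cols,
    physician_ids = tab$physician_id,
    n = n,
    coef_draws = coef_draws,
    coef_table = coef_table,
    sigma = draws[, "sigma"],
    R_draws = R_draws,
    R2_draws = R2_draws,
    R = unname(quantile(R_draws, c(0.5, 0.025, 0.975), names = FALSE)),
    R2 = unname(quantile(R2_draws, c(0.5, 0.025, 0.975), names = FALSE)),
    fitted = colMeans(eta_draws),
    observed = y,
    chains = chains,
    rhat = rhat,
    priors = priors,
    mcmc = mcmc
  ), class = "prediction_fit")
}

#' @export
print.prediction_fit <- function(x, ...) {
  cat(sprintf("Prediction fit: %s ~ %d network parameters (n = %d physicians)\n",
              x$instrument, length(x$predictors), x$n))
  cat(sprintf("  R = %.3f [%.3f, %.3f], R^2 = %.3f [%.3f, %.3f]\n",
              x$R[1], x$R[2], x$R[3], x$R2[1], x$R2[2], x$R2[3]))
  tb <- x$coef_table
  tb$estimate <- round(tb$estimate, 2)
  tb$ci_low <- round(tb$ci_low, 2)
  tb$ci_high <- round(tb$ci_high, 2)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' @export
coef.prediction_fit <- function(object, ...) {
  setNames(object$coef_table$estimate, object$coef_table$predictor)
}

#' @export
summary.prediction_fit <- function(object, ...) {
  list(instrument = object$instrument, n = object$n,
       coefficients = object$coef_table,
       R = object$R, R2 = object$R2,
       max_rhat = max(object$rhat$rhat, na.rm = TRUE))
}

#' @export
fitted.prediction_fit <- function(object, ...) {
  setNames(object$fitted, object$physician_ids)
}

#' Predicted/observed calibration pairs of a prediction fit
#'
#' Per-physician posterior-mean prediction paired with the observed score,
#' optionally with lowess smoother coordinates for a calibration plot.
#'
#' @param fit A \code{prediction_fit}.
#' @param smooth Attach a lowess smoother as attribute \code{"smoother"}.
#' @return Data frame: physician_id, predicted, observed.
#' @export
calibration_pairs <- function(fit, smooth = FALSE) {
  stopifnot(inherits(fit, "prediction_fit"))
  out <- data.frame(physician_id = fit$physician_ids,
                    predicted = unname(fit$fitted),
                    observed = fit$observed,
                    stringsAsFactors = FALSE)
  if (smooth && nrow(out) >= 3) {
    sm <- lowess(out$predicted, out$observed)
    attr(out, "smoother") <- data.frame(x = sm$x, y = sm$y)
  }
  out
}

#' @export
plot.prediction_fit <- function(x, ...) {
  cp <- calibration_pairs(x, smooth = TRUE)
  rng <- range(c(cp$predicted, cp$observed))
  graphics::plot(cp$predicted, cp$observed, xlim = rng, ylim = rng,
                 xlab = "Predicted score", ylab = "Observed score",
                 main = sprintf("Calibration: %s", x$instrument), pch = 16, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  sm <- attr(cp, "smoother")
  if (!is.null(sm)) graphics::lines(sm$x, sm$y, col = "grey30")
  invisible(x)
}

prior_from_file_entry <- function(spec, instrument, pred_cols, base = prior_spec()) {
  entry <- spec[[instrument]]
  if (is.null(entry)) {
    stopf("prior file has no entry for instrument %s", instrument)
  }
  sm <- rep(base$slope_mean, length.out = length(pred_cols))
  ss <- rep(base$slope_sd, length.out = length(pred_cols))
  names(sm) <- names(ss) <- pred_cols
  for (cl in pred_cols) {
    if (!is.null(entry[[cl]])) {
      sm[cl] <- entry[[cl]]$mean
      ss[cl] <- entry[[cl]]$sd
    }
  }
  im <- base$intercept_mean; is_ <- base$intercept_sd
  if (!is.null(entry$intercept)) {
    im <- entry$intercept$mean; is_ <- entry$intercept$sd
  }
  prior_spec(slope_mean = unname(sm), slope_sd = unname(ss),
             intercept_mean = im, intercept_sd = is_,
             sigma_scale = base$sigma_scale, autoscale = FALSE,
             provenance = "file")
}

#' Confirmatory prediction of observer-rated competence
#'
#' Fits, per instrument, the fixed confirmatory model: activation, instrength
#' and outstrength of focusing the decision (skill 1), eliciting preferences
#' (skill 6) and deliberating the decision (skill 7) as predictors (nine
#' coefficients), with informative per-coefficient Gaussian priors read from a
#' prior file (e.g. posterior summaries from an earlier patient-rated study).
#' Without a prior file, weakly informative defaults are used with a warning.
#'
#' @param networks List of physician networks.
#' @param scores Aggregated competence scores
#'   (\code{\link{aggregate_observer}} output).
#' @param prior_file Path to a \code{\link{read_prior_file}} file, an already
#'   parsed prior list, or NULL.
#' @param mcmc An \code{\link{mcmc_config}}.
#' @param skills Fixed predictor skill set (default \code{c(1, 6, 7)}).
#' @param instruments Instruments to fit (default: all present in scores).
#' @return Object of class \code{sdm_prediction_report}: list of
#'   \code{prediction_fit}s (one per instrument) plus metadata.
#' @export
confirmatory_model <- function(networks, scores, prior_file = NULL,
                               mcmc = mcmc_config(), skills = c(1L, 6L, 7L),
                               instruments = NULL) {
  table <- assemble_predictors(networks, skills = skills, scores = scores)
  pred_cols <- attr(table, "predictors")
  instruments <- instruments %||% attr(table, "instruments")
  spec <- NULL
  if (is.null(prior_file)) {
    warning("no prior file supplied; falling back to weakly informative default priors",
            call. = FALSE)
  } else if (is.character(prior_file)) {
    spec <- read_prior_file(prior_file)
  } else {
    spec <- prior_file
  }
  fits <- list()
  for (i in seq_along(instruments)) {
    ins <- instruments[i]
    pr <- if (is.null(spec)) prior_spec(autoscale = TRUE)
          else prior_from_file_entry(spec, ins, pred_cols)
    mc <- mcmc
    mc$seed <- child_seed(mcmc$seed, 300 + i)
    fits[[ins]] <- fit_prediction(table, ins, priors = pr, mcmc = mc)
  }
  structure(list(model = "confirmatory", skills = skills, fits = fits,
                 predictors = pred_cols, table = table),
            class = "sdm_prediction_report")
}

#' Two-stage exploratory prediction of observer-rated competence
#'
#' Stage 1 fits, for each parameter type (activation, instrength,
#' outstrength) and each instrument, a regression on that type's parameters of
#' all nine skills. A skill is selected when any of its parameters is a
#' significant predictor (95\% CI excluding zero) in any stage-1 model. The
#' final model regresses each instrument on activation, instrength and
#' outstrength of the selected skills, with weakly informative priors
#' throughout. An empty selection yields intercept-only final models.
#'
#' @inheritParams confirmatory_model
#' @param priors Weakly informative \code{\link{prior_spec}} used in all
#'   stages.
#' @return Object of class \code{sdm_exploratory}: \code{stage1} (nested
#'   fits by type and instrument), \code{selected_skills}, and \code{final}
#'   (an \code{sdm_prediction_report}).
#' @export
exploratory_procedure <- function(networks, scores,
                                  priors = prior_spec(autoscale = TRUE),
                                  mcmc = mcmc_config(), instruments = NULL) {
  types <- c("activation", "instrength", "outstrength")
  all_skills <- seq_along(networks[[1]]$skills)
  stage1 <- list()
  selected <- integer(0)
  cnt <- 0L
  for (tp in types) {
    table_t <- assemble_predictors(networks, skills = all_skills, types = tp,
                                   scores = scores)
    ins_t <- instruments %||% attr(table_t, "instruments")
    stage1[[tp]] <- list()
    for (ins in ins_t) {
      cnt <- cnt + 1L
      mc <- mcmc
      mc$seed <- child_seed(mcmc$seed, 400 + cnt)
      fit <- fit_prediction(table_t, ins, priors = priors, mcmc = mc)
      stage1[[tp]][[ins]] <- fit
      sig <- fit$coef_table[fit$coef_table$significant &
                              fit$coef_table$predictor != "(Intercept)", ]
      if (nrow(sig)) {
        sk <- as.integer(sub(".*_skill_", "", sig$predictor))
        selected <- union(selected, sk)
      }
    }
  }
  selected <- sort(selected)

  table_f <- assemble_predictors(networks, skills = selected, scores = scores)
  ins_f <- instruments %||% attr(table_f, "instruments")
  final_fits <- list()
  for (i in seq_along(ins_f)) {
    mc <- mcmc
    mc$seed <- child_seed(mcmc$seed, 500 + i)
    final_fits[[ins_f[i]]] <- fit_prediction(table_f, ins_f[i], priors = priors,
                                             mcmc = mc)
  }
  final <- structure(list(model = "exploratory", skills = selected,
                          fits = final_fits,
                          predictors = attr(table_f, "predictors"),
                          table = table_f),
                     class = "sdm_prediction_report")
  structure(list(stage1 = stage1, selected_skills = selected, final = final),
            class = "sdm_exploratory")
}

#' @export
print.sdm_prediction_report <- function(x, ...) {
  cat(sprintf("%s prediction report: skills {%s}, %d predictor columns\n",
              tools::toTitleCase(x$model), paste(x$skills, collapse = ","),
              length(x$predictors)))
  for (ins in names(x$fits)) {
    f <- x$fits[[ins]]
    cat(sprintf("  %s (n = %d): R = %.3f [%.3f, %.3f], R^2 = %.3f\n",
                ins, f$n, f$R[1], f$R[2], f$R[3], f$R2[1]))
  }
  invisible(x)
}

#' @export
print.sdm_exploratory <- function(x, ...) {
  cat(sprintf("Exploratory procedure: selected skills {%s}\n",
              paste(x$selected_skills, collapse = ",")))
  print(x$final)
  invisible(x)
}

#' Coefficient table of a prediction report
#'
#' Stacks the per-instrument coefficient tables (estimate, ci_low, ci_high,
#' significant) of a confirmatory or exploratory-final report; the row layout
#' mirrors the published reporting surface (intercept plus one row per
#' (skill, parameter-type) predictor, per instrument).
#'
#' @param report An \code{sdm_prediction_report}.
#' @return Data frame with an \code{instrument} column followed by the
#'   coefficient summaries.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "sdm_prediction_report"))
  do.call(rbind, lapply(names(report$fits), function(ins) {
    cbind(instrument = ins, report$fits[[ins]]$coef_table,
          stringsAsFactors = FALSE)
  }))
}

#' Fit statistics of a prediction report
#'
#' @param report An \code{sdm_prediction_report}.
#' @return Data frame: instrument, n, R and R-squared posterior medians with
#'   95\% credible intervals.
#' @export
report_fit_stats <- function(report) {
  stopifnot(inherits(report, "sdm_prediction_report"))
  do.call(rbind, lapply(names(report$fits), function(ins) {
    f <- report$fits[[ins]]
    data.frame(instrument = ins, n = f$n,
               R = f$R[1], R_ci_low = f$R[2], R_ci_high = f$R[3],
               R2 = f$R2[1], R2_ci_low = f$R2[2], R2_ci_high = f$R2[3],
               stringsAsFactors = FALSE)
  }))
}
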