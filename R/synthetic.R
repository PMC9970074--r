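# Synthetic-data generator with analytic ground truth.
#
# The joint generative model per physician is a multivariate Gaussian over the
# nine skill ratings, parameterized by a precision matrix Omega_p. The
# node-wise linear regressions used for estimation are exactly the
# conditionals of this joint, so the true directed edge weight from skill k to
# skill j for physician p is -Omega_p[j,k] / Omega_p[j,j]. This gives every
# recovery test an analytic truth.

default_item_means <- function() {
  # self-ratings of SDM skills sit in the upper half of the 0-5 scale;
  # planning actions (9) is used most, eliciting preferences (6) least
  c(3.4, 3.3, 3.6, 3.8, 3.5, 3.1, 3.3, 3.9, 4.0)
}

# Fixed default conditional-dependence topology over the nine skills:
# skills 1-2 form a dyad disconnected from the rest; 3,4,6,8 cluster around 7;
# 5 hangs off 4 and 9 off 8. Entries are partial correlations.
default_structure_edges <- function() {
  rbind(
    c(1, 2, 0.45),
    c(3, 7, 0.22), c(4, 7, 0.22), c(6, 7, 0.22), c(7, 8, 0.22),
    c(3, 4, 0.18), c(4, 6, 0.18), c(6, 8, 0.18),
    c(4, 5, 0.25), c(8, 9, 0.25)
  )
}

precision_from_edges <- function(edges, n_skills) {
  O <- diag(n_skills)
  if (!is.null(edges) && nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      j <- edges[r, 1]; k <- edges[r, 2]
      O[j, k] <- O[k, j] <- -edges[r, 3]
    }
  }
  O
}

default_observer_model <- function() {
  list(
    instruments = c("OPTION-12", "OPTION-5", "4HCS"),
    intercepts = c("OPTION-12" = 20, "OPTION-5" = 15, "4HCS" = 30),
    coefficients = data.frame(
      instrument = rep(c("OPTION-12", "OPTION-5", "4HCS"), each = 4),
      skill = rep(c(6L, 6L, 7L, 1L), times = 3),
      type = rep(c("activation", "outstrength", "outstrength", "activation"), times = 3),
      coefficient = c(
        12, 4, -5, 2,   # OPTION-12
        15, 3, -4, 1,   # OPTION-5
        8, 5, -3, 1     # 4HCS
      ),
      stringsAsFactors = FALSE
    ),
    noise_sd = c("OPTION-12" = 5, "OPTION-5" = 5, "4HCS" = 5)
  )
}

#' Sample a ground-truth generative model for skill ratings
#'
#' Draws a "true model": a population precision matrix over the skills, one
#' (possibly perturbed) precision matrix per physician, per-physician item
#' means, and a linear observer-score model. Node-wise regression coefficients
#' implied by a precision matrix \eqn{\Omega} are
#' \eqn{\beta_{j \leftarrow k} = -\omega_{jk}/\omega_{jj}}, which defines the
#' true directed edge weights used by recovery tests.
#'
#' @param n_physicians Number of physicians (default 28, the scale of a
#'   realistic outpatient SDM study).
#' @param n_skills Number of skills (default 9).
#' @param structure Either \code{"sdm"} (fixed default topology: skills 1--2
#'   form a dyad conditionally independent of the rest, skills 3,4,6,8 cluster
#'   around 7, with 5 and 9 peripheral) or \code{"random"} (each skill pair is
#'   conditionally independent with probability \code{sparsity}).
#' @param sparsity For \code{structure = "random"}: probability that a given
#'   off-diagonal precision entry is zero. \code{sparsity = 1} yields a
#'   diagonal population precision (all true edges zero).
#' @param heterogeneity Standard deviation of the additive, symmetric
#'   perturbation applied to the structurally nonzero off-diagonal precision
#'   entries of each physician. 0 makes all physicians identical. Perturbation
#'   is restricted to the structural support so the conditional-independence
#'   topology is shared by all physicians.
#' @param mean_heterogeneity Standard deviation of per-physician item-mean
#'   deviations around \code{item_means} (rating points). Gives physicians
#'   distinct true activations.
#' @param item_means Population item means on the 0--5 scale (length
#'   \code{n_skills}).
#' @param observer_model List with elements \code{instruments},
#'   \code{intercepts}, \code{coefficients} (data frame: instrument, skill,
#'   type, coefficient) and \code{noise_sd}; defaults to a sparse model in
#'   which activation and outstrength of eliciting preferences (skill 6) and
#'   outstrength of deliberating the decision (skill 7) drive the scores.
#' @param eig_floor Smallest admissible eigenvalue of a physician precision
#'   matrix; perturbations violating it are halved and retried.
#' @param max_retries Retries of the shrink-and-retry repair before erroring.
#' @param seed Integer seed; the model is a pure function of the arguments
#'   and the seed.
#' @return An object of class \code{sdm_true_model}.
#' @seealso \code{\link{true_network_params}}, \code{\link{simulate_ratings}},
#'   \code{\link{simulate_observer_scores}}
#' @export
#' @examples
#' m <- sample_true_model(n_physicians = 4, heterogeneity = 0.05, seed = 1)
#' round(m$population_precision[1:3, 1:3], 2)
sample_true_model <- function(n_physicians = 28L,
                              n_skills = 9L,
                              structure = c("sdm", "random"),
                              sparsity = 0.6,
                              heterogeneity = 0.08,
                              mean_heterogeneity = 0.3,
                              item_means = NULL,
                              observer_model = default_observer_model(),
                              eig_floor = 0.05,
                              max_retries = 8L,
                              seed = 1L) {
  structure <- match.arg(structure)
  if (n_physicians < 1L) stopf("n_physicians must be >= 1")
  if (heterogeneity < 0 || mean_heterogeneity < 0) stopf("heterogeneity scales must be >= 0")
  if (is.null(item_means)) {
    item_means <- if (n_skills == 9L) default_item_means() else rep(3, n_skills)
  }
  if (length(item_means) != n_skills) stopf("item_means must have length n_skills")

  with_seed(seed, {
    if (structure == "sdm") {
      if (n_skills != 9L) stopf("structure = 'sdm' requires n_skills = 9")
      edges <- default_structure_edges()
    } else {
      pairs <- which(upper.tri(diag(n_skills)), arr.ind = TRUE)
      keep <- runif(nrow(pairs)) >= sparsity
      edges <- if (any(keep)) {
        cbind(pairs[keep, , drop = FALSE],
              runif(sum(keep), 0.15, 0.3) * sample(c(-1, 1), sum(keep), TRUE))
      } else NULL
      if (!is.null(edges)) {
        # repair: shrink all partial correlations until PD
        for (i in 0:max_retries) {
          O <- precision_from_edges(edges, n_skills)
          if (min(eigen(O, symmetric = TRUE, only.values = TRUE)$values) > eig_floor) break
          edges[, 3] <- edges[, 3] / 2
        }
      }
    }
    pop <- precision_from_edges(edges, n_skills)
    if (min(eigen(pop, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stopf("population precision matrix is not positive definite")
    }

    support <- pop != 0 & row(pop) != col(pop)
    phys_prec <- vector("list", n_physicians)
    for (p in seq_len(n_physicians)) {
      scale_p <- heterogeneity
      for (try in seq_len(max_retries + 1L)) {
        O <- pop
        if (scale_p > 0 && any(support)) {
          idx <- which(support & upper.tri(support), arr.ind = TRUE)
          delta <- rnorm(nrow(idx), 0, scale_p)
          for (r in seq_len(nrow(idx))) {
            O[idx[r, 1], idx[r, 2]] <- O[idx[r, 1], idx[r, 2]] + delta[r]
            O[idx[r, 2], idx[r, 1]] <- O[idx[r, 1], idx[r, 2]]
          }
        }
        if (min(eigen(O, symmetric = TRUE, only.values = TRUE)$values) > eig_floor) break
        if (try > max_retries) {
          stopf("could not obtain a positive-definite physician precision after %d retries; reduce heterogeneity", max_retries)
        }
        scale_p <- scale_p / 2
      }
      phys_prec[[p]] <- O
    }

    ids <- sprintf("P%02d", seq_len(n_physicians))
    means <- matrix(rep(item_means, each = n_physicians), n_physicians, n_skills)
    if (mean_heterogeneity > 0) {
      means <- means + matrix(rnorm(n_physicians * n_skills, 0, mean_heterogeneity),
                              n_physicians, n_skills)
      means <- pmin(pmax(means, 0), 5)
    }
    dimnames(means) <- list(ids, skill_cols(n_skills))
    names(phys_prec) <- ids

    structure(list(
      n_physicians = n_physicians,
      n_skills = n_skills,
      physician_ids = ids,
      population_precision = pop,
      physician_precisions = phys_prec,
      item_means = item_means,
      physician_means = means,
      observer_model = observer_model,
      heterogeneity = heterogeneity,
      mean_heterogeneity = mean_heterogeneity,
      seed = as.integer(seed)
    ), class = "sdm_true_model")
  })
}

#' @export
print.sdm_true_model <- function(x, ...) {
  cat("Ground-truth skills model\n")
  cat(sprintf("  physicians: %d, skills: %d\n", x$n_physicians, x$n_skills))
  cat(sprintf("  nonzero population partial correlations: %d\n",
              sum(x$population_precision[upper.tri(x$population_precision)] != 0)))
  cat(sprintf("  heterogeneity (precision / means): %.3g / %.3g\n",
              x$heterogeneity, x$mean_heterogeneity))
  invisible(x)
}

# true directed edge matrix W[k, j] = -omega_jk / omega_jj for one precision matrix
true_edges_of <- function(Omega) {
  K <- nrow(Omega)
  W <- -t(Omega / diag(Omega))  # row k = predictor, col j = outcome
  diag(W) <- 0
  dimnames(W) <- list(skill_cols(K), skill_cols(K))
  W
}

#' True network parameters implied by a ground-truth model
#'
#' Computes, for every physician, the true directed edge weights
#' \eqn{-\omega_{jk}/\omega_{jj}}, the true activation (the physician's item
#' means) and the true instrength/outstrength (sums over incoming/outgoing
#' true edges; the truth has no credible-interval pruning).
#'
#' @param model An \code{sdm_true_model}.
#' @return List with \code{edges} (array physician x predictor-skill x
#'   outcome-skill) and \code{params} (long data frame: physician_id, skill,
#'   activation, instrength, outstrength).
#' @export
true_network_params <- function(model) {
  stopifnot(inherits(model, "sdm_true_model"))
  K <- model$n_skills
  P <- model$n_physicians
  edges <- array(0, dim = c(P, K, K),
                 dimnames = list(model$physician_ids, skill_cols(K), skill_cols(K)))
  rows <- vector("list", P)
  for (p in seq_len(P)) {
    W <- true_edges_of(model$physician_precisions[[p]])
    edges[p, , ] <- W
    rows[[p]] <- data.frame(
      physician_id = model$physician_ids[p],
      skill = seq_len(K),
      activation = unname(model$physician_means[p, ]),
      instrength = colSums(W),
      outstrength = rowSums(W),
      stringsAsFactors = FALSE
    )
  }
  list(edges = edges, params = do.call(rbind, rows))
}

#' Simulate consultation-level skill ratings
#'
#' Each consultation row is drawn from the physician's multivariate Gaussian
#' (mean: the physician's item means, covariance: inverse of the physician's
#' precision matrix). With \code{discretize = TRUE} the draws are clipped to
#' [0, 5] and rounded to the integer grid of the questionnaire; continuous
#' mode is kept for exact recovery tests.
#'
#' @param model An \code{sdm_true_model}.
#' @param consultations Consultations per physician: a single count or a
#'   vector of per-physician counts (default 11, a realistic average).
#' @param discretize Clip to [0, 5] and round to integers (default TRUE).
#' @param seed Integer seed.
#' @return A rating table: data frame with \code{physician_id},
#'   \code{consultation_id} and \code{skill_1 ... skill_K} columns.
#' @export
#' @examples
#' m <- sample_true_model(n_physicians = 2, seed = 1)
#' r <- simulate_ratings(m, consultations = 3, seed = 2)
#' dim(r)
simulate_ratings <- function(model, consultations = 11L, discretize = TRUE, seed = 1L) {
  stopifnot(inherits(model, "sdm_true_model"))
  P <- model$n_physicians
  counts <- if (length(consultations) == 1L) rep(as.integer(consultations), P)
            else as.integer(consultations)
  if (length(counts) != P) stopf("consultations must be a scalar or length n_physicians")
  if (any(counts < 1L)) stopf("consultation counts must be >= 1")

  with_seed(seed, {
    out <- vector("list", P)
    for (p in seq_len(P)) {
      Sigma <- solve(model$physician_precisions[[p]])
      X <- MASS::mvrnorm(counts[p], mu = model$physician_means[p, ], Sigma = Sigma)
      X <- matrix(X, nrow = counts[p])
      if (discretize) X <- round(pmin(pmax(X, 0), 5))
      df <- data.frame(
        physician_id = model$physician_ids[p],
        consultation_id = sprintf("C%03d", seq_len(counts[p])),
        stringsAsFactors = FALSE
      )
      df[skill_cols(model$n_skills)] <- as.data.frame(X)
      out[[p]] <- df
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Set rating cells missing completely at random
#'
#' @param ratings A rating table.
#' @param rate Per-cell missingness probability in [0, 1).
#' @param seed Integer seed (reproducible mask).
#' @return The rating table with skill cells set to \code{NA}; ids untouched.
#' @export
inject_missingness <- function(ratings, rate, seed = 1L) {
  assert_ratings(ratings)
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  if (rate == 0) return(ratings)
  K <- n_skills_of(ratings)
  with_seed(seed, {
    R <- rating_matrix(ratings)
    mask <- matrix(runif(length(R)) < rate, nrow(R), ncol(R))
    R[mask] <- NA_real_
    ratings[skill_cols(K)] <- as.data.frame(R)
    ratings
  })
}

#' Simulate observer competence scores from true network parameters
#'
#' For each instrument, a physician's score is
#' \code{intercept + sum(coefficient * parameter) + Gaussian noise}, clipped
#' to [0, 100]. Parameters are the true activation, instrength and
#' outstrength from \code{\link{true_network_params}}.
#'
#' @param model An \code{sdm_true_model}.
#' @param params Optional precomputed \code{true_network_params(model)}.
#' @param physician_ids Physicians receiving scores (default: all). Emulates
#'   studies where only a subset of consultations is audio-recorded.
#' @param seed Integer seed.
#' @return Data frame with \code{physician_id}, \code{instrument},
#'   \code{score} (0--100 scale) and \code{linear_predictor} (pre-noise,
#'   pre-clipping truth, useful for recovery checks).
#' @export
simulate_observer_scores <- function(model, params = NULL, physician_ids = NULL,
                                     seed = 1L) {
  stopifnot(inherits(model, "sdm_true_model"))
  om <- model$observer_model
  params <- params %||% true_network_params(model)
  ids <- physician_ids %||% model$physician_ids
  pp <- params$params
  with_seed(seed, {
    rows <- list()
    for (ins in om$instruments) {
      cf <- om$coefficients[om$coefficients$instrument == ins, , drop = FALSE]
      eta <- rep(unname(om$intercepts[ins]), length(ids))
      if (nrow(cf)) {
        for (r in seq_len(nrow(cf))) {
          sel <- pp$skill == cf$skill[r]
          val <- pp[[cf$type[r]]][sel][match(ids, pp$physician_id[sel])]
          eta <- eta + cf$coefficient[r] * val
        }
      }
      score <- pmin(pmax(eta + rnorm(length(ids), 0, unname(om$noise_sd[ins])), 0), 100)
      rows[[ins]] <- data.frame(physician_id = ids, instrument = ins,
                                score = score, linear_predictor = eta,
                                stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

#' Simulate a complete study-scale dataset
#'
#' Convenience wrapper reproducing the scale of a realistic outpatient SDM
#' study: 28 physicians with 11 consultations each (308 rows), light
#' item-level missingness, and observer scores for a 24-physician subset with
#' per-instrument coverage 22/24/22 (OPTION-12 / OPTION-5 / 4HCS).
#'
#' @param seed Integer seed driving every stochastic step.
#' @param n_physicians,consultations,missing_rate Scale knobs (study defaults).
#' @return List with \code{model}, \code{ratings} (with injected missingness),
#'   \code{observer} (long score table) and \code{truth}
#'   (\code{true_network_params}).
#' @export
simulate_study <- function(seed = 1L, n_physicians = 28L, consultations = 11L,
                           missing_rate = 0.01) {
  model <- sample_true_model(n_physicians = n_physicians, seed = child_seed(seed, 1))
  ratings <- simulate_ratings(model, consultations = consultations,
                              discretize = TRUE, seed = child_seed(seed, 2))
  ratings <- inject_missingness(ratings, missing_rate, seed = child_seed(seed, 3))
  truth <- true_network_params(model)
  n_rated <- min(24L, n_physicians)
  rated <- model$physician_ids[seq_len(n_rated)]
  observer <- simulate_observer_scores(model, params = truth,
                                       physician_ids = rated,
                                       seed = child_seed(seed, 4))
  # per-instrument coverage: OPTION-12 and 4HCS miss the last two rated physicians
  if (n_rated >= 4L) {
    drop <- rated[(n_rated - 1L):n_rated]
    observer <- observer[!(observer$instrument %in% c("OPTION-12", "4HCS") &
                             observer$physician_id %in% drop), ]
    rownames(observer) <- NULL
  }
  list(model = model, ratings = ratings, observer = observer, truth = truth)
}

#' Write / read a ground-truth model as JSON
#'
#' @param model An \code{sdm_true_model}.
#' @param path File path.
#' @return \code{write_true_model} returns \code{path} invisibly;
#'   \code{read_true_model} returns the reconstructed \code{sdm_true_model}.
#' @export
write_true_model <- function(model, path) {
  stopifnot(inherits(model, "sdm_true_model"))
  x <- unclass(model)
  x$physician_precisions <- lapply(x$physician_precisions, unname)
  x$population_precision <- unname(x$population_precision)
  x$physician_means <- unname(x$physician_means)
  # named atomic vectors lose names as JSON arrays; store as objects
  x$observer_model$intercepts <- as.list(x$observer_model$intercepts)
  x$observer_model$noise_sd <- as.list(x$observer_model$noise_sd)
  x$item_means <- as.numeric(x$item_means)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_true_model
#' @export
read_true_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$population_precision <- as.matrix(x$population_precision)
  x$physician_precisions <- lapply(x$physician_precisions, as.matrix)
  x$physician_means <- as.matrix(x$physician_means)
  dimnames(x$physician_means) <- list(x$physician_ids, skill_cols(x$n_skills))
  names(x$physician_precisions) <- x$physician_ids
  x$observer_model$intercepts <- unlist(x$observer_model$intercepts)
  x$observer_model$noise_sd <- unlist(x$observer_model$noise_sd)
  x$observer_model$coefficients <- as.data.frame(x$observer_model$coefficients)
  structure(x, class = "sdm_true_model")
}
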