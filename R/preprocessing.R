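# Tabular I/O, the consultation-level missingness rule, EM imputation and
# observer-score rescaling/aggregation.

#' Read and validate a consultation-level rating table
#'
#' Expects a CSV with columns \code{physician_id}, \code{consultation_id} and
#' \code{skill_1 ... skill_9} (ratings 0--5; empty cells or a sentinel string
#' are missing). Validation failures name the offending row and column.
#'
#' @param path CSV file path.
#' @param na Strings treated as missing (besides empty cells).
#' @return A validated rating table (data frame).
#' @export
read_ratings <- function(path, na = c("", "NA")) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = na,
                 check.names = FALSE)
  K <- n_skills_of(df)
  if (K < 2L) stopf("malformed header in %s: expected skill_* columns", path)
  for (cl in skill_cols(K)) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(!is.na(df[[cl]]) & is.na(suppressWarnings(as.numeric(df[[cl]]))))
      if (length(bad)) {
        stopf("non-numeric rating in %s, rows %s", cl,
              paste(utils::head(bad, 5), collapse = ", "))
      }
      df[[cl]] <- as.numeric(df[[cl]])
    }
  }
  df$physician_id <- as.character(df$physician_id)
  df$consultation_id <- as.character(df$consultation_id)
  assert_ratings(df, check_range = TRUE)
  df
}

#' Write a rating table to CSV
#' @param ratings A rating table.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  assert_ratings(ratings)
  write.csv(ratings, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Exclude consultations with more than two missing skills
#'
#' Applies the consultation-level missingness rule: a consultation is dropped
#' when three or more of the nine skills are missing; consultations with one
#' or two missing items are kept for EM imputation.
#'
#' @param ratings A rating table.
#' @param max_missing Largest number of missing skill items a consultation may
#'   have and still be retained (default 2).
#' @return List with \code{ratings} (retained rows) and \code{excluded}
#'   (data frame: physician_id, consultation_id, n_missing of dropped rows).
#' @export
filter_missing <- function(ratings, max_missing = 2L) {
  assert_ratings(ratings)
  nm <- rowSums(is.na(rating_matrix(ratings)))
  drop <- nm > max_missing
  excluded <- data.frame(
    physician_id = ratings$physician_id[drop],
    consultation_id = ratings$consultation_id[drop],
    n_missing = nm[drop],
    stringsAsFactors = FALSE
  )
  kept <- ratings[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(ratings = kept, excluded = excluded)
}

# observed-data log-likelihood of rows under MVN(mu, Sigma), missing entries
# marginalized out
mvn_obs_loglik <- function(X, mu, Sigma) {
  ll <- 0
  pat <- apply(!is.na(X), 1, function(z) paste(as.integer(z), collapse = ""))
  for (pt in unique(pat)) {
    rows <- which(pat == pt)
    obs <- !is.na(X[rows[1], ])
    if (!any(obs)) next
    So <- Sigma[obs, obs, drop = FALSE]
    Xo <- X[rows, obs, drop = FALSE]
    d <- sum(obs)
    ch <- chol(So)
    Z <- forwardsolve(t(ch), t(Xo) - mu[obs])
    ll <- ll + length(rows) * (-0.5 * d * log(2 * pi) - sum(log(diag(ch)))) -
      0.5 * sum(Z^2)
  }
  ll
}

#' Impute missing skill items by expectation-maximization
#'
#' Fits a single multivariate Gaussian to all consultations pooled (maximum
#' likelihood via EM) and replaces each missing cell with its conditional
#' expectation given the observed items of that consultation. Imputed values
#' stay continuous; observed cells are untouched. The observed-data
#' log-likelihood is non-decreasing over iterations; convergence is declared
#' when successive log-likelihoods differ by less than \code{tol}.
#'
#' @param ratings A rating table in which every consultation has at most
#'   \code{max_missing} missing skills (apply \code{\link{filter_missing}}
#'   first).
#' @param tol Convergence threshold on the log-likelihood difference.
#' @param max_iter Maximum EM iterations; non-convergence is an error
#'   carrying the iteration trace.
#' @param max_missing Guard consistent with \code{\link{filter_missing}}.
#' @param per_physician Fit a separate Gaussian per physician instead of
#'   pooling (off by default: per-physician row counts are usually too small
#'   for a stable 9-dimensional covariance).
#' @return The completed rating table, with attribute \code{"em"}: a list with
#'   \code{loglik} (trace), \code{iterations}, \code{converged}, \code{mu},
#'   \code{sigma}.
#' @export
impute_em <- function(ratings, tol = 1e-6, max_iter = 100L, max_missing = 2L,
                      per_physician = FALSE) {
  assert_ratings(ratings)
  K <- n_skills_of(ratings)
  X <- rating_matrix(ratings)
  nm <- rowSums(is.na(X))
  if (any(nm > max_missing)) {
    stopf("%d consultation(s) have more than %d missing skills; run filter_missing first",
          sum(nm > max_missing), max_missing)
  }
  if (per_physician) {
    pieces <- split(seq_len(nrow(ratings)), ratings$physician_id)
    out <- ratings
    for (idx in pieces) {
      sub <- impute_em(ratings[idx, , drop = FALSE], tol = tol,
                       max_iter = max_iter, max_missing = max_missing)
      out[idx, skill_cols(K)] <- sub[skill_cols(K)]
    }
    return(out)
  }
  if (!anyNA(X)) {
    ll <- tryCatch(
      mvn_obs_loglik(X, colMeans(X), stats::cov(X) * (nrow(X) - 1) / nrow(X)),
      error = function(e) NA_real_  # singular covariance (n <= K): no density
    )
    attr(ratings, "em") <- list(loglik = ll, iterations = 0L, converged = TRUE)
    return(ratings)
  }

  n <- nrow(X)
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- X
  for (k in seq_len(K)) Xc[is.na(Xc[, k]), k] <- mu[k]
  Sigma <- stats::cov(Xc) * (n - 1) / n
  Sigma <- Sigma + diag(1e-6, K)

  ll_trace <- numeric(0)
  converged <- FALSE
  miss_rows <- which(rowSums(is.na(X)) > 0)
  for (it in seq_len(max_iter)) {
    # E-step: conditional means and residual covariance contributions
    Xhat <- X
    Cacc <- matrix(0, K, K)
    for (i in miss_rows) {
      m <- is.na(X[i, ]); o <- !m
      Soo_inv_Som <- solve(Sigma[o, o, drop = FALSE], Sigma[o, m, drop = FALSE])
      Xhat[i, m] <- mu[m] + drop(crossprod(Soo_inv_Som, X[i, o] - mu[o]))
      Cmm <- Sigma[m, m, drop = FALSE] -
        crossprod(Soo_inv_Som, Sigma[o, m, drop = FALSE])
      Cacc[m, m] <- Cacc[m, m] + Cmm
    }
    # M-step (ML, 1/n normalization keeps EM monotone)
    mu_new <- colMeans(Xhat)
    D <- sweep(Xhat, 2, mu_new)
    Sigma_new <- (crossprod(D) + Cacc) / n
    mu <- mu_new
    Sigma <- Sigma_new + diag(1e-10, K)
    ll <- mvn_obs_loglik(X, mu, Sigma)
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll_trace[it] - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max_iter > 1L) {
    stopf("EM did not converge in %d iterations (log-likelihood trace: %s ...)",
          max_iter, paste(round(utils::tail(ll_trace, 3), 4), collapse = ", "))
  }
  # final E-step under converged parameters
  Xout <- X
  for (i in miss_rows) {
    m <- is.na(X[i, ]); o <- !m
    Soo_inv_Som <- solve(Sigma[o, o, drop = FALSE], Sigma[o, m, drop = FALSE])
    Xout[i, m] <- mu[m] + drop(crossprod(Soo_inv_Som, X[i, o] - mu[o]))
  }
  ratings[skill_cols(K)] <- as.data.frame(Xout)
  attr(ratings, "em") <- list(loglik = ll_trace, iterations = length(ll_trace),
                              converged = converged, mu = mu, sigma = Sigma)
  ratings
}

#' Rescale an instrument score to the 0--100 range
#'
#' Affine, order-preserving transform \code{100 * (raw - min) / (max - min)};
#' higher values indicate higher competence.
#'
#' @param raw Raw score(s) within the instrument range.
#' @param instrument_min,instrument_max The instrument's raw range.
#' @return Score(s) in [0, 100].
#' @export
#' @examples
#' rescale_score(36, 12, 60)  # midpoint -> 50
rescale_score <- function(raw, instrument_min, instrument_max) {
  if (instrument_max <= instrument_min) stopf("instrument_max must exceed instrument_min")
  if (any(!is.na(raw) & (raw < instrument_min | raw > instrument_max))) {
    stopf("raw score outside [%g, %g]", instrument_min, instrument_max)
  }
  100 * (raw - instrument_min) / (instrument_max - instrument_min)
}

#' Read an observer score table and rescale to 0--100
#'
#' Expects a CSV with columns \code{physician_id}, optional
#' \code{consultation_id}, \code{instrument} and \code{raw_score}. Each
#' instrument's raw range is supplied via \code{instruments} (a named list of
#' \code{list(min =, max =)}); instruments absent from the config are assumed
#' already on the 0--100 scale.
#'
#' @param path CSV file path.
#' @param instruments Named list of raw ranges per instrument.
#' @return Data frame with a rescaled \code{score} column in [0, 100].
#' @export
read_observer <- function(path, instruments = list()) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("physician_id", "instrument", "raw_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("observer table lacks columns: %s", paste(miss, collapse = ", "))
  df$physician_id <- as.character(df$physician_id)
  df$score <- df$raw_score
  for (ins in names(instruments)) {
    sel <- df$instrument == ins
    rg <- instruments[[ins]]
    df$score[sel] <- rescale_score(df$raw_score[sel], rg$min, rg$max)
  }
  if (any(!is.na(df$score) & (df$score < 0 | df$score > 100))) {
    stopf("observer scores outside [0, 100] after rescaling; check instrument ranges")
  }
  df
}

#' Aggregate observer scores into per-physician competence scores
#'
#' Arithmetic mean of the (rescaled) observer score per physician per
#' instrument, with the count of contributing consultations. Physicians with
#' no rated consultation for an instrument are absent from that instrument's
#' rows, not zero-filled.
#'
#' @param scores Data frame with \code{physician_id}, \code{instrument} and
#'   \code{score} columns (0--100).
#' @return Data frame: \code{physician_id}, \code{instrument}, \code{score}
#'   (mean), \code{n_consultations}.
#' @export
aggregate_observer <- function(scores) {
  need <- c("physician_id", "instrument", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stopf("score table lacks columns: %s", paste(miss, collapse = ", "))
  ok <- !is.na(scores$score)
  scores <- scores[ok, , drop = FALSE]
  key <- interaction(scores$physician_id, scores$instrument, drop = TRUE)
  agg <- data.frame(
    physician_id = tapply(scores$physician_id, key, `[`, 1),
    instrument = tapply(scores$instrument, key, `[`, 1),
    score = as.numeric(tapply(scores$score, key, mean)),
    n_consultations = as.integer(tapply(scores$score, key, length)),
    stringsAsFactors = FALSE
  )
  rownames(agg) <- NULL
  agg[order(agg$instrument, agg$physician_id), , drop = FALSE]
}
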