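# Preprocessing: rating I/O and validation, the missingness rule, EM
# imputation against closed-form conditional-Gaussian oracles, observer
# rescaling and aggregation.

make_ratings <- function(R, ids = NULL) {
  n <- nrow(R)
  df <- data.frame(
    physician_id = ids %||% rep("P01", n),
    consultation_id = sprintf("C%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  df[paste0("skill_", seq_len(ncol(R)))] <- as.data.frame(R)
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("rating files round-trip and are validated on read", {
  m <- sample_true_model(n_physicians = 3, seed = 1)
  r <- inject_missingness(simulate_ratings(m, 4, seed = 2), 0.05, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_ratings(r, path)
  r2 <- read_ratings(path)
  expect_equal(r2, r)

  bad <- r
  bad$skill_3[2] <- 7
  path2 <- tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE, na = "")
  expect_error(read_ratings(path2), "skill_3")
  expect_error(read_ratings(path2), "row 2")

  dup <- r
  dup$consultation_id[2] <- dup$consultation_id[1]
  path3 <- tempfile(fileext = ".csv")
  write.csv(dup, path3, row.names = FALSE, na = "")
  expect_error(read_ratings(path3), "duplicate")

  # empty cells come back as missing, not zero
  txt <- "physician_id,consultation_id,skill_1,skill_2\nP1,C1,3,\nP1,C2,2,4\nP1,C3,1,0\n"
  path4 <- tempfile(fileext = ".csv")
  writeLines(txt, path4)
  r4 <- read_ratings(path4)
  expect_equal(nrow(r4), 3)
  expect_true(is.na(r4$skill_2[1]))
  expect_equal(r4$skill_2[3], 0)
})

test_that("consultations with more than two missing skills are excluded", {
  R <- matrix(3, 4, 9)
  R[1, 1:3] <- NA   # 3 missing -> excluded
  R[2, 1:2] <- NA   # 2 missing -> retained
  R[3, 5] <- NA     # 1 missing -> retained
  r <- make_ratings(R)
  flt <- filter_missing(r)
  expect_equal(nrow(flt$ratings), 3)
  expect_equal(flt$excluded$consultation_id, "C001")
  expect_equal(flt$excluded$n_missing, 3)
  # idempotent
  flt2 <- filter_missing(flt$ratings)
  expect_identical(flt2$ratings, flt$ratings)
  expect_equal(nrow(flt2$excluded), 0)
  # fully observed table untouched, empty report
  full <- make_ratings(matrix(2, 3, 9))
  flt3 <- filter_missing(full)
  expect_identical(flt3$ratings, full)
  expect_equal(nrow(flt3$excluded), 0)
})

test_that("EM is an identity on complete data and refuses >2 missing", {
  r <- make_ratings(matrix(rnorm(45, 3), 5, 9))
  out <- impute_em(r)
  expect_true(attr(out, "em")$converged)
  attr(out, "em") <- NULL
  expect_identical(out, r)
  R <- matrix(3, 3, 9); R[1, 1:4] <- NA
  expect_error(impute_em(make_ratings(R)), "filter_missing")
})

test_that("EM imputation matches the closed-form conditional mean (bivariate)", {
  # monotone pattern: skill_1 missing on some rows, skill_2 complete. The
  # observed-data MLE factorizes, so the imputed value must equal the
  # complete-case least-squares prediction of skill_1 from skill_2.
  set.seed(101)
  n <- 400
  x2 <- rnorm(n, 3, 1)
  x1 <- 1 + 0.6 * x2 + rnorm(n, 0, 0.5)
  R <- cbind(x1, x2)
  miss <- c(5, 50, 333)
  R[miss, 1] <- NA
  r <- make_ratings(R)
  imp <- impute_em(r, tol = 1e-12, max_iter = 1000)
  cc <- !(seq_len(n) %in% miss)
  ols <- lm(R[cc, 1] ~ R[cc, 2])
  pred <- coef(ols)[1] + coef(ols)[2] * x2[miss]
  expect_equal(imp$skill_1[miss], unname(pred), tolerance = 1e-4)
  # observed cells are bit-identical
  expect_identical(imp$skill_2, r$skill_2)
  expect_identical(imp$skill_1[cc], r$skill_1[cc])
})

test_that("EM imputes two jointly missing cells at the Schur-complement mean (9-variate)", {
  m <- sample_true_model(n_physicians = 1, heterogeneity = 0, seed = 55)
  r <- simulate_ratings(m, consultations = 300, discretize = FALSE, seed = 56)
  R <- as.matrix(r[, paste0("skill_", 1:9)])
  # monotone block pattern: skills 2 and 7 jointly missing on a few rows
  miss <- c(3, 80, 150)
  R[miss, c(2, 7)] <- NA
  rr <- make_ratings(R)
  imp <- impute_em(rr, tol = 1e-12, max_iter = 1000)
  cc <- setdiff(seq_len(nrow(R)), miss)
  obs_cols <- setdiff(1:9, c(2, 7))
  # oracle: multivariate least squares of the missing block on the observed
  # block over complete cases (the factorized MLE's conditional mean)
  fit <- lm(R[cc, c(2, 7)] ~ R[cc, obs_cols])
  pred <- cbind(1, R[miss, obs_cols]) %*% coef(fit)
  got <- as.matrix(imp[miss, paste0("skill_", c(2, 7))])
  expect_equal(unname(got), unname(pred), tolerance = 1e-4)
})

test_that("EM log-likelihood is non-decreasing on scattered missingness", {
  m <- sample_true_model(n_physicians = 4, seed = 61)
  r <- simulate_ratings(m, consultations = 40, discretize = FALSE, seed = 62)
  r <- inject_missingness(r, 0.04, seed = 63)
  r <- filter_missing(r)$ratings
  imp <- impute_em(r, tol = 1e-9, max_iter = 500)
  ll <- attr(imp, "em")$loglik
  expect_gt(length(ll), 1)
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("EM reports non-convergence with an iteration trace", {
  set.seed(71)
  R <- matrix(rnorm(900, 3), 100, 9)
  R[1:30, 1] <- NA
  err <- tryCatch(impute_em(make_ratings(R), tol = 0, max_iter = 5),
                  error = function(e) conditionMessage(e))
  expect_match(err, "did not converge")
  expect_match(err, "5 iterations")
})

test_that("rescale_score is the exact affine map onto 0-100", {
  expect_equal(rescale_score(60, 12, 60), 100)
  expect_equal(rescale_score(12, 12, 60), 0)
  expect_equal(rescale_score(36, 12, 60), 50)
  # affine and order-preserving, hence invertible
  raw <- c(15, 20, 33, 59)
  sc <- rescale_score(raw, 12, 60)
  expect_true(all(diff(sc) > 0))
  expect_equal(sc / 100 * (60 - 12) + 12, raw)
  expect_error(rescale_score(61, 12, 60), "outside")
  expect_error(rescale_score(30, 60, 12), "exceed")
})

test_that("observer aggregation averages per physician and instrument", {
  obs <- data.frame(
    physician_id = c("A", "A", "A", "B", "B"),
    instrument = c("OPTION-5", "OPTION-5", "OPTION-5", "OPTION-5", "4HCS"),
    score = c(20, 40, 60, 10, 80)
  )
  agg <- aggregate_observer(obs)
  expect_equal(agg$score[agg$physician_id == "A" & agg$instrument == "OPTION-5"], 40)
  expect_equal(agg$n_consultations[agg$physician_id == "A" & agg$instrument == "OPTION-5"], 3)
  # physician A has no 4HCS rows: absent, not zero-filled
  expect_false(any(agg$physician_id == "A" & agg$instrument == "4HCS"))
  expect_equal(nrow(agg), 3)
})

test_that("observer files are read and rescaled by instrument range", {
  df <- data.frame(physician_id = c("A", "A", "B"),
                   consultation_id = c("C1", "C2", "C1"),
                   instrument = c("OPTION-12", "OPTION-12", "4HCS"),
                   raw_score = c(12, 48, 4))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  obs <- read_observer(path, instruments = list(
    "OPTION-12" = list(min = 0, max = 48), "4HCS" = list(min = 1, max = 5)
  ))
  expect_equal(obs$score, c(25, 100, 75))
  # instruments absent from the config pass through unscaled
  obs2 <- read_observer(path)
  expect_equal(obs2$score, obs2$raw_score)
  # out-of-range raw values are rejected
  bad <- df; bad$raw_score[1] <- 50
  path2 <- tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(
    read_observer(path2, instruments = list("OPTION-12" = list(min = 0, max = 48))),
    "outside"
  )
})
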