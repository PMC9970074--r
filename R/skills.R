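# Skill indexing, column conventions and small shared utilities.

#' Names of the nine SDM skills
#'
#' Returns the fixed labels of the nine shared decision making skills, in the
#' standard item order of the 9-item physician questionnaire (ratings 0--5).
#'
#' @param n_skills Number of skills; only the default 9 carries the standard
#'   labels, other values get generic labels (useful for toy examples).
#' @return Character vector of skill labels.
#' @export
#' @examples
#' skill_labels()
skill_labels <- function(n_skills = 9L) {
  std <- c(
    "focusing the decision", "sharing the decision", "presenting options",
    "informing on options", "supporting comprehension", "eliciting preferences",
    "deliberating the decision", "selecting an option", "planning actions"
  )
  if (n_skills == 9L) std else paste("skill", seq_len(n_skills))
}

skill_cols <- function(n_skills = 9L) paste0("skill_", seq_len(n_skills))

# number of skill_* columns in a rating table
n_skills_of <- function(ratings) {
  sum(grepl("^skill_[0-9]+$", names(ratings)))
}

rating_matrix <- function(ratings) {
  as.matrix(ratings[, skill_cols(n_skills_of(ratings)), drop = FALSE])
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

# derive a child seed from a master seed, kept within 32-bit integer range
child_seed <- function(seed, k) as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_ratings <- function(ratings, require_complete = FALSE, check_range = FALSE) {
  K <- n_skills_of(ratings)
  if (K < 2L) stopf("rating table must contain at least two skill_* columns")
  need <- c("physician_id", "consultation_id", skill_cols(K))
  miss <- setdiff(need, names(ratings))
  if (length(miss)) stopf("rating table lacks columns: %s", paste(miss, collapse = ", "))
  key <- paste(ratings$physician_id, ratings$consultation_id, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate (physician_id, consultation_id) pairs")
  R <- rating_matrix(ratings)
  # range is a contract of rating files (0-5 questionnaire grid); continuous
  # simulation output for recovery tests is deliberately unbounded
  bad <- if (check_range) which(!is.na(R) & (R < 0 | R > 5), arr.ind = TRUE)
         else matrix(integer(0), 0, 2)
  if (nrow(bad)) {
    stopf(
      "ratings outside [0, 5]: %s",
      paste(sprintf("row %d, %s (=%g)", bad[, 1], colnames(R)[bad[, 2]],
                    R[bad]), collapse = "; ")
    )
  }
  if (require_complete && anyNA(R)) stopf("rating table contains missing skills; impute first")
  invisible(ratings)
}
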