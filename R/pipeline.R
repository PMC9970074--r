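# File-based pipeline orchestration: a YAML config drives three stages
# (simulate -> fit-networks -> predict) with CSV/JSON handoffs, a manifest per
# stage, and logging of counts at stage boundaries. A thin command-line
# wrapper over these functions ships in inst/cli/sdmnet.R.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "sdmnet-output",
    simulate = list(
      n_physicians = 28L, consultations = 11L, heterogeneity = 0.08,
      mean_heterogeneity = 0.3, missing_rate = 0.01, discretize = TRUE,
      study_coverage = TRUE
    ),
    paths = list(ratings = NULL, observer = NULL, prior_file = NULL),
    instruments = list(),   # per-instrument raw ranges: list(min =, max =)
    em = list(tol = 1e-6, max_iter = 100L),
    mcmc = list(n_chains = 4L, iterations = 10000L, burn_in = 5000L,
                thinning = 10L, n_adapt = 500L),
    prune_level = 0.95,
    varying = "correlated",
    confirmatory_skills = c(1L, 6L, 7L),
    instruments_used = NULL  # restrict prediction to these instruments
  )
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration and merges it over the documented defaults.
#' Unknown top-level keys are rejected by name.
#'
#' @param path YAML file, or NULL for the defaults.
#' @param overrides Named list applied on top (e.g. from CLI flags).
#' @return A validated config list of class \code{sdm_config}.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, user)
  if (cfg$prune_level <= 0 || cfg$prune_level >= 1) {
    stopf("prune_level must be in (0, 1)")
  }
  structure(cfg, class = c("sdm_config", "list"))
}

config_mcmc <- function(cfg, seed_offset = 0L) {
  m <- cfg$mcmc
  mcmc_config(n_chains = m$n_chains, iterations = m$iterations,
              burn_in = m$burn_in, thinning = m$thinning,
              n_adapt = m$n_adapt %||% 500L,
              seed = child_seed(cfg$seed, seed_offset))
}

config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$output_dir <- NULL  # where results go does not affect what they are
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, stage, outputs, extra = list()) {
  manifest <- c(list(
    stage = stage,
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    package = "sdmnet",
    package_version = as.character(packageVersion("sdmnet")),
    outputs = outputs
  ), extra)
  path <- file.path(cfg$output_dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline stage: simulate a synthetic study
#'
#' Generates a ground-truth model, consultation ratings (with injected
#' missingness) and observer scores, and writes them under the configured
#' output directory together with the ground truth (JSON) and a manifest.
#'
#' @param config An \code{\link{read_pipeline_config}} result (or path to one).
#' @return Invisibly, a list of the written file paths.
#' @export
run_simulate <- function(config = read_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  model <- sample_true_model(
    n_physicians = sim$n_physicians,
    heterogeneity = sim$heterogeneity,
    mean_heterogeneity = sim$mean_heterogeneity,
    seed = child_seed(config$seed, 1)
  )
  ratings <- simulate_ratings(model, consultations = sim$consultations,
                              discretize = isTRUE(sim$discretize),
                              seed = child_seed(config$seed, 2))
  ratings <- inject_missingness(ratings, sim$missing_rate,
                                seed = child_seed(config$seed, 3))
  truth <- true_network_params(model)
  rated <- if (isTRUE(sim$study_coverage)) {
    model$physician_ids[seq_len(min(24L, model$n_physicians))]
  } else model$physician_ids
  observer <- simulate_observer_scores(model, params = truth,
                                       physician_ids = rated,
                                       seed = child_seed(config$seed, 4))
  if (isTRUE(sim$study_coverage) && length(rated) >= 4L) {
    drop <- rated[(length(rated) - 1L):length(rated)]
    observer <- observer[!(observer$instrument %in% c("OPTION-12", "4HCS") &
                             observer$physician_id %in% drop), ]
  }
  paths <- list(
    ratings = file.path(config$output_dir, "ratings.csv"),
    observer = file.path(config$output_dir, "observer.csv"),
    true_model = file.path(config$output_dir, "true_model.json")
  )
  write_ratings(ratings, paths$ratings)
  obs_out <- data.frame(physician_id = observer$physician_id,
                        consultation_id = NA_character_,
                        instrument = observer$instrument,
                        raw_score = observer$score,
                        stringsAsFactors = FALSE)
  write.csv(obs_out, paths$observer, row.names = FALSE, na = "")
  write_true_model(model, paths$true_model)
  message(sprintf("simulate: %d physicians, %d consultations, %d observer rows",
                  model$n_physicians, nrow(ratings), nrow(observer)))
  write_manifest(config, "simulate", paths,
                 extra = list(n_physicians = model$n_physicians,
                              n_consultations = nrow(ratings)))
  invisible(paths)
}

#' Pipeline stage: estimate networks
#'
#' Reads ratings, applies the consultation-level missingness rule, imputes
#' remaining gaps by EM, fits the nine node-wise multilevel regressions,
#' builds one network per physician plus the population network, and writes
#' networks (JSON), a convergence report (CSV), node parameters (CSV) and a
#' manifest.
#'
#' @param config Config list or YAML path.
#' @param rhat_threshold Convergence flagging threshold.
#' @param on_nonconvergence \code{"error"} (default) or \code{"warn"} when any
#'   parameter exceeds the threshold.
#' @return Invisibly: list with \code{fits}, \code{networks},
#'   \code{population}, \code{exclusions}, \code{files}.
#' @export
run_fit_networks <- function(config = read_pipeline_config(),
                             rhat_threshold = 1.05,
                             on_nonconvergence = c("error", "warn")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  on_nonconvergence <- match.arg(on_nonconvergence)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  ratings_path <- config$paths$ratings %||%
    file.path(config$output_dir, "ratings.csv")
  ratings <- read_ratings(ratings_path)

  flt <- filter_missing(ratings)
  if (nrow(flt$excluded)) {
    message(sprintf("fit-networks: excluded %d consultation(s) with >2 missing skills: %s",
                    nrow(flt$excluded),
                    paste(flt$excluded$physician_id, flt$excluded$consultation_id,
                          sep = "/", collapse = ", ")))
  }
  complete <- impute_em(flt$ratings, tol = config$em$tol,
                        max_iter = config$em$max_iter)

  fits <- fit_all_nodes(complete, priors = prior_spec(),
                        mcmc = config_mcmc(config, 10L),
                        varying = config$varying)

  conv <- do.call(rbind, lapply(fits$fits, function(f) {
    data.frame(outcome = f$outcome_name, parameter = f$rhat$parameter,
               rhat = f$rhat$rhat, stringsAsFactors = FALSE)
  }))
  conv$flagged <- conv$rhat > rhat_threshold
  n_flag <- sum(conv$flagged, na.rm = TRUE)
  if (n_flag > 0) {
    msg <- sprintf("%d parameter(s) exceed R-hat %.3f (max %.4f)",
                   n_flag, rhat_threshold, max(conv$rhat, na.rm = TRUE))
    if (on_nonconvergence == "error") stopf("%s", msg) else warning(msg, call. = FALSE)
  }

  networks <- lapply(fits$physician_ids, function(id) {
    layout_network(
      build_physician_network(fits, complete, id, level = config$prune_level),
      seed = child_seed(config$seed, 20)
    )
  })
  names(networks) <- fits$physician_ids
  population <- layout_network(
    build_population_network(fits, complete, level = config$prune_level),
    seed = child_seed(config$seed, 21)
  )

  net_dir <- file.path(config$output_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  files <- list(
    convergence = file.path(config$output_dir, "convergence.csv"),
    exclusions = file.path(config$output_dir, "exclusions.csv"),
    node_params = file.path(config$output_dir, "network_parameters.csv"),
    posterior_summaries = file.path(config$output_dir, "posterior_summaries.csv"),
    population = file.path(net_dir, "population.json")
  )
  post <- do.call(rbind, lapply(fits$fits, function(f) {
    s <- summary(f)
    names(s)[names(s) == "ci_low"] <- "q2.5"
    names(s)[names(s) == "ci_high"] <- "q97.5"
    cbind(outcome = f$outcome_name, s)
  }))
  write.csv(post, files$posterior_summaries, row.names = FALSE)
  write.csv(conv, files$convergence, row.names = FALSE)
  write.csv(flt$excluded, files$exclusions, row.names = FALSE)
  params <- do.call(rbind, lapply(networks, network_params))
  write.csv(params, files$node_params, row.names = FALSE)
  export_network(population, files$population, format = "json")
  for (id in names(networks)) {
    export_network(networks[[id]], file.path(net_dir, paste0(id, ".json")),
                   format = "json")
  }
  message(sprintf("fit-networks: %d physicians, %d retained population edges, max R-hat %.4f",
                  length(networks), sum(population$retain),
                  max(conv$rhat, na.rm = TRUE)))
  write_manifest(config, "fit-networks", files,
                 extra = list(n_physicians = length(networks),
                              n_excluded = nrow(flt$excluded),
                              n_population_edges = sum(population$retain)))
  invisible(list(fits = fits, networks = networks, population = population,
                 exclusions = flt$excluded, files = files))
}

#' Pipeline stage: predict observer-rated competence
#'
#' Reads the per-physician networks and observer scores, aggregates scores per
#' physician, and runs the confirmatory model and the exploratory procedure.
#' Writes coefficient tables, fit statistics and calibration pairs as CSV,
#' plus a manifest.
#'
#' @param config Config list or YAML path.
#' @param networks Optional list of \code{sdm_network}s (else read from the
#'   output directory of the fit-networks stage).
#' @return Invisibly: list with \code{confirmatory}, \code{exploratory},
#'   \code{scores}, \code{files}.
#' @export
run_predict <- function(config = read_pipeline_config(), networks = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(networks)) {
    net_dir <- file.path(config$output_dir, "networks")
    nf <- setdiff(list.files(net_dir, pattern = "\\.json$", full.names = TRUE),
                  file.path(net_dir, "population.json"))
    if (!length(nf)) stopf("no physician networks found under %s; run fit-networks first", net_dir)
    networks <- lapply(nf, import_network)
    names(networks) <- vapply(networks, function(n) n$physician_id, character(1))
  }
  observer_path <- config$paths$observer %||%
    file.path(config$output_dir, "observer.csv")
  observer <- read_observer(observer_path, instruments = config$instruments)
  scores <- aggregate_observer(observer)
  if (!is.null(config$instruments_used)) {
    scores <- scores[scores$instrument %in% config$instruments_used, , drop = FALSE]
  }
  scores <- scores[scores$physician_id %in% names(networks), , drop = FALSE]

  mcmc <- config_mcmc(config, 30L)
  conf <- confirmatory_model(networks, scores,
                             prior_file = config$paths$prior_file,
                             mcmc = mcmc, skills = config$confirmatory_skills)
  expl <- exploratory_procedure(networks, scores, mcmc = mcmc)

  files <- list(
    confirmatory_coefficients = file.path(config$output_dir, "confirmatory_coefficients.csv"),
    confirmatory_fit = file.path(config$output_dir, "confirmatory_fit_stats.csv"),
    exploratory_coefficients = file.path(config$output_dir, "exploratory_coefficients.csv"),
    exploratory_fit = file.path(config$output_dir, "exploratory_fit_stats.csv"),
    stage1_coefficients = file.path(config$output_dir, "exploratory_stage1.csv")
  )
  write.csv(report_table(conf), files$confirmatory_coefficients, row.names = FALSE)
  write.csv(report_fit_stats(conf), files$confirmatory_fit, row.names = FALSE)
  write.csv(report_table(expl$final), files$exploratory_coefficients, row.names = FALSE)
  write.csv(report_fit_stats(expl$final), files$exploratory_fit, row.names = FALSE)
  stage1 <- do.call(rbind, lapply(names(expl$stage1), function(tp) {
    do.call(rbind, lapply(names(expl$stage1[[tp]]), function(ins) {
      cbind(type = tp, instrument = ins,
            expl$stage1[[tp]][[ins]]$coef_table, stringsAsFactors = FALSE)
    }))
  }))
  write.csv(stage1, files$stage1_coefficients, row.names = FALSE)
  for (ins in names(conf$fits)) {
    fn <- file.path(config$output_dir,
                    paste0("calibration_confirmatory_", gsub("[^A-Za-z0-9]", "", ins), ".csv"))
    write.csv(calibration_pairs(conf$fits[[ins]]), fn, row.names = FALSE)
    files[[paste0("calibration_", ins)]] <- fn
  }
  message(sprintf("predict: %d instruments; exploratory selected skills {%s}",
                  length(conf$fits), paste(expl$selected_skills, collapse = ",")))
  write_manifest(config, "predict", files,
                 extra = list(selected_skills = expl$selected_skills))
  invisible(list(confirmatory = conf, exploratory = expl, scores = scores,
                 files = files))
}
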