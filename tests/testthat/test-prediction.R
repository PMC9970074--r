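# Competence prediction: predictor assembly, Bayesian regression contracts,
# confirmatory priors, the exploratory two-stage procedure, calibration.

# small synthetic predictor table with a known linear signal
toy_table <- function(n = 24, noise_sd = 0, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n, 3, 0.5); x2 <- rnorm(n, 1, 0.4); x3 <- rnorm(n, 0.5, 0.3)
  y <- 10 + 8 * x1 - 6 * x2 + rnorm(n, 0, noise_sd)
  tab <- data.frame(physician_id = sprintf("P%02d", 1:n),
                    activation_skill_1 = x1, instrength_skill_1 = x2,
                    outstrength_skill_1 = x3, OBS = y,
                    stringsAsFactors = FALSE)
  attr(tab, "predictors") <- c("activation_skill_1", "instrength_skill_1",
                               "outstrength_skill_1")
  attr(tab, "instruments") <- "OBS"
  tab
}

test_that("predictor tables have deterministic skill-major, type-minor columns", {
  nets <- fix_networks()
  tab <- assemble_predictors(nets, skills = c(1, 6, 7), scores = fix_scores())
  expect_equal(attr(tab, "predictors"), c(
    "activation_skill_1", "instrength_skill_1", "outstrength_skill_1",
    "activation_skill_6", "instrength_skill_6", "outstrength_skill_6",
    "activation_skill_7", "instrength_skill_7", "outstrength_skill_7"
  ))
  expect_equal(length(attr(tab, "predictors")), 9)
  tab2 <- assemble_predictors(nets, skills = c(1, 3, 4, 6))
  expect_equal(length(attr(tab2, "predictors")), 12)
  tab0 <- assemble_predictors(nets, skills = integer(0))
  expect_equal(length(attr(tab0, "predictors")), 0)
  # values are copied from the networks
  expect_equal(tab$activation_skill_6[tab$physician_id == "P01"],
               unname(nets[["P01"]]$activation[6]))
  expect_equal(tab$outstrength_skill_7[tab$physician_id == "P03"],
               unname(nets[["P03"]]$outstrength[7]))
  # response columns align by physician, NA where unscored
  sc <- fix_scores()
  sc <- sc[!(sc$instrument == "OPTION-5" & sc$physician_id == "P02"), ]
  tab3 <- assemble_predictors(nets, skills = 1, scores = sc)
  expect_true(is.na(tab3[["OPTION-5"]][tab3$physician_id == "P02"]))
})

test_that("a noiseless linear signal is fit essentially perfectly", {
  fit <- fit_prediction(toy_table(noise_sd = 0), "OBS", mcmc = light_mcmc(201))
  expect_gte(fit$R[1], 0.999)
  ct <- fit$coef_table
  expect_true(ct$significant[ct$predictor == "activation_skill_1"])
  expect_true(ct$significant[ct$predictor == "instrength_skill_1"])
  expect_equal(ct$estimate[ct$predictor == "activation_skill_1"], 8,
               tolerance = 0.05)
  cp <- calibration_pairs(fit)
  expect_equal(nrow(cp), fit$n)
  expect_lt(max(abs(cp$predicted - cp$observed)), 0.5)
})

test_that("significance flags, CIs and R/R2 draws are internally coherent", {
  fit <- fit_prediction(toy_table(noise_sd = 5, seed = 3), "OBS",
                        mcmc = light_mcmc(202))
  ct <- fit$coef_table
  expect_equal(ct$significant, ct$ci_low > 0 | ct$ci_high < 0)
  expect_true(all(ct$ci_low <= ct$estimate & ct$estimate <= ct$ci_high))
  expect_identical(fit$R2_draws, fit$R_draws^2)
  expect_equal(fit$R[1], median(fit$R_draws))
  expect_equal(fit$R2[1], median(fit$R2_draws))
  expect_true(all(fit$R_draws >= 0 & fit$R_draws <= 1))
})

test_that("degenerate designs are refused with informative errors", {
  tab <- toy_table(n = 4)
  expect_error(fit_prediction(tab, "OBS", mcmc = light_mcmc(203)), "small-n")
  tab2 <- toy_table(n = 30, noise_sd = 1)
  tab2$outstrength_skill_1 <- 2 * tab2$activation_skill_1  # collinear
  expect_warning(
    fit_prediction(tab2, "OBS", mcmc = light_mcmc(204)),
    "rank-deficient.*outstrength_skill_1"
  )
  # a constant (all-zero strength) column is surfaced the same way but the
  # fit proceeds and the unidentified coefficient is never significant
  tab3 <- toy_table(n = 30, noise_sd = 1, seed = 8)
  tab3$outstrength_skill_1 <- 0
  fit3 <- suppressWarnings(fit_prediction(tab3, "OBS", mcmc = light_mcmc(214)))
  ct3 <- fit3$coef_table
  expect_false(ct3$significant[ct3$predictor == "outstrength_skill_1"])
})

test_that("dominant priors pull posterior means to the prior means", {
  tab <- toy_table(n = 30, noise_sd = 2, seed = 5)
  target <- c(1, -1, 0.5)
  fit <- fit_prediction(tab, "OBS",
                        priors = prior_spec(slope_mean = target,
                                            slope_sd = 1e-4,
                                            intercept_sd = 100,
                                            autoscale = FALSE),
                        mcmc = light_mcmc(205))
  est <- coef(fit)[-1]
  expect_equal(unname(est), target, tolerance = 1e-2)
})

test_that("confirmatory model uses the fixed skill set and file priors", {
  nets <- fix_networks()
  sc <- fix_scores()
  prior_path <- system.file("extdata", "synthetic-confirmatory-priors.yaml",
                            package = "sdmnet")
  rep <- confirmatory_model(nets, sc, prior_file = prior_path,
                            mcmc = light_mcmc(206))
  expect_s3_class(rep, "sdm_prediction_report")
  expect_equal(rep$skills, c(1, 6, 7))
  expect_equal(length(rep$predictors), 9)
  expect_setequal(names(rep$fits), c("OPTION-12", "OPTION-5", "4HCS"))
  tb <- report_table(rep)
  # per instrument: intercept + 9 predictor rows
  expect_equal(nrow(tb), 3 * 10)
  expect_equal(sum(tb$predictor == "(Intercept)"), 3)
  fs <- report_fit_stats(rep)
  expect_true(all(fs$R >= 0 & fs$R <= 1))
  expect_true(all(fs$R2 <= fs$R))
  # missing prior file falls back with a warning
  expect_warning(
    confirmatory_model(nets, sc[sc$instrument == "OPTION-5", ],
                       mcmc = light_mcmc(207)),
    "weakly informative"
  )
})

test_that("tight file priors shrink confirmatory estimates toward the prior means", {
  nets <- fix_networks()
  sc <- fix_scores()
  sc <- sc[sc$instrument == "OPTION-5", ]
  spec <- list("OPTION-5" = list(
    intercept = list(mean = 50, sd = 1e-3),
    activation_skill_6 = list(mean = 7, sd = 1e-4)
  ))
  attr(spec, "provenance") <- "file"
  rep <- confirmatory_model(nets, sc, prior_file = spec, mcmc = light_mcmc(208))
  ct <- rep$fits[["OPTION-5"]]$coef_table
  expect_equal(ct$estimate[ct$predictor == "activation_skill_6"], 7,
               tolerance = 1e-2)
  expect_equal(ct$estimate[ct$predictor == "(Intercept)"], 50, tolerance = 0.1)
})

test_that("exploratory selection finds a strong driver skill and reports 3 parameters per selected skill", {
  # responses driven only by skill 6 activation, strong signal
  nets <- fix_networks()
  tabA <- assemble_predictors(nets, skills = 1:9, types = "activation")
  set.seed(209)
  y <- 10 + 25 * tabA$activation_skill_6 + rnorm(nrow(tabA), 0, 1)
  sc <- data.frame(physician_id = tabA$physician_id, instrument = "OBS",
                   score = pmin(pmax(y, 0), 100), stringsAsFactors = FALSE)
  expl <- exploratory_procedure(nets, sc, mcmc = light_mcmc(210))
  expect_true(6 %in% expl$selected_skills)
  expect_equal(length(expl$final$predictors), 3 * length(expl$selected_skills))
  expect_equal(names(expl$stage1), c("activation", "instrength", "outstrength"))
  expect_equal(length(expl$stage1$activation), 1) # one instrument
})

test_that("an empty stage-1 selection yields intercept-only final models", {
  nets <- fix_networks()
  sc <- fix_scores()[fix_scores()$instrument == "4HCS", ]
  # priors concentrated at zero make every stage-1 slope non-significant
  null_priors <- prior_spec(slope_sd = 1e-6, intercept_sd = 100, autoscale = FALSE)
  expl <- exploratory_procedure(nets, sc, priors = null_priors,
                                mcmc = light_mcmc(211))
  expect_equal(expl$selected_skills, integer(0))
  expect_equal(length(expl$final$predictors), 0)
  f <- expl$final$fits[["4HCS"]]
  expect_equal(nrow(f$coef_table), 1)
  expect_equal(f$coef_table$predictor, "(Intercept)")
  expect_equal(f$R[1], 0)
})

test_that("calibration pairs round-trip through CSV and carry a smoother", {
  fit <- fit_prediction(toy_table(noise_sd = 3, seed = 7), "OBS",
                        mcmc = light_mcmc(212))
  cp <- calibration_pairs(fit, smooth = TRUE)
  expect_equal(nrow(cp), fit$n)
  expect_false(is.null(attr(cp, "smoother")))
  path <- tempfile(fileext = ".csv")
  write.csv(cp, path, row.names = FALSE)
  cp2 <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(cp2$predicted, cp$predicted)
  expect_equal(cp2$observed, cp$observed)
})
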