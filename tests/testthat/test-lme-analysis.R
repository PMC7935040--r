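test_that("the model grammar parses the canonical specifications", {
  m1 <- model_spec_one("ac")
  expect_identical(m1$rhs, "tiv_z + region + strength_z * rgm_z")
  m2 <- model_spec_two("mc")
  expect_identical(m2$rhs,
                   "tiv_z + region * strength_z + region * rgm_z")
  # unicode crossing and plain interactions
  expect_identical(model_spec("ac", c("degree × rgm"))$rhs,
                   "strength_z * rgm_z")
  expect_identical(model_spec("ac", c("degree:rgm"))$rhs,
                   "strength_z:rgm_z")
  expect_error(model_spec("ac", c("volume")), "unknown variable")
  expect_error(model_spec("ac", character(0)), "non-empty")
})

test_that("fit_lme recovers planted coefficients with sane Wald inference", {
  cfg <- lme_fixture_config(true_betas = c(degree = 0.36, rgm = 0.44,
                                           `degree:rgm` = 0.04),
                            n_subjects = 40, n_regions = 40, seed = 101)
  tab <- generate_lme_fixture(cfg)
  fit <- expect_silent_fit(fit_lme(tab, model_spec_one("ac"), "ML"))
  expect_s3_class(fit, "model_result")
  expect_true(fit$converged)
  expect_identical(fit$n_obs, 1600L)
  co <- fit$coefficients
  expect_true(all(co$ci_low <= co$beta & co$beta <= co$ci_high))
  get <- function(term) co[co$term == term, ]
  expect_equal(get("strength_z")$beta, 0.36, tolerance = 0.12)
  expect_equal(get("rgm_z")$beta, 0.44, tolerance = 0.12)
  # strongly supported terms are significant
  expect_lt(get("strength_z")$p_raw, 1e-10)
  expect_lt(get("rgm_z")$p_raw, 1e-10)
})

test_that("fit_lme enforces its contracts", {
  cfg <- lme_fixture_config(n_subjects = 1, n_regions = 10, seed = 1)
  tab1 <- generate_lme_fixture(cfg)
  expect_error(fit_lme(tab1, model_spec_one("ac"), "ML"),
               ">= 2 participants")
  # rank-deficient designs name the aliased columns
  tab <- generate_lme_fixture(lme_fixture_config(n_subjects = 6,
                                                 n_regions = 8, seed = 2))
  tab$rgm_z <- tab$strength_z
  expect_error(fit_lme(tab, model_spec("ac", c("degree", "rgm")), "ML"),
               "rank deficient.*rgm_z")
  # unscaled tables are rejected
  raw <- tab
  raw$ac_z <- NULL
  expect_error(fit_lme(raw, model_spec_one("ac")), "scaled view")
})

test_that("estimates are invariant to row shuffling", {
  tab <- generate_lme_fixture(lme_fixture_config(n_subjects = 10,
                                                 n_regions = 12, seed = 3))
  f1 <- expect_silent_fit(fit_lme(tab, model_spec_one("ac"), "ML"))
  set.seed(4)
  shuf <- tab[sample(nrow(tab)), ]
  class(shuf) <- class(tab)
  attr(shuf, "scaling") <- attr(tab, "scaling")
  f2 <- expect_silent_fit(fit_lme(shuf, model_spec_one("ac"), "ML"))
  expect_equal(f1$coefficients$beta, f2$coefficients$beta,
               tolerance = 1e-8)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-8)
})

test_that("likelihood ratios of nested fits are non-negative", {
  for (seed in 1:5) {
    tab <- generate_lme_fixture(lme_fixture_config(
      n_subjects = 8, n_regions = 10, seed = 500 + seed))
    f0 <- expect_silent_fit(fit_lme(tab, model_spec("ac", c("degree")),
                                    "ML"))
    f1 <- expect_silent_fit(fit_lme(tab, model_spec("ac", c("degree",
                                                            "rgm")), "ML"))
    expect_gte(f1$log_likelihood - f0$log_likelihood, -1e-6)
  }
})

test_that("stepwise selection keeps strong terms and traces decisions", {
  # interaction planted at ~10x its standard error
  tab <- generate_lme_fixture(lme_fixture_config(
    true_betas = c(degree = 0.36, rgm = 0.44, `degree:rgm` = 0.5),
    n_subjects = 20, n_regions = 20, seed = 11))
  sel <- expect_silent_fit(
    stepwise_select(tab, model_spec("ac", c("tiv", "degree", "rgm")),
                    c("degree:rgm")))
  expect_true(sel$trace$kept[1])
  expect_lt(sel$trace$p[1], 1e-6)
  expect_true("degree:rgm" %in% sel$spec$fixed_terms)
  # duplicate candidate adds no parameters
  expect_error(
    expect_silent_fit(
      stepwise_select(tab, model_spec("ac", c("tiv", "degree", "rgm")),
                      c("rgm"))),
    "no parameters")
  expect_error(stepwise_select(tab, model_spec_one("ac"), character(0)),
               "non-empty")
})

test_that("regional effects extract per-region slopes with Bonferroni", {
  co <- tiny_cohort(n_subjects = 8, n_regions = 12, seed = 51)
  profs <- lapply(co$connectomes, control_profile)
  tab <- center_and_scale(assemble(profs, co$volumetrics, co$atlas))
  m2 <- expect_silent_fit(fit_lme(tab, model_spec_two("ac"), "REML"))
  for (fam in c("rgm", "degree")) {
    re <- regional_effects(m2, fam)
    expect_identical(nrow(re), 12L)
    expect_setequal(re$region, co$atlas$region_name)
    expect_equal(re$p_bonf, pmin(1, re$p_raw * 12))
    expect_true(all(re$ci_low <= re$beta & re$beta <= re$ci_high))
  }
  # model 1 has no regional interaction family
  m1 <- expect_silent_fit(fit_lme(tab, model_spec_one("ac"), "REML"))
  expect_error(regional_effects(m1, "rgm"), "model 2")
})

test_that("a planted regional interaction is detected as the top effect", {
  # build a fixture with an explicit region x rgm effect in one region
  set.seed(61)
  ns <- 25; nr <- 10
  subj <- sprintf("s%02d", seq_len(ns))
  regs <- sprintf("r%02d", seq_len(nr))
  d <- expand.grid(subject_id = subj, region_name = regs,
                   stringsAsFactors = FALSE)
  d$strength_z <- rnorm(nrow(d))
  d$rgm_z <- rnorm(nrow(d))
  d$tiv_z <- rnorm(ns)[match(d$subject_id, subj)]
  slope <- ifelse(d$region_name == "r07", 1.5, 0.2)
  d$ac_z <- slope * d$rgm_z + 0.3 * d$strength_z +
    rnorm(ns, 0, 0.3)[match(d$subject_id, subj)] + rnorm(nrow(d), 0, 0.5)
  d$mc_z <- rnorm(nrow(d))
  d$ac <- d$ac_z; d$mc <- d$mc_z; d$strength <- d$strength_z
  d$rgm <- d$rgm_z; d$tiv <- d$tiv_z
  class(d) <- c("study_table", "data.frame")
  attr(d, "scaling") <- list(pre_standardized = TRUE)
  m2 <- expect_silent_fit(fit_lme(d, model_spec_two("ac"), "REML"))
  re <- regional_effects(m2, "rgm")
  expect_identical(re$region[which.max(re$beta)], "r07")
  expect_lt(re$p_bonf[re$region == "r07"], 0.05)
})

test_that("model results serialize to JSON and TSV", {
  tab <- generate_lme_fixture(lme_fixture_config(n_subjects = 8,
                                                 n_regions = 10, seed = 71))
  fit <- expect_silent_fit(fit_lme(tab, model_spec_one("ac"), "REML"))
  js <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_model_result(fit, js, tsv)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(back$fit_method, "REML")
  expect_equal(back$log_likelihood, fit$log_likelihood)
  expect_identical(nrow(read.delim(tsv)), nrow(fit$coefficients))
})
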