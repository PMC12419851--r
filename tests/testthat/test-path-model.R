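test_that("standardization is exact, idempotent, and leaves binaries alone", {
  ch <- small_cohort(60, seed = 2)
  ch$AGE <- c(0, 2, 4, rep(2, 57))
  std <- standardize_continuous(ch, columns = "AGE")
  # sample-SD convention (denominator n - 1)
  expect_equal(std$AGE[1:3],
               (c(0, 2, 4) - mean(ch$AGE)) / sd(ch$AGE))
  std2 <- standardize_continuous(standardize_continuous(ch))
  expect_equal(std2$GrimAgeEAA_z,
               standardize_continuous(ch)$GrimAgeEAA_z, tolerance = 1e-12)
  expect_equal(std2$SEX, ch$SEX)
  bad <- ch
  bad$TELO_MEAN_z <- 0
  expect_error(standardize_continuous(bad), "TELO_MEAN_z")

  # plain three-point check of the convention
  toy <- data.frame(AGE = c(0, 2, 4))
  expect_equal(standardize_continuous(toy, "AGE")$AGE, c(-1, 0, 1))
})

test_that("linear node fits are exact WLS with sane designs", {
  ch <- standardize_continuous(small_cohort(800, seed = 14))
  est <- fit_linear_node("GrimAgeEAA", c("DunedinPoAm", "PhenoAgeEAA", "SEX"),
                         ch)
  ref <- lm(GrimAgeEAA_z ~ DunedinPoAm_z + PhenoAgeEAA_z + SEX, data = ch)
  expect_equal(est$beta, unname(coef(ref)[-1]), tolerance = 1e-10)
  expect_equal(est$se, unname(sqrt(diag(vcov(ref)))[-1]), tolerance = 1e-10)

  # unit weights: weighted and unweighted fits coincide
  d1 <- survey_design(rep(1, nrow(ch)))
  est2 <- fit_linear_node("GrimAgeEAA", c("DunedinPoAm", "PhenoAgeEAA", "SEX"),
                          ch, d1, "model2_weighted")
  expect_equal(est2$beta, est$beta, tolerance = 1e-10)
  # self-representing subjects: robust SE close to classical
  expect_lt(max(abs(est2$se / est$se - 1)), 0.15)
})

test_that("the Weibull node matches survreg and the exponential closed form", {
  ch <- standardize_continuous(small_cohort(2000, seed = 6))
  wf <- fit_weibull_node(ch$time, ch$DIED, c("AGE", "GrimAgeEAA"), ch)
  sr <- survival::survreg(survival::Surv(time, DIED) ~ AGE + GrimAgeEAA_z,
                          data = ch, dist = "weibull")
  expect_equal(wf$shape, 1 / sr$scale, tolerance = 1e-5)
  expect_equal(wf$estimates$beta, unname(-coef(sr)[-1] / sr$scale),
               tolerance = 1e-5)

  # exponential data with a binary covariate: closed-form rate-ratio MLE
  set.seed(44)
  n <- 4000
  x <- rbinom(n, 1, 0.5)
  beta <- 0.6
  t0 <- rexp(n, rate = 0.08 * exp(beta * x))
  cens <- 10
  time <- pmin(t0, cens); ev <- as.integer(t0 < cens)
  dfx <- data.frame(x = x)
  wf2 <- agingnet:::weibull_ph_fit(time, ev, cbind(x = x))
  lnhr_closed <- log((sum(ev[x == 1]) / sum(time[x == 1])) /
                       (sum(ev[x == 0]) / sum(time[x == 0])))
  expect_equal(unname(wf2$beta), lnhr_closed, tolerance = 0.02)
  expect_lt(abs(wf2$shape - 1), 0.05)

  # a covariate independent of the hazard gets a near-zero LnHR
  ch$noise <- rnorm(nrow(ch))
  wf3 <- agingnet:::weibull_ph_fit(ch$time, ch$DIED, cbind(noise = ch$noise))
  expect_lt(abs(wf3$beta), 3 * sqrt(diag(wf3$vcov))[3])
  expect_error(agingnet:::weibull_ph_fit(ch$time, rep(0L, nrow(ch)),
                                         cbind(x = ch$noise)), "event")
})

test_that("discrete-hazard node handles degenerate inputs", {
  ch <- small_cohort(600, seed = 9)
  pp <- to_person_period(standardize_continuous(ch), 2)
  est <- fit_discrete_hazard_node(pp, c("AGE", "GrimAgeEAA"))
  expect_equal(est$child, rep("DIED", 2))
  expect_true(all(est$se > 0))
  ppc <- pp
  ppc$death_k <- 0L
  expect_error(fit_discrete_hazard_node(ppc, "AGE"), "events")
  no_per <- pp[, !grepl("^PER_", names(pp))]
  expect_error(fit_discrete_hazard_node(no_per, "AGE"), "dummies")
})

test_that("the assembled path model covers every arc deterministically", {
  cfg <- nhanes_cfg()
  ch <- small_cohort(1200, seed = 33)
  pm <- fit_path_model(cfg$model, ch)
  expect_s3_class(pm, "path_model_result")
  expect_equal(nrow(pm$estimates), 19L)
  expect_true(all(pm$estimates$se > 0))
  expect_true(all(pm$estimates$p > 0 & pm$estimates$p <= 1))
  expect_gt(pm$weibull_shape_hat, 0)
  # rerun gives identical output
  pm2 <- fit_path_model(cfg$model, ch)
  expect_identical(pm$estimates, pm2$estimates)

  empty <- data.frame(parent = character(0), child = character(0))
  pm3 <- fit_path_model(empty, ch)
  expect_equal(nrow(pm3$estimates), 0L)
})

test_that("weights rescale-invariance and model1/model2 agreement hold", {
  ch <- small_cohort(900, seed = 41)
  ch$weight <- rlnorm(nrow(ch), 0, 0.4)
  ch$psu <- rep_len(1:25, nrow(ch))
  cfg <- nhanes_cfg()
  d1 <- survey_design(ch$weight, ch$psu)
  d2 <- survey_design(7 * ch$weight, ch$psu)
  pm1 <- fit_path_model(cfg$model, ch, d1, "model2_weighted")
  pm2 <- fit_path_model(cfg$model, ch, d2, "model2_weighted")
  expect_equal(pm1$estimates$beta, pm2$estimates$beta, tolerance = 1e-8)
  expect_equal(pm1$estimates$se, pm2$estimates$se, tolerance = 1e-6)

  # with unit weights the two model variants give the same point estimates
  chu <- ch
  chu$weight <- 1
  m1 <- fit_path_model(cfg$model, chu, model_tag = "model1_srs")
  m2 <- fit_path_model(cfg$model, chu, model_tag = "model2_weighted")
  expect_equal(m1$estimates$beta, m2$estimates$beta, tolerance = 1e-8)
})

test_that("nominal 95% intervals cover the generating coefficient", {
  cfg <- nhanes_cfg()
  R <- 800
  cover <- logical(R)
  for (r in 1:R) {
    ch <- standardize_continuous(
      generate_cohort(cfg$model, cfg$demographics, seed = 5000 + r))
    f <- fit_linear_node("GrimAgeEAA", c("DunedinPoAm", "PhenoAgeEAA", "SEX"),
                         ch)
    i <- which(f$parent == "SEX")
    cover[r] <- abs(f$beta[i] - (-0.500)) <= 1.96 * f$se[i]
  }
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("indirect effects multiply coefficients with delta-method errors", {
  res <- structure(list(estimates = data.frame(
    parent = c("SEX", "GrimAgeEAA", "AGE"),
    child = c("GrimAgeEAA", "DIED", "DIED"),
    beta = c(-0.5, 0.421, 0.978),
    se = c(0.026, 0.027, 0.031),
    p = c(0, 0, 0), stringsAsFactors = FALSE),
    weibull_shape_hat = 1.5, model_tag = "model1_srs"),
    class = "path_model_result")
  ie <- indirect_effect(c("SEX", "GrimAgeEAA", "DIED"), res)
  expect_equal(ie$effect, -0.5 * 0.421)
  expect_equal(ie$se,
               sqrt(0.421^2 * 0.026^2 + 0.5^2 * 0.027^2), tolerance = 1e-12)
  # a single arc returns the coefficient itself
  ie2 <- indirect_effect(c("AGE", "DIED"), res)
  expect_equal(ie2$effect, 0.978)
  expect_equal(ie2$se, 0.031)
  expect_error(indirect_effect(c("AGE", "GrimAgeEAA", "DIED"), res),
               "no fitted arc")
  # any zero coefficient nulls the product
  res$estimates$beta[1] <- 0
  expect_equal(indirect_effect(c("SEX", "GrimAgeEAA", "DIED"), res)$effect, 0)
})
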