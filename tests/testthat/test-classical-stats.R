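test_that("correlation matrices are symmetric with unit diagonal", {
  ch <- small_cohort(200, seed = 3)
  r <- pearson_matrix(ch)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 6))
  df <- data.frame(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), cst = 1)
  expect_warning(r2 <- pearson_matrix(df, c("a", "b", "cst")), "cst")
  expect_equal(r2["a", "b"], -1)
  expect_true(is.na(r2["a", "cst"]))
})

test_that("observed correlations agree with the model-implied moments", {
  cfg <- nhanes_cfg()
  demo <- cfg$demographics
  demo$n <- 5000L
  ch <- generate_cohort(cfg$model, demo, seed = 12)
  r <- pearson_matrix(ch)
  ic <- implied_covariance(cfg$model, cfg$demographics)
  expect_lt(abs(r["GrimAgeEAA_z", "DunedinPoAm_z"] -
                  ic$cov["GrimAgeEAA", "DunedinPoAm"]), 0.05)
})

test_that("tertile assignment is rank-invariant with ties going low", {
  t9 <- tertile_assign(1:9)
  expect_equal(as.character(t9), rep(c("T1", "T2", "T3"), each = 3))
  # monotone transforms preserve the labels
  expect_equal(tertile_assign(exp(1:9)), t9)
  # heavy ties at a cut fall into the lower group, matching the quantile rule
  v <- c(1, 2, 3, 3, 3, 5, 6, 7, 9)
  q <- quantile(v, c(1, 2) / 3, names = FALSE)
  expected <- ifelse(v <= q[1], "T1", ifelse(v <= q[2], "T2", "T3"))
  expect_equal(as.character(tertile_assign(v)), expected)
  expect_error(tertile_assign(rep(1, 10)), "degenerate")
})

test_that("the product-limit curve matches hand computation and weight scaling", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$curves$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$curves$survival[km$curves$time == 2], 0.5)

  ch <- small_cohort(300, seed = 19)
  grp <- tertile_assign(ch$GrimAgeEAA_z)
  w <- runif(300, 0.5, 2)
  k1 <- km_curve(ch$time, ch$DIED, grp, w)
  k2 <- km_curve(ch$time, ch$DIED, grp, 2 * w)
  expect_equal(k1$curves$survival, k2$curves$survival, tolerance = 1e-12)
  # no events: survival stays at one
  k3 <- km_curve(c(2, 3, 4), c(0, 0, 0))
  expect_true(all(k3$curves$survival == 1))
  # monotone non-increasing within group, bounded by [0, 1]
  for (g in levels(grp)) {
    s <- k1$curves$survival[k1$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("log-rank matches the hand oracle and survdiff, and needs 2 groups", {
  tm <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 1); gr <- c("A", "A", "B", "B")
  lr <- logrank_test(tm, ev, gr)
  expect_equal(lr$chisq, oracle_logrank(tm, ev, gr), tolerance = 1e-10)
  expect_equal(lr$df, 1L)

  # identical groups give a zero statistic
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 0, 1, 0), c("A", "A", "B", "B"))
  expect_lt(lr0$chisq, 1e-10)

  ch <- small_cohort(250, seed = 23)
  grp <- tertile_assign(ch$TELO_MEAN_z)
  lr1 <- logrank_test(ch$time, ch$DIED, grp)
  sd1 <- survival::survdiff(survival::Surv(time, DIED) ~ grp,
                            data = data.frame(time = ch$time,
                                              DIED = ch$DIED, grp = grp))
  expect_equal(lr1$chisq, sd1$chisq, tolerance = 1e-8)
  # weighted statistic agrees with the loop oracle
  w <- runif(250, 0.5, 3)
  g2 <- ifelse(grp == "T1", "lo", "hi")
  lr2 <- logrank_test(ch$time, ch$DIED, g2, w)
  expect_equal(lr2$chisq, oracle_logrank(ch$time, ch$DIED, g2, w),
               tolerance = 1e-8)
  expect_error(logrank_test(tm, ev, rep("A", 4)), "two groups")
})

test_that("Cox fits maximize the partial likelihood (grid oracle)", {
  tm <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  cx <- cox_fit(tm, ev, data.frame(x = x))
  # no ties: Efron = Breslow = exact partial likelihood; 1-D grid search
  pl <- function(b) {
    risk <- exp(b * x)
    sum(b * x[ev == 1] - log(rev(cumsum(rev(risk)))[ev == 1]))
  }
  grid <- seq(-3, 3, by = 5e-4)
  bhat <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(cx$coefficients$lnhr, bhat, tolerance = 1e-3)
  expect_true(cx$coefficients$lower < cx$coefficients$lnhr &
                cx$coefficients$lnhr < cx$coefficients$upper)

  # a null covariate stays near zero
  ch <- small_cohort(800, seed = 29)
  ch$noise <- rnorm(800)
  cx2 <- cox_fit(ch$time, ch$DIED, ch[, c("noise", "AGE")])
  i <- cx2$coefficients$term == "noise"
  expect_lt(abs(cx2$coefficients$lnhr[i]), 3 * cx2$coefficients$se[i])
})

test_that("Cox and Weibull log hazard ratios agree on proportional-hazards data", {
  cfg <- nhanes_cfg()
  demo <- cfg$demographics
  demo$n <- 5000L
  ch <- standardize_continuous(generate_cohort(cfg$model, demo, seed = 55))
  wb <- fit_weibull_node(ch$time, ch$DIED, c("AGE", "GrimAgeEAA"), ch)
  cx <- cox_fit(ch$time, ch$DIED, ch[, c("AGE", "GrimAgeEAA_z")])
  expect_lt(max(abs(cx$coefficients$lnhr / wb$estimates$beta - 1)), 0.05)
})

test_that("Schoenfeld diagnostics flag only genuine non-proportionality", {
  # strongly time-varying effect: hazard sign flips at the median time
  set.seed(61)
  hits <- 0L
  for (i in 1:40) {
    n <- 400
    x <- rnorm(n)
    u <- runif(n)
    # piecewise exponential: rate exp(x) before t = 1, exp(-x) after
    r1 <- 0.7 * exp(x); r2 <- 0.7 * exp(-x)
    t1 <- -log(u) / r1
    tt <- ifelse(t1 < 1, t1, 1 + (t1 - 1) * r1 / r2)
    time <- pmin(tt, 4); ev <- as.integer(tt < 4)
    cx <- cox_fit(time, ev, data.frame(x = x))
    sch <- schoenfeld_test(cx)
    if (sch$p[sch$term == "x"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 33L)  # > 80% rejection under a flipped effect

  # single-covariate model: the global test is the covariate test
  ch <- small_cohort(500, seed = 31)
  cx <- cox_fit(ch$time, ch$DIED, ch[, "GrimAgeEAA_z", drop = FALSE])
  sch <- schoenfeld_test(cx)
  expect_equal(sch$p[sch$term == "GLOBAL"], sch$p[sch$term != "GLOBAL"],
               tolerance = 1e-9)
})

test_that("concordance equals brute-force pair counting", {
  expect_equal(harrell_c(c(4, 3, 2, 1), c(1, 2, 3, 4), rep(1, 4)), 1.0)
  expect_equal(harrell_c(rep(1, 6), c(1, 2, 3, 4, 5, 6), rep(1, 6)), 0.5)
  set.seed(90)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    time <- round(runif(n, 0.1, 10), 3)
    ev <- rbinom(n, 1, 0.7)
    lp <- round(rnorm(n), 1)  # rounding forces tied predictions
    if (sum(ev) == 0) ev[1] <- 1L
    expect_equal(harrell_c(lp, time, ev), brute_force_c(lp, time, ev),
                 tolerance = 1e-12)
  }
  expect_error(harrell_c(c(1, 2), c(3, 3), c(0, 0)), "comparable")
})

test_that("age-residualization removes confounding by construction", {
  ch <- small_cohort(1500, seed = 35)
  res <- residualize(ch$DunedinPoAm_z, ch$AGE)
  expect_lt(abs(mean(res)), 1e-10)
  expect_lt(abs(cor(res, ch$AGE)), 1e-10)
  expect_error(residualize(ch$DunedinPoAm_z, rep(50, nrow(ch))), "constant")

  # synthetic age confounding: x carries an age signal but no direct effect
  set.seed(3)
  n <- 3000
  age <- rnorm(n)
  x <- 0.8 * age + rnorm(n)
  t0 <- rexp(n, 0.1 * exp(0.8 * age))
  time <- pmin(t0, 15); ev <- as.integer(t0 < 15)
  raw <- cox_fit(time, ev, data.frame(x = x))$coefficients$lnhr
  adj <- cox_fit(time, ev, data.frame(x = residualize(x, age)))
  expect_lt(abs(adj$coefficients$lnhr), abs(raw))
})

test_that("forced covariates survive every LASSO mode and the true clock wins", {
  ch <- small_cohort(2522, seed = 47)
  las <- lasso_paths(ch, half_sample_seed = 47)
  expect_true(las$chosen_mode %in% c("cv", "min_bic", "adaptive"))
  expect_true(all(c("AGE", "SEX") %in% names(las$full_coefficients)))
  expect_true(is.finite(las$half_sample$fit_half_r2))

  # only the Hannum clock feeds telomere length in the generating model
  hits <- integer(0)
  other <- integer(0)
  for (r in 1:30) {
    chr <- small_cohort(2522, seed = 400 + r)
    sel <- lasso_paths(chr, half_sample_seed = r)$selected
    hits <- c(hits, "HannumAgeEAA_z" %in% sel)
    other <- c(other, length(setdiff(sel, "HannumAgeEAA_z")))
  }
  expect_gte(mean(hits), 0.85)
  expect_lte(mean(other > 0), 0.35)
})
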