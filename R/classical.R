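#' Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations over the requested columns.
#' Zero-variance columns yield `NA` entries and a warning naming them.
#'
#' @param cohort a data.frame.
#' @param columns columns to correlate; defaults to the biomarker z-scores.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(cohort, columns = paste0(BIOMARKER_NODES, "_z")) {
  X <- as.matrix(cohort[, columns, drop = FALSE])
  if (sum(stats::complete.cases(X)) < 3) stopf("need at least 3 complete rows")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0)) {
    warning(sprintf("zero-variance column(s): %s",
                    paste(columns[sds == 0], collapse = ", ")), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  diag(r)[sds > 0] <- 1
  r
}

#' Tertile group assignment
#'
#' Unweighted sample tertiles; values tied with a cut point fall in the
#' lower group. Labels are `T1`, `T2`, `T3`.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @return factor of group labels.
#' @export
tertile_assign <- function(values) {
  if (length(unique(values)) < 3L) {
    stopf("degenerate distribution: fewer than 3 distinct values")
  }
  q <- stats::quantile(values, c(1, 2) / 3, names = FALSE, type = 7)
  lab <- ifelse(values <= q[1], "T1", ifelse(values <= q[2], "T2", "T3"))
  factor(lab, levels = c("T1", "T2", "T3"))
}

#' Weighted Kaplan-Meier curves by group
#'
#' Weighted product-limit estimator per group. With unit weights and no
#' censoring this reduces to the empirical survival function; curves are
#' invariant to rescaling all weights.
#'
#' @param time,event follow-up times (> 0) and 0/1 event indicators.
#' @param group group labels (one group is fine).
#' @param weights positive sampling weights; defaults to 1.
#' @return object of class `surv_fit_result`: tidy data.frame `curves` with
#'   columns `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_curve <- function(time, event, group = rep("all", length(time)),
                     weights = NULL) {
  if (any(time <= 0)) stopf("times must be > 0")
  weights <- weights %||% rep(1, length(time))
  group <- as.factor(group)
  if (any(table(group) == 0)) stopf("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           weights = weights)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(group)[1], length(sm$time)) else {
    sub("^group=", "", as.character(sm$strata))
  }
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       stringsAsFactors = FALSE)
  structure(list(curves = curves), class = "surv_fit_result")
}

#' Weighted log-rank test
#'
#' Score-test form of the log-rank statistic with sampling weights: at each
#' event time the weighted observed and expected death counts are
#' accumulated per group, with the (weighted) hypergeometric variance.
#' With unit weights this is the classical log-rank test.
#'
#' @param time,event follow-up and 0/1 event indicator.
#' @param group at least two groups.
#' @param weights positive weights; defaults to 1.
#' @return list with `chisq`, `df`, `p`, and the per-group
#'   `observed` / `expected` weighted counts.
#' @export
logrank_test <- function(time, event, group, weights = NULL) {
  weights <- weights %||% rep(1, length(time))
  weights <- weights / mean(weights)  # rescale-invariant
  group <- as.factor(group)
  G <- nlevels(group)
  if (G < 2L) stopf("log-rank needs at least two groups")
  times <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(G), levels(group))
  V <- matrix(0, G, G, dimnames = list(levels(group), levels(group)))
  for (tt in times) {
    at <- time >= tt
    Y <- sum(weights[at])
    if (Y <= 0) next
    d <- sum(weights[at & time == tt & event == 1])
    if (d == 0) next
    Yg <- vapply(levels(group), function(g) sum(weights[at & group == g]),
                 numeric(1))
    dg <- vapply(levels(group), function(g)
      sum(weights[at & time == tt & event == 1 & group == g]), numeric(1))
    O <- O + dg
    E <- E + d * Yg / Y
    # hypergeometric covariance with weighted totals
    cf <- d * (Y - d) / max(Y - 1, 1e-12)
    Vt <- cf * (diag(Yg / Y, G) - tcrossprod(Yg / Y))
    V <- V + Vt
  }
  om <- (O - E)[-G]
  Vm <- V[-G, -G, drop = FALSE]
  chisq <- drop(t(om) %*% solve(Vm, om))
  df <- G - 1L
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Weighted Cox proportional-hazards fit
#'
#' Weighted partial likelihood via [survival::coxph()] with Efron ties by
#' default; reports log hazard ratios with SEs, 95% CIs, Harrell's C
#' (unweighted), and flags monotone-likelihood (perfect-ranking) fits.
#'
#' @param time,event follow-up and event indicator.
#' @param covariates data.frame or matrix of covariates.
#' @param weights positive weights; defaults to 1.
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `cox_result`: data.frame `coefficients`
#'   (`term`, `lnhr`, `se`, `lower`, `upper`), `concordance`, `ties`,
#'   and the underlying `fit`.
#' @export
cox_fit <- function(time, event, covariates, weights = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(event) < 1) stopf("at least one event is required")
  covariates <- as.data.frame(covariates)
  weights <- weights %||% rep(1, length(time))
  df <- cbind(data.frame(.time = time, .event = event, .w = weights),
              covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  fit <- suppressWarnings(survival::coxph(fml, data = df, weights = .w,
                                          ties = ties, x = TRUE))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf) > 15)) {
    warning("monotone likelihood: a covariate perfectly ranks survival",
            call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  lp <- drop(fit$x %*% cf)
  structure(list(
    coefficients = data.frame(term = names(cf), lnhr = unname(cf),
                              se = unname(se),
                              lower = unname(cf - 1.96 * se),
                              upper = unname(cf + 1.96 * se),
                              p = 2 * stats::pnorm(-abs(unname(cf / se))),
                              stringsAsFactors = FALSE),
    concordance = harrell_c(lp, time, event),
    ties = ties, fit = fit), class = "cox_result")
}

#' Schoenfeld proportional-hazards diagnostic
#'
#' Correlates the scaled Schoenfeld residuals of a fitted Cox model with the
#' (identity-transformed) event times; reports per-covariate and global
#' chi-square p-values via [survival::cox.zph()].
#'
#' @param cox_result a `cox_result` from [cox_fit].
#' @return data.frame with `term`, `chisq`, `df`, `p` (last row `GLOBAL`).
#' @export
schoenfeld_test <- function(cox_result) {
  fit <- cox_result$fit
  if (sum(fit$nevent) < 2) stopf("need at least 2 events")
  z <- survival::cox.zph(fit, transform = "identity", global = TRUE)
  out <- as.data.frame(z$table)
  data.frame(term = rownames(out), chisq = out$chisq, df = out$df,
             p = out$p, stringsAsFactors = FALSE)
}

#' Harrell's concordance for censored survival data
#'
#' Fraction of comparable pairs in which the subject with the higher risk
#' score fails earlier, ties in the score counted 1/2; comparability follows
#' the usual right-censoring rule (the shorter time must be an event).
#'
#' @param linear_predictor risk scores (higher = riskier).
#' @param time,event follow-up and event indicator.
#' @return concordance in `[0, 1]`.
#' @export
harrell_c <- function(linear_predictor, time, event) {
  cc <- survival::concordance(survival::Surv(time, event) ~ linear_predictor,
                              reverse = TRUE)
  counts <- cc$count
  comparable <- counts[["concordant"]] + counts[["discordant"]] +
    counts[["tied.x"]]
  if (comparable <= 0) stopf("no comparable pairs")
  unname((counts[["concordant"]] + 0.5 * counts[["tied.x"]]) / comparable)
}

#' Residualize a biomarker on chronological age
#'
#' OLS residuals of `values` on `age` with intercept; mean zero and exactly
#' orthogonal to age. Used for the age-independent sensitivity analysis of
#' the pace-of-aging measure.
#'
#' @param values numeric vector.
#' @param age chronological ages (not constant).
#' @return residual vector.
#' @export
residualize <- function(values, age) {
  if (length(values) < 3L) stopf("need n >= 3")
  if (stats::sd(age) == 0) stopf("age is constant")
  stats::resid(stats::lm(values ~ age))
}

#' Penalized fit at a fixed penalty value
#'
#' Evaluates the forced-covariate LASSO at one penalty value: the penalized
#' covariates carry the L1 penalty, the forced covariates none. At zero
#' penalty this is ordinary least squares on all covariates; as the penalty
#' grows the penalized coefficients vanish while the forced ones remain fit.
#'
#' @inheritParams lasso_paths
#' @param lambda non-negative penalty value.
#' @return named coefficient vector (including the intercept).
#' @export
lasso_fit <- function(cohort, outcome = "TELO_MEAN_z",
                      penalized = c("HorvathAgeEAA_z", "HannumAgeEAA_z",
                                    "PhenoAgeEAA_z", "GrimAgeEAA_z",
                                    "DunedinPoAm_z"),
                      forced = c("AGE", "SEX", "NHB", "HISP", "OTHER"),
                      lambda) {
  if (lambda < 0) stopf("lambda must be >= 0")
  vars <- c(penalized, forced)
  y <- cohort[[outcome]]
  X <- as.matrix(cohort[, vars, drop = FALSE])
  pf <- c(rep(1, length(penalized)), rep(0, length(forced)))
  # descend the path to the requested penalty for a warm-started exact-ish fit
  lams <- sort(unique(c(exp(seq(log(1e3), log(max(lambda, 1e-4)),
                                length.out = 60)), lambda)),
               decreasing = TRUE)
  gf <- glmnet::glmnet(X, y, penalty.factor = pf, lambda = lams,
                       thresh = 1e-14, maxit = 10^7)
  co <- as.matrix(stats::coef(gf, s = lambda, exact = FALSE))
  stats::setNames(co[, 1], rownames(co))
}

#' LASSO selection of clocks predicting telomere length
#'
#' L1 path on the penalized covariates only, with the exogenous covariates
#' forced (unpenalized). Three penalty-selection modes are computed --
#' 10-fold cross-validation, minimum BIC along the path, and adaptive LASSO
#' with weights `1/|b_ols|` -- and the simplest (fewest selected penalized
#' covariates; ties toward min-BIC) is refit on the full sample. A seeded
#' half-sample protocol (stratified on the event indicator when present)
#' reports out-of-half fit.
#'
#' @param cohort data.frame.
#' @param outcome outcome column (default `TELO_MEAN_z`).
#' @param penalized penalized covariate columns (default the five clocks).
#' @param forced forced (unpenalized) covariate columns.
#' @param half_sample_seed seed for the half-sample split.
#' @param nfolds CV folds.
#' @return object of class `lasso_result`: per-mode selections, the chosen
#'   mode, full-sample coefficients, and the half-sample comparison.
#' @export
lasso_paths <- function(cohort, outcome = "TELO_MEAN_z",
                        penalized = c("HorvathAgeEAA_z", "HannumAgeEAA_z",
                                      "PhenoAgeEAA_z", "GrimAgeEAA_z",
                                      "DunedinPoAm_z"),
                        forced = c("AGE", "SEX", "NHB", "HISP", "OTHER"),
                        half_sample_seed = 1L, nfolds = 10L) {
  vars <- c(penalized, forced)
  if (nrow(cohort) < 2L * length(vars)) stopf("n too small for selection")
  y <- cohort[[outcome]]
  X <- as.matrix(cohort[, vars, drop = FALSE])
  pf <- c(rep(1, length(penalized)), rep(0, length(forced)))

  strat <- if (!is.null(cohort$DIED)) cohort$DIED else rep(0L, nrow(cohort))
  half <- with_seed(half_sample_seed, {
    idx <- logical(nrow(cohort))
    for (s in unique(strat)) {
      rows <- which(strat == s)
      idx[sample(rows, floor(length(rows) / 2))] <- TRUE
    }
    idx
  })
  Xh <- X[half, , drop = FALSE]; yh <- y[half]

  fit_mode <- function(mode) {
    if (mode == "cv") {
      cvf <- with_seed(half_sample_seed + 1L,
                       glmnet::cv.glmnet(Xh, yh, penalty.factor = pf,
                                         nfolds = nfolds))
      lam <- cvf$lambda.min
      co <- stats::coef(cvf, s = "lambda.min")
    } else if (mode == "min_bic") {
      gf <- glmnet::glmnet(Xh, yh, penalty.factor = pf)
      pred <- stats::predict(gf, Xh)
      rss <- colSums((yh - pred)^2)
      dfree <- gf$df + 1
      bic <- length(yh) * log(rss / length(yh)) + dfree * log(length(yh))
      lam <- gf$lambda[which.min(bic)]
      co <- stats::coef(gf, s = lam)
    } else {  # adaptive
      ols <- stats::lm.fit(cbind(1, Xh), yh)$coefficients[-1]
      apf <- pf / pmax(abs(ols), 1e-6)
      apf[pf == 0] <- 0
      cvf <- with_seed(half_sample_seed + 2L,
                       glmnet::cv.glmnet(Xh, yh, penalty.factor = apf,
                                         nfolds = nfolds))
      lam <- cvf$lambda.min
      co <- stats::coef(cvf, s = "lambda.min")
    }
    co <- as.matrix(co)
    sel <- penalized[abs(co[penalized, 1]) > 1e-8]
    list(mode = mode, lambda = lam, selected = sel,
         coefficients = co[, 1])
  }
  modes <- lapply(c("cv", "min_bic", "adaptive"), fit_mode)
  names(modes) <- c("cv", "min_bic", "adaptive")
  sizes <- vapply(modes, function(m) length(m$selected), integer(1))
  order_pref <- c("min_bic", "cv", "adaptive")  # tie toward min_bic
  chosen <- order_pref[which.min(sizes[order_pref])]
  sel <- modes[[chosen]]$selected
  # refit the simplest selection on the full sample by OLS
  full_vars <- c(sel, forced)
  Xf <- cbind(`(Intercept)` = 1, X[, full_vars, drop = FALSE])
  full_fit <- stats::lm.fit(Xf, y)
  r2 <- function(rows) {
    yy <- y[rows]
    pr <- drop(Xf[rows, , drop = FALSE] %*% full_fit$coefficients)
    1 - sum((yy - pr)^2) / sum((yy - mean(yy))^2)
  }
  structure(list(modes = modes, chosen_mode = chosen, selected = sel,
                 full_coefficients = full_fit$coefficients,
                 half_sample = list(fit_half_r2 = r2(which(half)),
                                    holdout_half_r2 = r2(which(!half)))),
            class = "lasso_result")
}
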