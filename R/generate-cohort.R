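#' Generate a synthetic cohort from a structural model
#'
#' Draws exogenous demographics (truncated-normal age, Bernoulli sex,
#' multinomial race/ethnicity), propagates continuous biomarker nodes through
#' the linear structural equations with Gaussian residuals sized for unit
#' marginal variance, then draws the death time from a Weibull
#' proportional-hazards law with hazard
#' `h(t) = kappa * lambda0 * t^(kappa-1) * exp(sum(beta * parent))` over the
#' parents of `DIED`, administratively censored at the cohort horizon. Fully
#' reproducible for a given seed.
#'
#' @param model a [structural_model].
#' @param demo a [demographics_config].
#' @param seed integer seed (mandatory).
#' @param weight_heterogeneity if `TRUE`, draws lognormal sampling weights
#'   (mean 1) and assigns subjects to 30 PSUs, for exercising design-adjusted
#'   estimation; otherwise weights are 1 with a single PSU/stratum.
#' @return a `data.frame` of class `cohort_table` with columns `id`, `AGE`
#'   (years), `SEX`, `NHB`, `HISP`, `OTHER` (0/1), the six biomarker z-score
#'   columns (`HorvathAgeEAA_z`, ..., `TELO_MEAN_z`), `time` (years), `DIED`
#'   (0/1), `weight`, `psu`, `stratum`.
#' @export
generate_cohort <- function(model, demo, seed, weight_heterogeneity = FALSE) {
  if (missing(seed)) stopf("seed is required (reproducibility is mandatory)")
  mom <- implied_covariance(model, demo)  # also validates residual variances
  n <- demo$n
  with_seed(seed, {
    lo <- demo$age_range[1]; hi <- demo$age_range[2]
    age <- rtruncnorm(n, demo$age_mean, demo$age_sd, lo, hi)
    tm <- truncnorm_moments(demo$age_mean, demo$age_sd, lo, hi)
    vals <- list(
      AGE = (age - tm$mean) / sqrt(tm$var),  # exact-moment z-score
      SEX = as.integer(stats::runif(n) < demo$prop_female)
    )
    u <- stats::runif(n)
    vals$NHB <- as.integer(u < demo$prop_nhb)
    vals$HISP <- as.integer(u >= demo$prop_nhb &
                            u < demo$prop_nhb + demo$prop_hisp)
    vals$OTHER <- as.integer(u >= demo$prop_nhb + demo$prop_hisp &
                             u < demo$prop_nhb + demo$prop_hisp +
                                 demo$prop_other)

    topo <- topological_order(model)
    surv <- model$nodes$name[model$nodes$family == "survival"]
    for (v in setdiff(topo, c(names(vals), surv))) {
      pa <- parents_of(model, v)
      b <- vapply(pa, function(p) edge_coef(model, p, v), numeric(1))
      eta <- rep(0, n)
      for (j in seq_along(pa)) eta <- eta + b[j] * vals[[pa[j]]]
      intercept <- -sum(b * mom$mean[pa])
      vals[[v]] <- intercept + eta + stats::rnorm(n, 0, mom$residual_sd[[v]])
    }

    pa_d <- parents_of(model, surv)
    eta_d <- rep(0, n)
    for (p in pa_d) eta_d <- eta_d + edge_coef(model, p, surv) * vals[[p]]
    # S(t) = exp(-lambda0 t^kappa e^eta)  =>  inverse-CDF draw
    uu <- stats::runif(n)
    tdeath <- (-log(uu) / (model$weibull_scale * exp(eta_d)))^
      (1 / model$weibull_shape)
    time <- pmin(tdeath, model$censor_time)
    died <- as.integer(tdeath < model$censor_time)

    if (weight_heterogeneity) {
      w <- stats::rlnorm(n, 0, 0.5)
      w <- w / mean(w)
      psu <- sample(rep_len(1:30, n))
    } else {
      w <- rep(1, n)
      psu <- rep(1L, n)
    }

    out <- data.frame(id = seq_len(n), AGE = age, SEX = vals$SEX,
                      NHB = vals$NHB, HISP = vals$HISP, OTHER = vals$OTHER,
                      stringsAsFactors = FALSE)
    for (v in BIOMARKER_NODES) out[[paste0(v, "_z")]] <- vals[[v]]
    out$time <- time
    out$DIED <- died
    out$weight <- w
    out$psu <- psu
    out$stratum <- 1L
    class(out) <- c("cohort_table", "data.frame")
    attr(out, "censor_time") <- model$censor_time
    out
  })
}

#' Validate a cohort table
#'
#' Checks the invariants a cohort table must satisfy: positive follow-up
#' times, mutually exclusive race dummies, no deaths recorded exactly at the
#' administrative censoring horizon, and positive weights.
#'
#' @param cohort a cohort `data.frame`.
#' @param censor_time optional horizon; defaults to the table's attribute.
#' @return the cohort, invisibly; errors describe the first violation.
#' @export
validate_cohort <- function(cohort, censor_time = attr(cohort, "censor_time")) {
  need <- c("id", "AGE", "SEX", "NHB", "HISP", "OTHER",
            paste0(BIOMARKER_NODES, "_z"), "time", "DIED")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("cohort missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(cohort$time <= 0)) {
    stopf("non-positive follow-up time for id(s): %s",
          paste(utils::head(cohort$id[cohort$time <= 0], 5), collapse = ", "))
  }
  if (any(cohort$NHB + cohort$HISP + cohort$OTHER > 1)) {
    stopf("race dummies are not mutually exclusive")
  }
  if (!is.null(censor_time) &&
      any(cohort$DIED == 1 & cohort$time == censor_time)) {
    stopf("death recorded exactly at the censoring horizon")
  }
  if (!is.null(cohort$weight) && any(cohort$weight <= 0)) {
    stopf("weights must be positive")
  }
  invisible(cohort)
}

#' Calibrate the baseline Weibull rate to a crude mortality-rate target
#'
#' Bisection on the baseline rate `lambda0` until the crude mortality rate
#' (deaths per 1000 person-years) of a large fixed-seed cohort matches the
#' target. The evaluation cohort's exogenous draws and uniform quantiles are
#' held fixed across bisection steps, making the crude rate strictly
#' increasing in `lambda0` and the search deterministic.
#'
#' @param model a [structural_model].
#' @param demo a [demographics_config] (its `n` is ignored for calibration).
#' @param target_rate target crude rate, deaths per 1000 person-years (> 0).
#' @param tol absolute tolerance on the achieved rate (same units).
#' @param n_calib calibration cohort size.
#' @param seed seed for the calibration cohort.
#' @param max_iter bisection iteration cap.
#' @return the model with `weibull_scale` updated; attributes
#'   `achieved_rate` and `iterations` record the calibration.
#' @export
calibrate_baseline_hazard <- function(model, demo, target_rate, tol = 1.0,
                                      n_calib = 20000L, seed = 20220101L,
                                      max_iter = 60L) {
  if (target_rate <= 0) stopf("target_rate must be > 0")
  demo_big <- demo
  demo_big$n <- as.integer(n_calib)
  # Fixed linear predictor and uniforms shared by every lambda0 evaluation.
  probe <- model
  probe$weibull_scale <- 1
  base <- generate_cohort(probe, demo_big, seed = seed)
  # back out eta and u from the unit-rate draw: t^kappa * e^eta = -log(u)
  surv <- model$nodes$name[model$nodes$family == "survival"]
  pa_d <- parents_of(model, surv)
  # reconstruct eta from stored columns (AGE re-z-scored with exact moments)
  tm <- truncnorm_moments(demo$age_mean, demo$age_sd,
                          demo$age_range[1], demo$age_range[2])
  col_val <- function(p) {
    if (p == "AGE") (base$AGE - tm$mean) / sqrt(tm$var)
    else base[[node_column(p)]]
  }
  eta <- rep(0, nrow(base))
  for (p in pa_d) eta <- eta + edge_coef(model, p, surv) * col_val(p)
  # uniforms implied by the unit-rate cohort (uncensored latent times)
  tl <- with_seed(seed + 1L, stats::runif(nrow(base)))
  neg_log_u <- -log(tl)

  crude_rate <- function(lambda0) {
    tdeath <- (neg_log_u / (lambda0 * exp(eta)))^(1 / model$weibull_shape)
    time <- pmin(tdeath, model$censor_time)
    died <- tdeath < model$censor_time
    1000 * sum(died) / sum(time)
  }
  lo <- model$weibull_scale; hi <- model$weibull_scale
  for (i in 1:40) { if (crude_rate(lo) < target_rate) break; lo <- lo / 2 }
  for (i in 1:40) { if (crude_rate(hi) > target_rate) break; hi <- hi * 2 }
  if (crude_rate(lo) > target_rate || crude_rate(hi) < target_rate) {
    stopf("bracketing failed: rate(%.3g)=%.2f, rate(%.3g)=%.2f, target %.2f",
          lo, crude_rate(lo), hi, crude_rate(hi), target_rate)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- sqrt(lo * hi)
    r <- crude_rate(mid)
    if (abs(r - target_rate) <= tol * 0.5 || it >= max_iter) break
    if (r < target_rate) lo <- mid else hi <- mid
  }
  if (abs(r - target_rate) > tol) {
    stopf("calibration did not reach tolerance after %d iterations; last bracket [%.4g, %.4g], rate %.2f",
          it, lo, hi, r)
  }
  out <- model
  out$weibull_scale <- mid
  attr(out, "achieved_rate") <- r
  attr(out, "iterations") <- it
  out
}

#' Crude mortality rate of a cohort
#'
#' Deaths divided by total person-years, times 1000.
#'
#' @param cohort a cohort table with `time` and `DIED` columns.
#' @return deaths per 1000 person-years.
#' @export
crude_mortality_rate <- function(cohort) {
  1000 * sum(cohort$DIED) / sum(cohort$time)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a cohort table.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
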