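# Shared fixtures built in code.

nhanes_cfg <- function() load_default_config("nhanes")
hrs_cfg <- function() load_default_config("hrs")

small_cohort <- function(n = 400, seed = 11, cohort = "nhanes") {
  cfg <- load_default_config(cohort)
  cfg$demographics$n <- as.integer(n)
  generate_cohort(cfg$model, cfg$demographics, seed = seed)
}

# tiny hand-specified structural model: x -> y with configurable beta
toy_model <- function(beta = 0.5, shape = 1, scale = 0.05, censor = 10,
                      beta_died = 0.7) {
  nodes <- data.frame(name = c("AGE", "SEX", "NHB", "HISP", "OTHER",
                               "HorvathAgeEAA", "HannumAgeEAA", "PhenoAgeEAA",
                               "GrimAgeEAA", "DunedinPoAm", "TELO_MEAN",
                               "DIED"),
                      family = c("gaussian", rep("binomial", 4),
                                 rep("gaussian", 6), "survival"),
                      tier = c(rep(0L, 5), rep(1L, 6), 2L),
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = c("AGE", "GrimAgeEAA"),
                      child = c("GrimAgeEAA", "DIED"),
                      beta = c(beta, beta_died), stringsAsFactors = FALSE)
  structural_model(nodes, edges, weibull_shape = shape, weibull_scale = scale,
                   censor_time = censor)
}

toy_demo <- function(n = 500) {
  demographics_config(n = n, age_mean = 64, age_sd = 10, prop_female = 0.5,
                      prop_nhb = 0.1, prop_hisp = 0.1, prop_other = 0.05)
}

# independent brute-force concordance: all pairs, standard censoring rule
brute_force_c <- function(lp, time, event) {
  n <- length(time)
  conc <- comp <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]
    # the shorter observed time must be an event to compare
    if (ti == tj && event[i] && event[j]) next  # tied failure times: skip
    if (ti < tj && !event[i]) next
    if (tj < ti && !event[j]) next
    if (ti == tj && !(event[i] || event[j])) next
    if (ti == tj) { # one event, one censored at same time: censored survives longer
      shorter <- if (event[i]) i else j
    } else shorter <- if (ti < tj) i else j
    longer <- if (shorter == i) j else i
    comp <- comp + 1
    if (lp[shorter] > lp[longer]) conc <- conc + 1
    else if (lp[shorter] == lp[longer]) conc <- conc + 0.5
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# hand log-rank oracle: loop over event times, weighted counts
oracle_logrank <- function(time, event, group, weights = rep(1, length(time))) {
  weights <- weights / mean(weights)
  g <- as.factor(group)
  lev <- levels(g)
  O <- E <- V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at <- time >= tt
    Y <- sum(weights[at])
    d <- sum(weights[at & time == tt & event == 1])
    Y1 <- sum(weights[at & g == lev[1]])
    d1 <- sum(weights[at & time == tt & event == 1 & g == lev[1]])
    O <- O + d1
    E <- E + d * Y1 / Y
    V <- V + d * (Y - d) / max(Y - 1, 1e-12) * (Y1 / Y) * (1 - Y1 / Y)
  }
  (O - E)^2 / V
}

undirected_arcs <- function(arcs) {
  arcs <- arcs[!grepl("^PER_", arcs$parent), , drop = FALSE]
  unique(apply(arcs, 1, function(r) paste(sort(c(r[["parent"]], r[["child"]])),
                                          collapse = "~")))
}

# person-period + percentile coding of a cohort, ready for structure search
abn_encode <- function(cohort, period_length = 2, n_bins = 10) {
  std <- standardize_continuous(cohort)
  pp <- to_person_period(std, period_length)
  nodes <- c("AGE", "SEX", "NHB", "HISP", "OTHER", "HorvathAgeEAA",
             "HannumAgeEAA", "PhenoAgeEAA", "GrimAgeEAA", "DunedinPoAm",
             "TELO_MEAN")
  for (v in nodes) {
    cl <- if (v %in% c("SEX", "NHB", "HISP", "OTHER")) v else
      if (v == "AGE") "AGE" else paste0(v, "_z")
    pp[[v]] <- if (cl == v && v != "AGE") pp[[cl]] else
      discretize_percentiles(pp[[cl]], n_bins)
  }
  pp$DIED <- pp$death_k
  pp
}
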