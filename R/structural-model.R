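#' Demographic configuration for a synthetic cohort
#'
#' Holds the marginal demographic structure a cohort is generated from: the
#' number of subjects, the (truncated normal) age distribution, the proportion
#' of women, and the race/ethnicity mix expressed as proportions of
#' non-Hispanic Black (NHB), Hispanic (HISP), and other (OTHER) participants,
#' with non-Hispanic White as the implicit remainder.
#'
#' @param n positive number of subjects (at least 2).
#' @param age_mean,age_sd mean and SD of the latent normal age distribution,
#'   in years; `age_sd` must be positive.
#' @param prop_female,prop_nhb,prop_hisp,prop_other proportions in `[0, 1]`;
#'   the three race/ethnicity proportions must sum to at most 1.
#' @param age_range length-2 numeric, the truncation interval for age in years.
#' @return an object of class `demographics_config`.
#' @export
demographics_config <- function(n, age_mean, age_sd, prop_female,
                                prop_nhb, prop_hisp, prop_other,
                                age_range = c(50, 85)) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stopf("n must be at least 2, got %s", n)
  if (!is.numeric(age_sd) || age_sd <= 0) stopf("age_sd must be > 0")
  props <- c(prop_female = prop_female, prop_nhb = prop_nhb,
             prop_hisp = prop_hisp, prop_other = prop_other)
  bad <- props < 0 | props > 1
  if (any(bad)) stopf("proportions must lie in [0, 1]: %s",
                      paste(names(props)[bad], collapse = ", "))
  if (prop_nhb + prop_hisp + prop_other > 1 + 1e-12) {
    stopf("prop_nhb + prop_hisp + prop_other must be <= 1")
  }
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stopf("age_range must be an increasing length-2 numeric")
  }
  structure(list(n = n, age_mean = age_mean, age_sd = age_sd,
                 prop_female = prop_female, prop_nhb = prop_nhb,
                 prop_hisp = prop_hisp, prop_other = prop_other,
                 age_range = as.numeric(age_range)),
            class = "demographics_config")
}

# Node roster shared by the default models.
DEMOGRAPHIC_NODES <- c("AGE", "SEX", "NHB", "HISP", "OTHER")
BIOMARKER_NODES <- c("HorvathAgeEAA", "HannumAgeEAA", "PhenoAgeEAA",
                     "GrimAgeEAA", "DunedinPoAm", "TELO_MEAN")
SURVIVAL_NODE <- "DIED"

#' Standard node roster
#'
#' The node table used by the built-in models: five exogenous demographics
#' (tier 0), six biomarker z-scores (tier 1), and the death indicator
#' (survival family, tier 2).
#'
#' @return data.frame with columns `name`, `family`, `tier`.
#' @export
default_nodes <- function() {
  data.frame(
    name = c(DEMOGRAPHIC_NODES, BIOMARKER_NODES, SURVIVAL_NODE),
    family = c("gaussian", rep("binomial", 4L),
               rep("gaussian", length(BIOMARKER_NODES)), "survival"),
    tier = c(rep(0L, 5L), rep(1L, length(BIOMARKER_NODES)), 2L),
    stringsAsFactors = FALSE
  )
}

# Cohort-table column corresponding to a node name.
node_column <- function(node) {
  ifelse(node %in% BIOMARKER_NODES, paste0(node, "_z"), node)
}

#' Structural model over demographic, biomarker, and survival nodes
#'
#' A directed acyclic structural model: linear-Gaussian equations for
#' continuous nodes (coefficients per 1 SD of continuous parents, per 0-to-1
#' change of binary parents), and a Weibull proportional-hazards equation for
#' the single survival node `DIED` (coefficients on the log-hazard scale).
#' Residual SDs of continuous endogenous nodes are implicitly solved so that
#' each has unit marginal variance when `target_unit_variance` is set.
#'
#' @param nodes data.frame with columns `name`, `family`
#'   (`"gaussian"`, `"binomial"`, or `"survival"`), `tier` (non-negative
#'   integer; tier 0 nodes are the exogenous demographics).
#' @param edges data.frame with columns `parent`, `child`, `beta`.
#' @param weibull_shape Weibull shape parameter kappa (> 0); values above 1
#'   give a hazard rising with time.
#' @param weibull_scale baseline Weibull rate lambda0 (> 0), the hazard scale
#'   at covariate value zero.
#' @param censor_time administrative censoring horizon in years.
#' @param target_unit_variance logical; solve residual variances so continuous
#'   nodes have unit marginal variance.
#' @return an object of class `structural_model`.
#' @export
structural_model <- function(nodes, edges, weibull_shape = 1.5,
                             weibull_scale = 0.005, censor_time = 20,
                             target_unit_variance = TRUE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need <- c("name", "family", "tier")
  if (!all(need %in% names(nodes))) stopf("nodes needs columns name, family, tier")
  if (!all(c("parent", "child", "beta") %in% names(edges))) {
    stopf("edges needs columns parent, child, beta")
  }
  if (anyDuplicated(nodes$name)) stopf("duplicate node names")
  surv <- nodes$name[nodes$family == "survival"]
  if (length(surv) != 1L) stopf("exactly one survival node is required")
  if (nodes$tier[nodes$name == surv] != max(nodes$tier)) {
    stopf("the survival node must occupy the maximal tier")
  }
  unknown <- setdiff(c(edges$parent, edges$child), nodes$name)
  if (length(unknown)) stopf("edges refer to unknown nodes: %s",
                             paste(unique(unknown), collapse = ", "))
  if (any(edges$parent == surv)) stopf("no edge may leave the survival node")
  tier0 <- nodes$name[nodes$tier == 0L]
  if (any(edges$child %in% tier0)) stopf("no edge may enter a tier-0 node")
  if (weibull_shape <= 0 || weibull_scale <= 0) {
    stopf("weibull_shape and weibull_scale must be > 0")
  }
  if (censor_time <= 0) stopf("censor_time must be > 0")
  m <- structure(list(nodes = nodes, edges = edges,
                      weibull_shape = weibull_shape,
                      weibull_scale = weibull_scale,
                      censor_time = censor_time,
                      target_unit_variance = isTRUE(target_unit_variance)),
                 class = "structural_model")
  topological_order(m)  # errors if cyclic
  m
}

#' @export
print.structural_model <- function(x, ...) {
  cat(sprintf("structural_model: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  Weibull shape %.3g, scale %.4g, censoring at %g years\n",
              x$weibull_shape, x$weibull_scale, x$censor_time))
  invisible(x)
}

# Topological order of the model's node names; errors on a cycle.
topological_order <- function(model) {
  nodes <- model$nodes$name
  edges <- model$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tb <- table(edges$child)
    indeg[names(tb)] <- as.integer(tb)
  }
  out <- character(0)
  avail <- nodes[indeg == 0L]
  indeg_left <- indeg
  while (length(avail)) {
    v <- sort(avail)[1L]
    avail <- setdiff(avail, v)
    out <- c(out, v)
    kids <- edges$child[edges$parent == v]
    for (k in kids) {
      indeg_left[k] <- indeg_left[k] - 1L
      if (indeg_left[k] == 0L) avail <- c(avail, k)
    }
  }
  if (length(out) != length(nodes)) stopf("edge set contains a cycle")
  out
}

edge_coef <- function(model, parent, child) {
  i <- model$edges$parent == parent & model$edges$child == child
  if (!any(i)) return(NA_real_)
  model$edges$beta[i][1]
}

parents_of <- function(model, child) {
  model$edges$parent[model$edges$child == child]
}

# Published path-model (Model 1) edge sets for the two default cohorts.
nhanes_edges <- function() {
  data.frame(
    parent = c("AGE", "AGE", "SEX", "SEX", "SEX", "NHB", "NHB", "NHB",
               "HISP", "HISP", "HorvathAgeEAA", "HorvathAgeEAA",
               "HorvathAgeEAA", "HannumAgeEAA", "PhenoAgeEAA", "PhenoAgeEAA",
               "GrimAgeEAA", "DunedinPoAm", "DunedinPoAm"),
    child  = c("TELO_MEAN", "DIED", "HorvathAgeEAA", "DunedinPoAm",
               "GrimAgeEAA", "DunedinPoAm", "HorvathAgeEAA", "HannumAgeEAA",
               "HorvathAgeEAA", "PhenoAgeEAA", "DunedinPoAm", "HannumAgeEAA",
               "PhenoAgeEAA", "TELO_MEAN", "HannumAgeEAA", "GrimAgeEAA",
               "DIED", "GrimAgeEAA", "PhenoAgeEAA"),
    beta   = c(-0.220, 0.978, -0.201, -0.270, -0.500, 0.192, -0.126, -0.358,
               -0.110, 0.197, 0.136, 0.433, 0.603, -0.132, 0.357, 0.163,
               0.421, 0.607, 0.269),
    stringsAsFactors = FALSE
  )
}

hrs_edges <- function() {
  data.frame(
    parent = c("AGE", "GrimAgeEAA", "AGE", "SEX", "SEX", "SEX", "NHB", "NHB",
               "HISP", "HorvathAgeEAA", "HorvathAgeEAA", "PhenoAgeEAA",
               "PhenoAgeEAA", "GrimAgeEAA", "DunedinPoAm", "DunedinPoAm"),
    child  = c("TELO_MEAN", "TELO_MEAN", "DIED", "HorvathAgeEAA",
               "DunedinPoAm", "GrimAgeEAA", "DunedinPoAm", "HannumAgeEAA",
               "PhenoAgeEAA", "DunedinPoAm", "HannumAgeEAA", "HannumAgeEAA",
               "GrimAgeEAA", "DIED", "GrimAgeEAA", "PhenoAgeEAA"),
    beta   = c(-0.140, -0.052, 0.944, -0.187, -0.258, -0.563, 0.347, -0.498,
               0.138, 0.120, 0.366, 0.344, 0.212, 0.462, 0.541, 0.254),
    stringsAsFactors = FALSE
  )
}

# Baseline Weibull rates calibrated once (via calibrate_baseline_hazard) to the
# cohort crude mortality-rate targets of 32.2 (NHANES, 20y) and 37.7 (HRS, 7y)
# deaths per 1000 person-years, at shape 1.5.
NHANES_BASELINE_RATE <- 0.0067971
HRS_BASELINE_RATE <- 0.0103265

#' Default cohort configurations
#'
#' Returns the demographic configuration and structural model for one of the
#' two built-in cohort emulations. Demographics follow the published cohort
#' descriptives; edge coefficients are the published path-model (Model 1)
#' estimates; the baseline Weibull rate is calibrated to the cohort crude
#' mortality rate (32.2 per 1000 person-years over a 20-year horizon for
#' `"nhanes"`, 37.7 over 7 years for `"hrs"`).
#'
#' @param cohort_name `"nhanes"` or `"hrs"`.
#' @return list with elements `demographics` (a [demographics_config]) and
#'   `model` (a [structural_model]).
#' @examples
#' cfg <- load_default_config("nhanes")
#' cfg$model
#' @export
load_default_config <- function(cohort_name) {
  valid <- c("nhanes", "hrs")
  if (!is.character(cohort_name) || length(cohort_name) != 1L ||
      !(tolower(cohort_name) %in% valid)) {
    stopf("unknown cohort name %s; valid names: %s",
          deparse(cohort_name), paste(valid, collapse = ", "))
  }
  if (tolower(cohort_name) == "nhanes") {
    demo <- demographics_config(n = 2522, age_mean = 64.0, age_sd = 10,
                                prop_female = 0.544, prop_nhb = 0.087,
                                prop_hisp = 0.094, prop_other = 0.033,
                                age_range = c(50, 85))
    model <- structural_model(default_nodes(), nhanes_edges(),
                              weibull_shape = 1.5,
                              weibull_scale = NHANES_BASELINE_RATE,
                              censor_time = 20)
  } else {
    demo <- demographics_config(n = 1029, age_mean = 73.1, age_sd = 9,
                                prop_female = 0.590, prop_nhb = 0.077,
                                prop_hisp = 0.073, prop_other = 0.025,
                                age_range = c(58, 95))
    model <- structural_model(default_nodes(), hrs_edges(),
                              weibull_shape = 1.5,
                              weibull_scale = HRS_BASELINE_RATE,
                              censor_time = 7)
  }
  list(demographics = demo, model = model)
}

#' Write / read a structural model as JSON or YAML
#'
#' Serializes a [structural_model] as a document with `nodes`,
#' `edges` (list of `{parent, child, beta}`), and `weibull`
#' (`{shape, scale, censor_time}`). Format is inferred from the file
#' extension (`.json`, `.yaml`/`.yml`).
#'
#' @param model a [structural_model].
#' @param path output (input) file path.
#' @return `write_structural_model` returns `path` invisibly;
#'   `read_structural_model` returns a [structural_model].
#' @export
write_structural_model <- function(model, path) {
  doc <- list(
    nodes = model$nodes,
    edges = model$edges,
    weibull = list(shape = model$weibull_shape, scale = model$weibull_scale,
                   censor_time = model$censor_time),
    target_unit_variance = model$target_unit_variance
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc$nodes <- lapply(seq_len(nrow(model$nodes)),
                        function(i) as.list(model$nodes[i, ]))
    doc$edges <- lapply(seq_len(nrow(model$edges)),
                        function(i) as.list(model$edges[i, ]))
    yaml::write_yaml(doc, path)
  } else stopf("unsupported extension in %s (use .json or .yaml)", path)
  invisible(path)
}

#' @rdname write_structural_model
#' @export
read_structural_model <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else stopf("unsupported extension in %s", path)
  to_df <- function(x, cols) {
    if (is.data.frame(x)) x[cols]
    else do.call(rbind, lapply(x, function(r) as.data.frame(r[cols])))
  }
  nodes <- to_df(doc$nodes, c("name", "family", "tier"))
  nodes$tier <- as.integer(nodes$tier)
  edges <- to_df(doc$edges, c("parent", "child", "beta"))
  edges$beta <- as.numeric(edges$beta)
  structural_model(nodes, edges,
                   weibull_shape = doc$weibull$shape,
                   weibull_scale = doc$weibull$scale,
                   censor_time = doc$weibull$censor_time,
                   target_unit_variance = isTRUE(doc$target_unit_variance))
}
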