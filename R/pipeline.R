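#' Pipeline configuration
#'
#' Validates and bundles everything one end-to-end run needs. Either a
#' built-in cohort name or a path to a structural-model document must be
#' given; the seed is mandatory.
#'
#' @param cohort_name `"nhanes"` or `"hrs"`, or `NULL` when `model_path`
#'   is given.
#' @param seed integer seed (mandatory).
#' @param output_dir run directory (created if needed).
#' @param model_path optional JSON/YAML structural model (see
#'   [read_structural_model]); requires `demographics`.
#' @param demographics a [demographics_config] when `model_path` is used.
#' @param n_override optional cohort size overriding the default.
#' @param period_length person-period interval in years.
#' @param n_bins percentile bins for discretization.
#' @param score_type `"bic"` or `"laplace"`.
#' @param parent_limits ascending limits for the structure search.
#' @param delta_fraction leveling-off threshold (see [select_parent_limit]).
#' @param weight_heterogeneity draw heterogeneous sampling weights.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_name = NULL, seed = NULL, output_dir,
                            model_path = NULL, demographics = NULL,
                            n_override = NULL, period_length = 2,
                            n_bins = 10L, score_type = "bic",
                            parent_limits = 1:3, delta_fraction = 0.01,
                            weight_heterogeneity = FALSE) {
  if (is.null(seed)) stopf("seed is mandatory in a pipeline config")
  if (is.null(cohort_name) && is.null(model_path)) {
    stopf("either cohort_name or model_path is required")
  }
  if (!is.null(model_path)) {
    if (!file.exists(model_path)) stopf("model file not found: %s", model_path)
    if (is.null(demographics)) {
      stopf("demographics must accompany a custom model")
    }
  }
  structure(list(cohort_name = cohort_name, seed = as.integer(seed),
                 output_dir = output_dir, model_path = model_path,
                 demographics = demographics,
                 n_override = n_override, period_length = period_length,
                 n_bins = as.integer(n_bins), score_type = score_type,
                 parent_limits = as.integer(parent_limits),
                 delta_fraction = delta_fraction,
                 weight_heterogeneity = isTRUE(weight_heterogeneity)),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Simulate, run the classical analyses, encode to person-period, learn the
#' network across parent limits with leveling-off selection, and fit the
#' path models (unweighted Model 1 and design-adjusted Model 2) on the
#' reference DAG. Every artifact is written as plain text under the run
#' directory, with a JSON manifest recording the configuration, seed, stage
#' status, and artifact list; a stage failure is recorded in the manifest
#' and earlier artifacts are retained. Idempotent per seed.
#'
#' @param config a [pipeline_config].
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("agingnet")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   config = config[setdiff(names(config), "demographics")],
                   stages = list(), artifacts = character(0))
  state <- new.env()
  stage <- function(name, fun) {
    res <- tryCatch({ fun(); list(status = "ok") },
                    error = function(e) list(status = "error",
                                             message = conditionMessage(e)))
    manifest$stages[[name]] <<- res
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    if (res$status != "ok") {
      stopf("stage %s failed: %s (prior artifacts retained)", name,
            res$message)
    }
  }
  add_artifact <- function(f) {
    manifest$artifacts <<- union(manifest$artifacts, basename(f))
  }

  stage("simulate", function() {
    if (!is.null(config$cohort_name)) {
      cfg <- load_default_config(config$cohort_name)
    } else {
      cfg <- list(model = read_structural_model(config$model_path),
                  demographics = config$demographics)
    }
    if (!is.null(config$n_override)) cfg$demographics$n <-
        as.integer(config$n_override)
    cohort <- generate_cohort(cfg$model, cfg$demographics, seed = config$seed,
                              weight_heterogeneity =
                                config$weight_heterogeneity)
    validate_cohort(cohort)
    state$model <- cfg$model
    state$cohort <- cohort
    write_cohort(cohort, out("cohort.csv"))
    add_artifact(out("cohort.csv"))
  })

  stage("classical", function() {
    ch <- state$cohort
    r <- pearson_matrix(ch)
    utils::write.csv(as.data.frame(r), out("correlations.csv"))
    km_rows <- list(); lr_rows <- list(); cox_rows <- list()
    for (bm in paste0(BIOMARKER_NODES, "_z")) {
      grp <- tertile_assign(ch[[bm]])
      km <- km_curve(ch$time, ch$DIED, grp, ch$weight)
      km$curves$marker <- bm
      km_rows[[bm]] <- km$curves
      lr <- logrank_test(ch$time, ch$DIED, grp, ch$weight)
      lr_rows[[bm]] <- data.frame(marker = bm, chisq = lr$chisq, df = lr$df,
                                  p = lr$p)
      cx <- cox_fit(ch$time, ch$DIED,
                    ch[, c(bm, "AGE", "SEX", "NHB", "HISP", "OTHER")],
                    weights = ch$weight)
      cc <- cx$coefficients[1, ]
      cox_rows[[bm]] <- data.frame(marker = bm, lnhr = cc$lnhr, se = cc$se,
                                   lower = cc$lower, upper = cc$upper,
                                   p = cc$p, harrell_c = cx$concordance)
    }
    utils::write.csv(do.call(rbind, km_rows), out("km_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, lr_rows), out("logrank.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, cox_rows), out("cox.csv"),
                     row.names = FALSE)
    las <- lasso_paths(ch, half_sample_seed = config$seed)
    utils::write.csv(
      data.frame(term = names(las$full_coefficients),
                 beta = unname(las$full_coefficients),
                 chosen_mode = las$chosen_mode),
      out("lasso.csv"), row.names = FALSE)
    for (f in c("correlations.csv", "km_curves.csv", "logrank.csv",
                "cox.csv", "lasso.csv")) add_artifact(f)
  })

  stage("encode", function() {
    ch <- standardize_continuous(state$cohort)
    pp <- to_person_period(ch, config$period_length)
    nodes <- c(DEMOGRAPHIC_NODES, BIOMARKER_NODES)
    abn <- pp
    for (v in nodes) {
      cl <- node_column(v)
      if (v %in% c("AGE", BIOMARKER_NODES)) {
        abn[[v]] <- discretize_percentiles(pp[[cl]], config$n_bins)
      } else {
        abn[[v]] <- pp[[cl]]
      }
    }
    abn[[SURVIVAL_NODE]] <- pp$death_k
    state$pp <- pp
    state$abn_data <- abn
    utils::write.csv(pp, out("person_period.csv"), row.names = FALSE)
    add_artifact("person_period.csv")
  })

  stage("learn", function() {
    per <- setdiff(grep("^PER_[0-9]+$", names(state$abn_data), value = TRUE),
                   "PER_1")
    cons <- default_abn_constraints(period_dummies = per,
                                    max_parents = max(config$parent_limits))
    fits <- fit_across_parent_limits(
      state$abn_data, c(DEMOGRAPHIC_NODES, BIOMARKER_NODES, SURVIVAL_NODE),
      cons, limits = config$parent_limits, score_type = config$score_type)
    for (L in names(fits$dags)) {
      write_dag(fits$dags[[L]], out(sprintf("dag_limit%s.dot", L)))
      write_dag(fits$dags[[L]], out(sprintf("dag_limit%s.graphml", L)))
      add_artifact(sprintf("dag_limit%s.dot", L))
      add_artifact(sprintf("dag_limit%s.graphml", L))
    }
    utils::write.csv(data.frame(limit = fits$limits, score = fits$scores),
                     out("score_trajectory.csv"), row.names = FALSE)
    add_artifact("score_trajectory.csv")
    state$selected_limit <- select_parent_limit(fits$scores, fits$limits,
                                                config$delta_fraction)
    state$fits <- fits
  })

  stage("fit_paths", function() {
    ch <- state$cohort
    design <- design_from_cohort(ch)
    for (tag in c("model1_srs", "model2_weighted")) {
      pm <- fit_path_model(state$model, ch, design, tag)
      f <- sprintf("path_%s.csv", sub("_.*$", "", tag))
      df <- pm$estimates
      df$model_tag <- tag
      df$weibull_shape_hat <- pm$weibull_shape_hat
      utils::write.csv(df, out(f), row.names = FALSE)
      add_artifact(f)
    }
  })

  manifest$selected_parent_limit <- state$selected_limit
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Structured diff between two pipeline runs
#'
#' Compares the fitted path arcs and estimates of two run directories:
#' the arc-set symmetric difference and per-arc estimate deltas for arcs
#' present in both.
#'
#' @param run_a,run_b run directories written by [run_pipeline].
#' @return list with `only_a`, `only_b` (arc data.frames) and `deltas`
#'   (per-common-arc beta differences).
#' @export
compare_runs <- function(run_a, run_b) {
  read_run <- function(d) {
    mf <- file.path(d, "manifest.json")
    if (!file.exists(mf)) stopf("manifest not readable in %s", d)
    paths <- utils::read.csv(file.path(d, "path_model1.csv"),
                             stringsAsFactors = FALSE)
    list(manifest = jsonlite::read_json(mf), paths = paths)
  }
  a <- read_run(run_a); b <- read_run(run_b)
  key <- function(df) paste(df$parent, df$child, sep = " -> ")
  ka <- key(a$paths); kb <- key(b$paths)
  common <- intersect(ka, kb)
  deltas <- data.frame(
    arc = common,
    beta_a = a$paths$beta[match(common, ka)],
    beta_b = b$paths$beta[match(common, kb)],
    stringsAsFactors = FALSE)
  deltas$delta <- deltas$beta_b - deltas$beta_a
  list(only_a = a$paths[!(ka %in% kb), c("parent", "child")],
       only_b = b$paths[!(kb %in% ka), c("parent", "child")],
       deltas = deltas)
}
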