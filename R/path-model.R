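#' Survey design descriptor
#'
#' @param weights positive sampling weights, one per subject.
#' @param psu primary sampling unit (cluster) labels; defaults to one PSU.
#' @param strata stratum labels (accepted for bookkeeping; variance uses
#'   weights and PSU clustering only).
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(weights, psu = NULL, strata = NULL) {
  if (any(weights <= 0)) stopf("weights must be > 0")
  n <- length(weights)
  psu <- psu %||% rep(1L, n)
  strata <- strata %||% rep(1L, n)
  if (length(psu) != n || length(strata) != n) {
    stopf("design columns must align with the weights")
  }
  structure(list(weights = weights, psu = psu, strata = strata, n = n),
            class = "survey_design")
}

design_from_cohort <- function(cohort) {
  survey_design(cohort$weight %||% rep(1, nrow(cohort)),
                cohort$psu %||% rep(1L, nrow(cohort)),
                cohort$stratum %||% rep(1L, nrow(cohort)))
}

# With a single PSU every subject is its own (self-representing) cluster.
effective_cluster <- function(design) {
  if (length(unique(design$psu)) < 2L) seq_len(design$n) else design$psu
}

#' Z-score the continuous columns of a cohort
#'
#' Standardizes `AGE` and the six biomarker columns to sample mean 0 and
#' sample SD 1 (denominator `n - 1`); binary columns are untouched.
#' Idempotent up to numerical precision.
#'
#' @param cohort a cohort table.
#' @param columns columns to standardize; defaults to `AGE` plus the
#'   biomarker z-score columns.
#' @return the cohort with standardized columns.
#' @export
standardize_continuous <- function(cohort,
                                   columns = c("AGE",
                                               paste0(BIOMARKER_NODES, "_z"))) {
  for (cl in intersect(columns, names(cohort))) {
    s <- stats::sd(cohort[[cl]])
    if (!is.finite(s) || s == 0) {
      stopf("column %s has zero variance and cannot be standardized", cl)
    }
    cohort[[cl]] <- (cohort[[cl]] - mean(cohort[[cl]])) / s
  }
  cohort
}

path_estimates <- function(parent, child, beta, se) {
  if (any(se <= 0)) stopf("non-positive standard error for child %s", child)
  data.frame(parent = parent, child = child, beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(beta / se)),
             stringsAsFactors = FALSE)
}

#' Fit one linear (Gaussian) node of the path model
#'
#' Weighted least squares of the child on its parents. Standard errors are
#' classical under `model1_srs` and cluster-robust (sandwich, clustered on
#' PSU) under `model2_weighted`; p-values are large-sample normal.
#'
#' @param child child node name.
#' @param parents parent node names.
#' @param cohort standardized cohort table (see [standardize_continuous]).
#' @param design a [survey_design]; defaults to the cohort's columns.
#' @param model_tag `"model1_srs"` or `"model2_weighted"`.
#' @return data.frame of path estimates (`parent`, `child`, `beta`, `se`, `p`).
#' @export
fit_linear_node <- function(child, parents, cohort, design = NULL,
                            model_tag = c("model1_srs", "model2_weighted")) {
  model_tag <- match.arg(model_tag)
  design <- design %||% design_from_cohort(cohort)
  ycol <- node_column(child)
  xcols <- node_column(parents)
  df <- cohort[, c(ycol, xcols), drop = FALSE]
  names(df) <- c(".y", parents)
  w <- if (model_tag == "model2_weighted") design$weights else rep(1, nrow(df))
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", parents),
                                               collapse = " + ")))
  fit <- stats::lm(fml, data = df, weights = w)
  if (any(is.na(stats::coef(fit)))) {
    stopf("collinear parents fitting %s: dropped %s", child,
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                collapse = ", "))
  }
  V <- if (model_tag == "model2_weighted") {
    sandwich::vcovCL(fit, cluster = effective_cluster(design))
  } else {
    stats::vcov(fit)
  }
  b <- stats::coef(fit)[-1]
  se <- sqrt(diag(V))[-1]
  path_estimates(parents, rep(child, length(parents)), unname(b), unname(se))
}

# Weibull proportional-hazards maximum likelihood.
# h(t) = kappa * lambda0 * t^(kappa - 1) * exp(x'beta); right-censored,
# weighted; theta = (log kappa, log lambda0, beta).
weibull_ph_fit <- function(time, event, X, weights = NULL, cluster = NULL) {
  n <- length(time)
  if (any(time <= 0)) stopf("times must be > 0")
  if (sum(event) < 1) stopf("at least one event is required")
  w <- weights %||% rep(1, n)
  X <- as.matrix(X)
  p <- ncol(X)
  lt <- log(time)
  nll <- function(th) {
    k <- exp(th[1]); l0 <- exp(th[2]); b <- th[-(1:2)]
    eta <- if (p) drop(X %*% b) else rep(0, n)
    H <- l0 * time^k * exp(eta)
    -sum(w * (event * (th[1] + th[2] + (k - 1) * lt + eta) - H))
  }
  grad_mat <- function(th) {
    k <- exp(th[1]); l0 <- exp(th[2]); b <- th[-(1:2)]
    eta <- if (p) drop(X %*% b) else rep(0, n)
    H <- l0 * time^k * exp(eta)
    g1 <- w * (event * (1 + k * lt) - k * H * lt)
    g2 <- w * (event - H)
    gb <- if (p) X * (w * (event - H)) else NULL
    cbind(g1, g2, gb)
  }
  gr <- function(th) -colSums(grad_mat(th))
  start <- c(0, log(sum(w * event) / sum(w * time)), rep(0, p))
  opt <- stats::optim(start, nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, nll, gr, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12))
    if (opt2$convergence != 0) {
      stopf("Weibull fit did not converge; gradient norm %.3g",
            sqrt(sum(gr(opt2$par)^2)))
    }
    opt <- opt2
  }
  th <- opt$par
  Hobs <- stats::optimHess(th, nll, gr)
  bread <- solve(Hobs)
  sc <- grad_mat(th)
  if (!is.null(cluster)) {
    sc <- rowsum(sc, group = cluster)
  }
  robust <- bread %*% crossprod(sc) %*% bread
  list(theta = th, shape = exp(th[1]), rate = exp(th[2]),
       beta = th[-(1:2)], vcov = bread, vcov_robust = robust,
       loglik = -opt$value)
}

#' Fit the Weibull mortality node of the path model
#'
#' Maximizes the right-censored (optionally weighted) Weibull
#' proportional-hazards log-likelihood by quasi-Newton from a closed-form
#' exponential-fit start, and reports each parent's log-hazard-ratio with a
#' standard error from the observed information (cluster-robust sandwich on
#' PSU under `model2_weighted`).
#'
#' @param time,event follow-up times (> 0) and 0/1 event indicators.
#' @param parents parent node names.
#' @param cohort standardized cohort table.
#' @param design a [survey_design].
#' @param model_tag `"model1_srs"` or `"model2_weighted"`.
#' @return list with `estimates` (path-estimate data.frame) and `shape`
#'   (the Weibull shape MLE).
#' @export
fit_weibull_node <- function(time, event, parents, cohort, design = NULL,
                             model_tag = c("model1_srs", "model2_weighted")) {
  model_tag <- match.arg(model_tag)
  design <- design %||% design_from_cohort(cohort)
  X <- as.matrix(cohort[, node_column(parents), drop = FALSE])
  weighted <- model_tag == "model2_weighted"
  fit <- weibull_ph_fit(time, event, X,
                        weights = if (weighted) design$weights else NULL,
                        cluster = if (weighted) effective_cluster(design) else NULL)
  V <- if (weighted) fit$vcov_robust else fit$vcov
  se <- sqrt(diag(V))[-(1:2)]
  list(estimates = path_estimates(parents, rep(SURVIVAL_NODE, length(parents)),
                                  fit$beta, unname(se)),
       shape = fit$shape, loglik = fit$loglik, rate = fit$rate)
}

#' Discrete-time hazard node (logistic on person-period rows)
#'
#' Logistic regression of the per-period death indicator on the parents plus
#' the period dummies, with `PER_1` dropped as the reference. Coefficients
#' are on the log-odds scale; for small per-period hazards they approximate
#' the continuous-time log hazard ratios.
#'
#' @param person_period a person-period table (see [to_person_period]).
#' @param parents parent node names.
#' @return data.frame of path estimates for the parents (period-dummy
#'   coefficients are attached as attribute `"period_effects"`).
#' @export
fit_discrete_hazard_node <- function(person_period, parents) {
  per_cols <- grep("^PER_[0-9]+$", names(person_period), value = TRUE)
  if (!length(per_cols)) stopf("period dummies are absent")
  if (sum(person_period$death_k) < 1) stopf("no events in the table")
  keep_per <- setdiff(per_cols, "PER_1")
  xcols <- c(node_column(parents), keep_per)
  fml <- stats::as.formula(paste("death_k ~",
                                 paste(sprintf("`%s`", xcols),
                                       collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = person_period,
                                     family = stats::binomial()))
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stopf("collinear covariates: %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  if (any(abs(cf[-1]) > 20)) {
    stopf("separation fitting the discrete hazard: %s",
          paste(names(cf)[abs(cf) > 20], collapse = ", "))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  ix <- seq_along(parents) + 1L
  out <- path_estimates(parents, rep(SURVIVAL_NODE, length(parents)),
                        unname(cf[ix]), unname(se[ix]))
  attr(out, "period_effects") <- cf[-seq_len(length(parents) + 1L)]
  out
}

#' Fit the full node-wise path model on a DAG
#'
#' Dispatches every child with at least one parent to the appropriate node
#' fit -- weighted least squares for Gaussian children, Weibull proportional
#' hazards for the mortality node -- and collects one estimate per arc.
#' Output rows are ordered topologically by child, then lexicographically by
#' parent.
#'
#' @param dag a [structural_model], a `scored_dag`, or an arc data.frame
#'   with columns `parent`, `child` (acyclic; the mortality node childless).
#' @param cohort a cohort table (standardized internally).
#' @param design a [survey_design]; defaults to the cohort's columns.
#' @param model_tag `"model1_srs"` (unweighted, classical SEs) or
#'   `"model2_weighted"` (weights + PSU cluster-robust SEs).
#' @return an object of class `path_model_result`: `estimates`,
#'   `weibull_shape_hat`, `model_tag`.
#' @export
fit_path_model <- function(dag, cohort, design = NULL,
                           model_tag = c("model1_srs", "model2_weighted")) {
  model_tag <- match.arg(model_tag)
  arcs <- if (inherits(dag, "structural_model")) {
    dag$edges[, c("parent", "child")]
  } else if (inherits(dag, "scored_dag")) dag$arcs else as.data.frame(dag)
  arcs <- arcs[!grepl("^PER_", arcs$parent), , drop = FALSE]
  nodes <- unique(c(arcs$parent, arcs$child))
  if (!arcs_acyclic(arcs, nodes)) stopf("dag must be acyclic")
  if (any(arcs$parent == SURVIVAL_NODE)) {
    stopf("the mortality node must be childless")
  }
  design <- design %||% design_from_cohort(cohort)
  std <- standardize_continuous(cohort)
  # topological order of children for deterministic output
  topo <- topo_order_arcs(arcs, sort(nodes))
  est <- list()
  shape_hat <- NA_real_
  for (ch in intersect(topo, unique(arcs$child))) {
    pa <- sort(arcs$parent[arcs$child == ch])
    res <- tryCatch({
      if (ch == SURVIVAL_NODE) {
        wf <- fit_weibull_node(std$time, std$DIED, pa, std, design, model_tag)
        shape_hat <- wf$shape
        wf$estimates
      } else {
        fit_linear_node(ch, pa, std, design, model_tag)
      }
    }, error = function(e) stopf("fitting child %s failed: %s", ch,
                                 conditionMessage(e)))
    est[[ch]] <- res
  }
  estimates <- do.call(rbind, est) %||%
    data.frame(parent = character(0), child = character(0),
               beta = numeric(0), se = numeric(0), p = numeric(0))
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, weibull_shape_hat = shape_hat,
                 model_tag = model_tag),
            class = "path_model_result")
}

#' @export
print.path_model_result <- function(x, ...) {
  cat(sprintf("path_model_result (%s): %d arcs, Weibull shape %.3f\n",
              x$model_tag, nrow(x$estimates), x$weibull_shape_hat))
  print(x$estimates, digits = 3)
  invisible(x)
}

#' Indirect effect along a directed path
#'
#' Product of the path coefficients along an ordered node chain, with a
#' first-order delta-method standard error assuming independence across the
#' node-wise equations (they share no parameters).
#'
#' @param path character vector of node names, consecutive pairs being arcs
#'   of the fitted model.
#' @param result a `path_model_result`.
#' @return list with `effect` and `se`.
#' @export
indirect_effect <- function(path, result) {
  if (length(path) < 2L) stopf("path needs at least two nodes")
  est <- result$estimates
  bs <- numeric(0); ses <- numeric(0)
  for (i in seq_len(length(path) - 1L)) {
    hit <- est$parent == path[i] & est$child == path[i + 1L]
    if (!any(hit)) stopf("no fitted arc %s -> %s", path[i], path[i + 1L])
    bs <- c(bs, est$beta[hit][1]); ses <- c(ses, est$se[hit][1])
  }
  effect <- prod(bs)
  # delta method: Var = sum_j (prod_{i != j} b_i)^2 se_j^2
  var <- sum(vapply(seq_along(bs), function(j)
    prod(bs[-j])^2 * ses[j]^2, numeric(1)))
  list(effect = effect, se = sqrt(var))
}
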