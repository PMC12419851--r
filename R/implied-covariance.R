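#' Exact implied moments of the non-survival nodes
#'
#' Propagates first and second moments through the linear structural system in
#' topological order: exogenous age contributes unit variance (it enters the
#' equations as an exact z-score of its truncated normal law), binary
#' exogenous nodes contribute `p(1-p)` with the multinomial covariance between
#' mutually exclusive race dummies, and each continuous endogenous node
#' receives the residual variance required for unit marginal variance. Serves
#' as the closed-form oracle the generator is tested against.
#'
#' @param model a [structural_model].
#' @param demo a [demographics_config].
#' @return list with `cov` (covariance matrix over non-survival nodes),
#'   `mean` (expectations), and `residual_sd` (per continuous endogenous
#'   node). Errors if any implied residual variance is non-positive, naming
#'   the offending node.
#' @export
implied_covariance <- function(model, demo) {
  stopifnot(inherits(model, "structural_model"),
            inherits(demo, "demographics_config"))
  topo <- topological_order(model)
  surv <- model$nodes$name[model$nodes$family == "survival"]
  topo <- setdiff(topo, surv)
  k <- length(topo)
  S <- matrix(0, k, k, dimnames = list(topo, topo))
  mu <- stats::setNames(numeric(k), topo)
  fam <- stats::setNames(model$nodes$family, model$nodes$name)
  tier <- stats::setNames(model$nodes$tier, model$nodes$name)
  resid_sd <- stats::setNames(numeric(0), character(0))

  pf <- demo$prop_female
  pr <- c(NHB = demo$prop_nhb, HISP = demo$prop_hisp, OTHER = demo$prop_other)

  for (v in topo) {
    pa <- parents_of(model, v)
    if (!length(pa)) {
      if (fam[[v]] == "binomial") {
        p <- if (v == "SEX") pf else pr[[v]]
        mu[v] <- p
        S[v, v] <- p * (1 - p)
        # mutually exclusive race dummies: Cov = -p_i p_j
        others <- intersect(setdiff(names(pr), v), topo)
        if (v %in% names(pr)) {
          for (o in others) {
            if (which(topo == o) < which(topo == v)) {
              S[v, o] <- S[o, v] <- -pr[[v]] * pr[[o]]
            }
          }
        }
      } else {
        mu[v] <- 0   # z-scored exogenous continuous node
        S[v, v] <- 1
      }
      next
    }
    b <- vapply(pa, function(p) edge_coef(model, p, v), numeric(1))
    prior <- topo[seq_len(which(topo == v) - 1L)]
    cross <- as.vector(S[pa, prior, drop = FALSE] |> crossprod(b))
    S[v, prior] <- S[prior, v] <- cross
    explained <- drop(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
    if (model$target_unit_variance) {
      r2 <- 1 - explained
      if (r2 <= 0) {
        stopf(paste0("node %s: implied residual variance %.4f <= 0 under ",
                     "unit marginal variance; configuration rejected"),
              v, r2)
      }
      S[v, v] <- 1
      resid_sd[v] <- sqrt(r2)
    } else {
      S[v, v] <- explained + 1
      resid_sd[v] <- 1
    }
    mu[v] <- sum(b * mu[pa])  # removed again by the mean-centering intercept
    mu[v] <- 0
  }
  list(cov = S, mean = mu, residual_sd = resid_sd)
}
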