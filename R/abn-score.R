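# Decomposable node scores for ABN structure learning.
#
# score_type "bic": maximized log-likelihood of the child's GLM on its
# parents (+ intercept) minus (k/2) log N, with k the number of free
# parameters (|Pa| + 2 for gaussian, including the residual variance;
# |Pa| + 1 for binomial). Higher is better.
#
# score_type "laplace": Laplace-approximate log marginal likelihood with
# independent Normal(0, 1000) priors on the GLM coefficients; for gaussian
# children the residual variance is profiled at its MLE.

PRIOR_VAR <- 1000

#' Score one child / parent-set family
#'
#' @param child child node (column) name; its family is `"binomial"` when the
#'   column is 0/1 with `binary_child = TRUE`, otherwise gaussian.
#' @param parent_set character vector of parent column names (possibly empty).
#' @param data data.frame containing child and parents.
#' @param score_type `"bic"` or `"laplace"`.
#' @param binary_child logical; fit a logistic model for the child.
#' @return a scalar score (higher is better); `-Inf` with a
#'   `"diagnostic"` attribute for collinear parents or perfect separation.
#' @export
node_score <- function(child, parent_set, data, score_type = c("bic", "laplace"),
                       binary_child = NULL) {
  score_type <- match.arg(score_type)
  y <- data[[child]]
  if (is.null(y)) stopf("child column %s not in data", child)
  miss <- setdiff(parent_set, names(data))
  if (length(miss)) stopf("parent column(s) missing: %s",
                          paste(miss, collapse = ", "))
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  for (p in parent_set) X <- cbind(X, data[[p]])
  colnames(X) <- c("(Intercept)", parent_set)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    return(structure(-Inf, diagnostic = sprintf(
      "collinear parents for %s: rank %d < %d", child, qr_x$rank, ncol(X))))
  }
  if (is.null(binary_child)) binary_child <- all(y %in% c(0, 1)) &&
      length(unique(y)) <= 2
  if (binary_child) {
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    if (any(abs(fit$coefficients[-1]) > 20)) {
      return(structure(-Inf, diagnostic = sprintf(
        "perfect separation fitting %s | {%s}", child,
        paste(parent_set, collapse = ", "))))
    }
    mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
    ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
    k <- length(parent_set) + 1L
    if (score_type == "bic") return(ll - k / 2 * log(n))
    return(laplace_binomial(X, y))
  }
  # gaussian child: closed form from the QR fit
  res <- qr.resid(qr_x, y)
  rss <- sum(res^2)
  sigma2 <- rss / n
  if (sigma2 <= 0) {
    return(structure(-Inf, diagnostic = sprintf(
      "degenerate zero residual variance for %s", child)))
  }
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- length(parent_set) + 2L
  if (score_type == "bic") return(ll - k / 2 * log(n))
  laplace_gaussian(X, y, sigma2)
}

# Laplace log marginal likelihood, gaussian child, sigma2 profiled at MLE.
laplace_gaussian <- function(X, y, sigma2) {
  d <- ncol(X)
  A <- crossprod(X) / sigma2 + diag(1 / PRIOR_VAR, d)
  bhat <- solve(A, crossprod(X, y) / sigma2)
  res <- y - X %*% bhat
  ll <- -length(y) / 2 * log(2 * pi * sigma2) - sum(res^2) / (2 * sigma2)
  lp <- sum(stats::dnorm(bhat, 0, sqrt(PRIOR_VAR), log = TRUE))
  ll + lp + d / 2 * log(2 * pi) - 0.5 * determinant(A)$modulus[1]
}

# Laplace log marginal likelihood, binomial child, Newton MAP.
laplace_binomial <- function(X, y, max_iter = 50L) {
  d <- ncol(X)
  b <- rep(0, d)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    g <- drop(crossprod(X, y - mu)) - b / PRIOR_VAR
    H <- crossprod(X * W, X) + diag(1 / PRIOR_VAR, d)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-9) break
  }
  eta <- drop(X %*% b)
  mu <- stats::plogis(eta)
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  H <- crossprod(X * (mu * (1 - mu)), X) + diag(1 / PRIOR_VAR, d)
  lp <- sum(stats::dnorm(b, 0, sqrt(PRIOR_VAR), log = TRUE))
  ll + lp + d / 2 * log(2 * pi) - 0.5 * determinant(H)$modulus[1]
}

cache_key <- function(child, parent_set) {
  paste0(child, "|", paste(sort(parent_set), collapse = ","))
}

#' Exhaustive per-family score cache
#'
#' Scores every admissible (child, parent set) family up to the constraint
#' set's parent limit. Gaussian families are scored from a single
#' cross-product matrix of the data (the residual sum of squares of any
#' sub-model is a Schur complement), so the cache over thousands of gaussian
#' families costs one pass over the rows.
#'
#' @param data data.frame of node columns.
#' @param nodes character vector of node names to search over (columns of
#'   `data`); nodes absent from `constraints$nodes` are not allowed.
#' @param constraints a [constraint_set].
#' @param score_type `"bic"` or `"laplace"`.
#' @param binary_nodes names of nodes to score with logistic models;
#'   defaults to 0/1 columns.
#' @return an object of class `score_cache`: list with `entries` (named
#'   numeric), `sets` (per child, list of parent sets), `score_type`, `n`.
#' @export
build_score_cache <- function(data, nodes, constraints,
                              score_type = c("bic", "laplace"),
                              binary_nodes = NULL) {
  score_type <- match.arg(score_type)
  stopifnot(inherits(constraints, "constraint_set"))
  if (!all(nodes %in% constraints$nodes)) {
    stopf("nodes must be covered by the constraint set")
  }
  if (is.null(binary_nodes)) {
    binary_nodes <- nodes[vapply(nodes, function(v)
      all(data[[v]] %in% c(0, 1)) && length(unique(data[[v]])) <= 2,
      logical(1))]
  }
  n <- nrow(data)
  # cross-product matrix for fast gaussian scoring
  allvars <- unique(c(nodes,
                      unlist(lapply(nodes, function(ch)
                        constraints$retained$parent[
                          constraints$retained$child == ch]))))
  M <- as.matrix(cbind(`(Intercept)` = rep(1, n),
                       data[, allvars, drop = FALSE]))
  XtX <- crossprod(M)
  gauss_score <- function(child, pa) {
    cols <- c("(Intercept)", pa)
    A <- XtX[cols, cols, drop = FALSE]
    b <- XtX[cols, child]
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) {
      return(structure(-Inf, diagnostic = sprintf(
        "collinear parents for %s", child)))
    }
    z <- backsolve(ch, forwardsolve(t(ch), b))
    rss <- XtX[child, child] - sum(b * z)
    rss <- max(rss, 0)
    sigma2 <- rss / n
    if (sigma2 <= 1e-300) {
      return(structure(-Inf,
                       diagnostic = sprintf("zero residual variance for %s",
                                            child)))
    }
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
    if (score_type == "bic") return(ll - (length(pa) + 2L) / 2 * log(n))
    laplace_gaussian(M[, cols, drop = FALSE], data[[child]], sigma2)
  }
  binom_score <- function(child, pa, eta0) {
    cols <- c("(Intercept)", pa)
    X <- M[, cols, drop = FALSE]
    y <- data[[child]]
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                           etastart = eta0))
    if (any(abs(fit$coefficients[-1]) > 20)) {
      return(structure(-Inf, diagnostic = sprintf(
        "perfect separation fitting %s | {%s}", child,
        paste(pa, collapse = ", "))))
    }
    mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
    ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
    k <- length(pa) + 1L
    if (score_type == "bic") return(ll - k / 2 * log(n))
    laplace_binomial(X, y)
  }
  entries <- new.env(parent = emptyenv())
  sets <- list()
  for (child in nodes) {
    psets <- enumerate_parent_sets(child, setdiff(nodes, child), constraints)
    sets[[child]] <- psets
    eta0 <- NULL
    if (child %in% binary_nodes) {
      # warm start every fit from the smallest (retained-only) model
      ret <- constraints$retained$parent[constraints$retained$child == child]
      base_cols <- c("(Intercept)", sort(ret))
      base <- suppressWarnings(stats::glm.fit(M[, base_cols, drop = FALSE],
                                              data[[child]],
                                              family = stats::binomial()))
      eta0 <- base$linear.predictors
    }
    for (pa in psets) {
      key <- cache_key(child, pa)
      s <- if (child %in% binary_nodes) {
        binom_score(child, pa, eta0)
      } else {
        gauss_score(child, pa)
      }
      assign(key, s, envir = entries)
    }
  }
  structure(list(entries = entries, sets = sets, nodes = nodes,
                 score_type = score_type, n = n,
                 constraints = constraints),
            class = "score_cache")
}

#' Look up a cached family score
#' @param cache a `score_cache`.
#' @param child child node name.
#' @param parent_set parent names.
#' @return the cached score, or `NULL` when the family is not cached.
#' @export
cache_lookup <- function(cache, child, parent_set) {
  key <- cache_key(child, parent_set)
  if (!exists(key, envir = cache$entries, inherits = FALSE)) return(NULL)
  get(key, envir = cache$entries)
}

#' Dump a score cache as a data.frame (child, parents, score)
#' @param cache a `score_cache`.
#' @return data.frame with one row per cached family.
#' @export
cache_as_data_frame <- function(cache) {
  rows <- list()
  for (child in names(cache$sets)) {
    for (pa in cache$sets[[child]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        child = child, parents = paste(pa, collapse = ";"),
        score = as.numeric(cache_lookup(cache, child, pa)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
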