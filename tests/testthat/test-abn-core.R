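test_that("gaussian node score matches the closed-form log-likelihood", {
  dat <- data.frame(y = c(-1, 1, -1, 1))
  s <- node_score("y", character(0), dat, "bic")
  # MLE: mean 0, sigma^2 = 1; k = 2 free parameters
  ll <- sum(dnorm(dat$y, 0, 1, log = TRUE))
  expect_equal(as.numeric(s), ll - (2 / 2) * log(4), tolerance = 1e-12)

  # with one parent the score uses the regression residual variance
  dat2 <- data.frame(y = c(1, 2, 3, 5), x = c(0, 1, 2, 4))
  fit <- lm(y ~ x, dat2)
  s2 <- node_score("y", "x", dat2, "bic")
  sigma2 <- mean(resid(fit)^2)
  ll2 <- -4 / 2 * (log(2 * pi * sigma2) + 1)
  expect_equal(as.numeric(s2), ll2 - (3 / 2) * log(4), tolerance = 1e-10)

  # collinear parents are rejected with -Inf
  dat3 <- data.frame(y = rnorm(10), a = 1:10, b = 2 * (1:10))
  s3 <- node_score("y", c("a", "b"), dat3, "bic")
  expect_identical(as.numeric(s3), -Inf)
  expect_match(attr(s3, "diagnostic"), "collinear")
})

test_that("a pure-noise parent shifts the BIC score by about -log(N)/2", {
  set.seed(202)
  N <- 200
  deltas <- replicate(200, {
    dat <- data.frame(y = rnorm(N), z = rnorm(N))
    node_score("y", "z", dat, "bic") - node_score("y", character(0), dat,
                                                  "bic")
  })
  # E[delta] = E[chisq(1)]/2 - log(N)/2 = 0.5 - log(N)/2
  expect_lt(abs(mean(deltas) - (0.5 - log(N) / 2)), 0.3)
})

test_that("binomial scores detect separation and match glm deviance", {
  set.seed(9)
  dat <- data.frame(x = rnorm(200))
  dat$y <- rbinom(200, 1, plogis(dat$x))
  s <- node_score("y", "x", dat, "bic")
  fit <- glm(y ~ x, dat, family = binomial())
  expect_equal(as.numeric(s), as.numeric(logLik(fit)) - (2 / 2) * log(200),
               tolerance = 1e-6)
  sep <- data.frame(x = c(-2, -1, 1, 2), y = c(0, 0, 1, 1))
  s2 <- node_score("y", "x", sep, "bic")
  expect_identical(as.numeric(s2), -Inf)
  expect_match(attr(s2, "diagnostic"), "separation")
})

test_that("laplace scores are finite and close to BIC at scale", {
  set.seed(12)
  dat <- data.frame(x = rnorm(500))
  dat$y <- 0.5 * dat$x + rnorm(500)
  dat$b <- rbinom(500, 1, plogis(dat$x))
  for (child in c("y", "b")) {
    sl <- node_score(child, "x", dat, "laplace")
    sb <- node_score(child, "x", dat, "bic")
    expect_true(is.finite(sl))
    # Laplace and BIC agree to O(1) at this sample size
    expect_lt(abs(sl - sb), 10)
  }
})

test_that("parent-set enumeration respects bans, retains, and the limit", {
  nodes <- c("a", "b", "c", "d")
  cons <- constraint_set(nodes, max_parents = 2L)
  sets <- enumerate_parent_sets("d", c("a", "b", "c"), cons)
  expect_length(sets, 1 + 3 + 3)

  cons2 <- constraint_set(nodes,
                          banned = data.frame(parent = "a", child = "d"),
                          max_parents = 2L)
  sets2 <- enumerate_parent_sets("d", c("a", "b", "c"), cons2)
  expect_false(any(vapply(sets2, function(s) "a" %in% s, logical(1))))

  cons3 <- constraint_set(nodes,
                          retained = data.frame(parent = "a", child = "d"),
                          max_parents = 1L)
  sets3 <- enumerate_parent_sets("d", c("a", "b", "c"), cons3)
  expect_true(all(vapply(sets3, function(s) "a" %in% s, logical(1))))
  expect_true(all(lengths(sets3) <= 2))   # retained plus at most one more

  # tiers: parents may not come from a higher tier
  cons4 <- constraint_set(nodes, tiers = c(a = 0L, b = 0L, c = 1L, d = 0L),
                          max_parents = 3L)
  sets4 <- enumerate_parent_sets("d", c("a", "b", "c"), cons4)
  expect_false(any(vapply(sets4, function(s) "c" %in% s, logical(1))))
})

test_that("the score cache is exhaustive and pure", {
  set.seed(5)
  nodes <- c("a", "b", "c")
  dat <- as.data.frame(matrix(rnorm(300), 100, 3,
                              dimnames = list(NULL, nodes)))
  cons <- constraint_set(nodes, max_parents = 2L)
  cache <- build_score_cache(dat, nodes, cons, "bic")
  expect_equal(lengths(cache$sets), c(a = 4L, b = 4L, c = 4L))
  # lookups equal fresh scores
  for (child in nodes) for (pa in cache$sets[[child]]) {
    expect_equal(as.numeric(cache_lookup(cache, child, pa)),
                 as.numeric(node_score(child, pa, dat, "bic")),
                 tolerance = 1e-8)
  }
  dump <- cache_as_data_frame(cache)
  expect_equal(nrow(dump), 12L)
  expect_true(all(is.finite(dump$score)))

  # a tier-0 child has only the empty parent set
  cons2 <- constraint_set(nodes, tiers = c(a = 0L, b = 1L, c = 1L),
                          max_parents = 2L)
  cache2 <- build_score_cache(dat, nodes, cons2, "bic")
  expect_length(cache2$sets[["a"]], 1L)
})

test_that("exact search equals brute force and respects constraints", {
  set.seed(71)
  for (i in 1:10) {
    nodes <- c("A", "B", "C", "D")
    n <- 120
    dat <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                                dimnames = list(NULL, nodes)))
    dat$B <- dat$B + runif(1, -1, 1) * dat$A
    dat$D <- dat$D + runif(1, -1, 1) * dat$C
    tiers <- setNames(sample(0:1, 4, replace = TRUE), nodes)
    banned <- data.frame(parent = "A", child = "C")
    cons <- constraint_set(nodes, banned = banned, tiers = tiers,
                           max_parents = 2L)
    cache <- build_score_cache(dat, nodes, cons, "bic")
    d1 <- most_probable_dag(cache)
    d2 <- brute_force_dag(cache)
    expect_equal(d1$total_score, d2$total_score, tolerance = 1e-7)
    expect_identical(d1$arcs, d2$arcs)
    # constraint soundness
    expect_false(any(d1$arcs$parent == "A" & d1$arcs$child == "C"))
    for (r in seq_len(nrow(d1$arcs))) {
      expect_lte(tiers[[d1$arcs$parent[r]]], tiers[[d1$arcs$child[r]]])
    }
    # decomposability
    expect_equal(d1$total_score, sum(d1$per_node_scores), tolerance = 1e-9)
  }
})

test_that("a strong generating arc is recovered and retained arcs are kept", {
  set.seed(88)
  hits <- 0L
  for (i in 1:40) {
    n <- 500
    x <- rnorm(n)
    y <- 2 * x + rnorm(n)
    z <- rnorm(n)
    dat <- data.frame(x = x, y = y, z = z)
    cons <- constraint_set(c("x", "y", "z"),
                           tiers = c(x = 0L, y = 1L, z = 1L),
                           max_parents = 2L)
    dag <- most_probable_dag(build_score_cache(dat, c("x", "y", "z"), cons,
                                               "bic"))
    if (any(dag$arcs$parent == "x" & dag$arcs$child == "y")) hits <- hits + 1L
  }
  expect_gte(hits, 38L)

  set.seed(4)
  dat <- data.frame(a = rnorm(80), b = rnorm(80), c = rnorm(80))
  cons <- constraint_set(c("a", "b", "c"),
                         retained = data.frame(parent = "a", child = "b"),
                         max_parents = 2L)
  dag <- most_probable_dag(build_score_cache(dat, c("a", "b", "c"), cons))
  expect_true(any(dag$arcs$parent == "a" & dag$arcs$child == "b"))
})

test_that("equal scores collapse to the empty graph by tie-break", {
  set.seed(2)
  dat <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  cons <- constraint_set(c("a", "b", "c"), max_parents = 2L)
  cache <- build_score_cache(dat, c("a", "b", "c"), cons, "bic")
  # force a fully degenerate problem: every family gets the same score
  for (key in ls(cache$entries)) assign(key, -1.0, envir = cache$entries)
  d <- most_probable_dag(cache)
  bf <- brute_force_dag(cache)
  expect_equal(nrow(d$arcs), 0L)
  expect_identical(d$arcs, bf$arcs)
})

test_that("parent-limit ladder is monotone in unpenalized likelihood", {
  set.seed(123)
  n <- 300
  dat <- data.frame(a = rnorm(n))
  dat$b <- 0.8 * dat$a + rnorm(n)
  dat$c <- 0.5 * dat$a - 0.5 * dat$b + rnorm(n)
  dat$d <- 0.4 * dat$b + 0.4 * dat$c + rnorm(n)
  nodes <- letters[1:4]
  cons <- constraint_set(nodes, max_parents = 3L)
  fits <- fit_across_parent_limits(dat, nodes, cons, limits = 1:3, "bic")
  expect_length(fits$dags, 3L)
  narcs <- vapply(fits$dags, function(d) nrow(d$arcs), integer(1))
  expect_true(all(diff(narcs) >= 0))
  # refit each selected DAG at the MLE: unpenalized fit cannot decrease
  ll <- vapply(fits$dags, function(d) {
    sum(vapply(nodes, function(ch) {
      pa <- d$parent_sets[[ch]]
      if (is.null(pa)) pa <- character(0)
      s <- node_score(ch, pa, dat, "bic")
      as.numeric(s) + (length(pa) + 2) / 2 * log(n)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-9))

  # a vacuous limit reproduces the unconstrained-parents solution
  fits2 <- fit_across_parent_limits(dat, nodes, cons, limits = c(3L, 5L))
  expect_equal(fits2$dags[["3"]]$total_score, fits2$dags[["5"]]$total_score,
               tolerance = 1e-9)
})

test_that("leveling-off selection follows the documented rule", {
  expect_equal(select_parent_limit(c(-100, -50, -49.9), limits = 1:3,
                                   delta_fraction = 0.01), 2L)
  expect_equal(select_parent_limit(c(-10, -10, -10), limits = 1:3), 1L)
  expect_equal(select_parent_limit(c(-100, -60, -20), limits = 1:3), 3L)
  expect_error(select_parent_limit(c(-1, NaN)), "finite")
  expect_error(select_parent_limit(-5), "two limits")
})

test_that("DAG files round-trip through DOT and GraphML", {
  arcs <- data.frame(parent = c("AGE", "GrimAgeEAA"),
                     child = c("GrimAgeEAA", "DIED"),
                     stringsAsFactors = FALSE)
  for (ext in c(".dot", ".graphml")) {
    f <- tempfile(fileext = ext)
    write_dag(arcs, f)
    back <- read_dag_arcs(f)
    expect_equal(back[order(back$parent), ], arcs[order(arcs$parent), ],
                 ignore_attr = TRUE)
  }
})
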