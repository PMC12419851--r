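# Exact most-probable-DAG search over a decomposable score cache.
#
# Tie-breaking is fully specified so results are reproducible: among DAGs of
# equal total score (absolute tolerance 1e-9), prefer fewer arcs, then the
# lexicographically preferred arc set (candidate arcs ranked alphabetically
# by (parent, child); the arc-indicator vector, read as a binary number with
# rank 1 most significant, is maximized -- i.e. low-ranked arcs are
# preferred). The same key is used by the brute-force oracle.

SCORE_TOL <- 1e-9

# rank lookup for tie values: named vector over "parent\rchild"
arc_ranks <- function(nodes) {
  pairs <- expand.grid(parent = nodes, child = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$parent != pairs$child, ]
  pairs <- pairs[order(pairs$parent, pairs$child), ]
  stats::setNames(2^-(seq_len(nrow(pairs))),
                  paste(pairs$parent, pairs$child, sep = "\r"))
}

tie_value <- function(parent_set, child, ranks) {
  if (!length(parent_set)) return(0)
  keys <- paste(parent_set, child, sep = "\r")
  sum(ranks[keys], na.rm = TRUE)
}

# key comparison: TRUE if (s1, a1, t1) is strictly better
key_better <- function(s1, a1, t1, s2, a2, t2) {
  if (s1 > s2 + SCORE_TOL) return(TRUE)
  if (s2 > s1 + SCORE_TOL) return(FALSE)
  if (a1 != a2) return(a1 < a2)
  t1 > t2
}

new_scored_dag <- function(parent_sets, cache) {
  arcs <- do.call(rbind, lapply(names(parent_sets), function(ch) {
    pa <- parent_sets[[ch]]
    if (!length(pa)) return(NULL)
    data.frame(parent = pa, child = ch, stringsAsFactors = FALSE)
  }))
  if (is.null(arcs)) arcs <- data.frame(parent = character(0),
                                        child = character(0),
                                        stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$parent, arcs$child), , drop = FALSE]
  rownames(arcs) <- NULL
  scores <- vapply(names(parent_sets), function(ch)
    as.numeric(cache_lookup(cache, ch, parent_sets[[ch]])), numeric(1))
  structure(list(arcs = arcs, parent_sets = parent_sets,
                 per_node_scores = scores, total_score = sum(scores)),
            class = "scored_dag")
}

#' @export
print.scored_dag <- function(x, ...) {
  cat(sprintf("scored_dag: %d arcs, total score %.4f\n",
              nrow(x$arcs), x$total_score))
  if (nrow(x$arcs)) {
    cat(paste0("  ", x$arcs$parent, " -> ", x$arcs$child, collapse = "\n"),
        "\n")
  }
  invisible(x)
}

# filter a cache's parent sets to a smaller non-retained parent limit
restrict_cache <- function(cache, limit) {
  out <- cache
  cons <- cache$constraints
  out$sets <- lapply(stats::setNames(names(cache$sets), names(cache$sets)),
                     function(ch) {
    ret <- cons$retained$parent[cons$retained$child == ch]
    Filter(function(pa) length(setdiff(pa, ret)) <= limit, cache$sets[[ch]])
  })
  out
}

#' Globally score-maximal DAG by exact dynamic programming
#'
#' Finds the DAG maximizing the decomposable total score under the cached
#' constraints, by dynamic programming over node subsets: per-node
#' best-parent-set-within-predecessors tables (subset zeta transform)
#' followed by a best-sink decomposition over the `2^n` subsets. Retained
#' parents outside the searched node set (e.g. period dummies) are fixed
#' exogenous covariates and do not enter the acyclicity bookkeeping.
#'
#' @param cache a `score_cache` from [build_score_cache].
#' @param constraints optional [constraint_set]; defaults to the cache's.
#' @param exact_ceiling refuse problems with more nodes than this (memory
#'   for the subset tables grows as `2^n`).
#' @return a `scored_dag`: `arcs`, `parent_sets`, `per_node_scores`,
#'   `total_score`.
#' @export
most_probable_dag <- function(cache, constraints = cache$constraints,
                              exact_ceiling = 25L) {
  nodes <- cache$nodes
  k <- length(nodes)
  if (k > exact_ceiling) {
    stopf(paste0("%d nodes exceeds the exact-search ceiling (%d); restrict ",
                 "the node set or raise exact_ceiling"), k, exact_ceiling)
  }
  ranks <- arc_ranks(union(nodes, unlist(cache$sets)))
  # per-node tables over subsets of the other k-1 nodes
  bps <- vector("list", k)
  for (vi in seq_len(k)) {
    v <- nodes[vi]
    other <- nodes[-vi]
    m_sets <- cache$sets[[v]]
    nm <- 2^(k - 1L)
    s <- rep(-Inf, nm); a <- rep(Inf, nm); tv <- rep(-Inf, nm)
    pick <- vector("list", nm)
    for (pa in m_sets) {
      inpos <- match(intersect(pa, other), other)
      m <- sum(2^(inpos - 1L)) + 1L
      sc <- as.numeric(cache_lookup(cache, v, pa))
      if (!is.finite(sc)) next
      ti <- tie_value(pa, v, ranks)
      if (key_better(sc, length(pa), ti, s[m], a[m], tv[m])) {
        s[m] <- sc; a[m] <- length(pa); tv[m] <- ti; pick[[m]] <- pa
      }
    }
    # subset zeta transform: best over all subsets of each mask
    if (k >= 2L) {
      for (b in seq_len(k - 1L)) {
        bit <- 2^(b - 1L)
        has <- which(bitwAnd(seq_len(nm) - 1L, bit) > 0L)
        src <- has - bit
        repl <- (s[src] > s[has] + SCORE_TOL) |
          (abs(s[src] - s[has]) <= SCORE_TOL &
             (a[src] < a[has] | (a[src] == a[has] & tv[src] > tv[has])))
        repl[is.na(repl)] <- FALSE
        if (any(repl)) {
          hi <- has[repl]; si <- src[repl]
          s[hi] <- s[si]; a[hi] <- a[si]; tv[hi] <- tv[si]
          pick[hi] <- pick[si]
        }
      }
    }
    bps[[vi]] <- list(s = s, a = a, t = tv, pick = pick)
  }
  # best-sink decomposition over subsets of all nodes
  nS <- 2^k
  best_s <- rep(-Inf, nS); best_a <- rep(Inf, nS); best_t <- rep(-Inf, nS)
  best_v <- integer(nS)
  best_s[1] <- 0; best_a[1] <- 0; best_t[1] <- 0
  local_mask <- function(g, vi) {
    # drop bit vi (1-based) from global mask g
    low <- bitwAnd(g, 2^(vi - 1L) - 1L)
    high <- bitwShiftL(bitwShiftR(g, vi), vi - 1L)
    low + high
  }
  for (g in seq_len(nS - 1L)) {
    for (vi in seq_len(k)) {
      bit <- 2^(vi - 1L)
      if (bitwAnd(g, bit) == 0L) next
      rest <- g - bit
      if (!is.finite(best_s[rest + 1L])) next
      lm <- local_mask(rest, vi)
      sv <- bps[[vi]]$s[lm + 1L]
      if (!is.finite(sv)) next
      cs <- best_s[rest + 1L] + sv
      ca <- best_a[rest + 1L] + bps[[vi]]$a[lm + 1L]
      ct <- best_t[rest + 1L] + bps[[vi]]$t[lm + 1L]
      if (key_better(cs, ca, ct, best_s[g + 1L], best_a[g + 1L],
                     best_t[g + 1L])) {
        best_s[g + 1L] <- cs; best_a[g + 1L] <- ca; best_t[g + 1L] <- ct
        best_v[g + 1L] <- vi
      }
    }
  }
  if (!is.finite(best_s[nS])) {
    stopf("no admissible DAG found (all candidate scores non-finite)")
  }
  # reconstruct
  parent_sets <- stats::setNames(vector("list", k), nodes)
  g <- nS - 1L
  while (g > 0L) {
    vi <- best_v[g + 1L]
    bit <- 2^(vi - 1L)
    rest <- g - bit
    lm <- local_mask(rest, vi)
    parent_sets[[nodes[vi]]] <- bps[[vi]]$pick[[lm + 1L]] %||% character(0)
    g <- rest
  }
  new_scored_dag(parent_sets, cache)
}

#' Exhaustive DAG maximization (testing oracle)
#'
#' Enumerates every combination of admissible parent sets over at most five
#' nodes, discards cyclic combinations, and returns the best under the same
#' score / fewest-arcs / lexicographic key as [most_probable_dag].
#'
#' @inheritParams most_probable_dag
#' @return a `scored_dag`.
#' @export
brute_force_dag <- function(cache, constraints = cache$constraints) {
  nodes <- cache$nodes
  if (length(nodes) > 5L) stopf("brute_force_dag is limited to 5 nodes")
  ranks <- arc_ranks(union(nodes, unlist(cache$sets)))
  sets <- cache$sets[nodes]
  idx <- lapply(sets, seq_along)
  grid <- do.call(expand.grid, c(idx, list(KEEP.OUT.ATTRS = FALSE)))
  best <- NULL; bs <- -Inf; ba <- Inf; bt <- -Inf
  for (r in seq_len(nrow(grid))) {
    ps <- stats::setNames(lapply(seq_along(nodes), function(j)
      sets[[j]][[grid[r, j]]]), nodes)
    arcs <- do.call(rbind, lapply(nodes, function(ch) {
      pa <- intersect(ps[[ch]], nodes)
      if (!length(pa)) return(NULL)
      data.frame(parent = pa, child = ch, stringsAsFactors = FALSE)
    }))
    arcs <- arcs %||% data.frame(parent = character(0), child = character(0))
    if (!arcs_acyclic(arcs, nodes)) next
    sc <- vapply(nodes, function(ch)
      as.numeric(cache_lookup(cache, ch, ps[[ch]])), numeric(1))
    if (any(!is.finite(sc))) next
    s <- sum(sc)
    a <- sum(lengths(ps))
    tv <- sum(vapply(nodes, function(ch) tie_value(ps[[ch]], ch, ranks),
                     numeric(1)))
    if (is.null(best) || key_better(s, a, tv, bs, ba, bt)) {
      best <- ps; bs <- s; ba <- a; bt <- tv
    }
  }
  if (is.null(best)) stopf("no admissible acyclic DAG found")
  new_scored_dag(best, cache)
}

#' Exact solutions across a ladder of parent limits
#'
#' Builds one score cache at the largest limit, restricts it to each limit in
#' turn, and solves each restricted problem exactly. The resulting total
#' scores form the trajectory that [select_parent_limit] applies the
#' leveling-off rule to.
#'
#' @param data data.frame of node columns.
#' @param nodes node names to search over.
#' @param constraints a [constraint_set] whose `max_parents` is at least
#'   `max(limits)`.
#' @param limits ascending integer parent limits (default 1:3).
#' @param score_type `"bic"` or `"laplace"`.
#' @return list with `dags` (one `scored_dag` per limit, named by limit),
#'   `scores` (numeric trajectory), `limits`.
#' @export
fit_across_parent_limits <- function(data, nodes, constraints,
                                     limits = 1:3,
                                     score_type = c("bic", "laplace")) {
  score_type <- match.arg(score_type)
  limits <- as.integer(limits)
  if (is.unsorted(limits, strictly = TRUE)) stopf("limits must be ascending")
  if (constraints$max_parents < max(limits)) {
    cons <- constraints
    cons$max_parents <- max(limits)
    constraints <- cons
  }
  cache <- build_score_cache(data, nodes, constraints, score_type)
  dags <- lapply(limits, function(L) most_probable_dag(restrict_cache(cache, L)))
  names(dags) <- as.character(limits)
  scores <- vapply(dags, function(d) d$total_score, numeric(1))
  list(dags = dags, scores = scores, limits = limits)
}

#' Leveling-off choice of the parent limit
#'
#' Returns the smallest limit `L` whose gain to the next limit,
#' `score(L+1) - score(L)`, is at most `delta_fraction` of the total score
#' range `max(1, score(last) - score(first))`; if the fit never levels off,
#' the largest limit is returned.
#'
#' @param scores numeric score trajectory (one per limit, ascending limits).
#' @param limits the corresponding limits; defaults to `seq_along(scores)`.
#' @param delta_fraction leveling threshold as a fraction of the score range.
#' @return the chosen limit.
#' @export
select_parent_limit <- function(scores, limits = seq_along(scores),
                                delta_fraction = 0.01) {
  if (length(scores) < 2L) stopf("need scores for at least two limits")
  if (any(!is.finite(scores))) stopf("non-finite scores")
  rng <- max(1, scores[length(scores)] - scores[1])
  thr <- delta_fraction * rng
  for (i in seq_len(length(scores) - 1L)) {
    if (scores[i + 1L] - scores[i] <= thr) return(limits[i])
  }
  limits[length(limits)]
}

#' Export a DAG as DOT or GraphML
#'
#' @param dag a `scored_dag` or any object with an `arcs` data.frame.
#' @param path output path (`.dot` / `.gv` or `.graphml`).
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path) {
  arcs <- if (is.data.frame(dag)) dag else dag$arcs
  nodes <- sort(unique(c(arcs$parent, arcs$child)))
  if (grepl("\\.(dot|gv)$", path, ignore.case = TRUE)) {
    lines <- c("digraph abn {",
               sprintf('  "%s";', nodes),
               sprintf('  "%s" -> "%s";', arcs$parent, arcs$child),
               "}")
    writeLines(lines, path)
  } else if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <graph id="abn" edgedefault="directed">',
      sprintf('    <node id="%s"/>', nodes),
      sprintf('    <edge source="%s" target="%s"/>', arcs$parent, arcs$child),
      '  </graph>', '</graphml>')
    writeLines(lines, path)
  } else stopf("unsupported extension in %s (use .dot or .graphml)", path)
  invisible(path)
}

#' Read arcs back from a DOT or GraphML file
#' @param path file written by [write_dag].
#' @return data.frame with columns `parent`, `child`.
#' @export
read_dag_arcs <- function(path) {
  lines <- readLines(path)
  if (grepl("\\.(dot|gv)$", path, ignore.case = TRUE)) {
    hit <- regmatches(lines, regexec('"([^"]+)" -> "([^"]+)"', lines))
    hit <- Filter(function(m) length(m) == 3L, hit)
    data.frame(parent = vapply(hit, `[`, "", 2L),
               child = vapply(hit, `[`, "", 3L), stringsAsFactors = FALSE)
  } else {
    hit <- regmatches(lines,
                      regexec('source="([^"]+)" target="([^"]+)"', lines))
    hit <- Filter(function(m) length(m) == 3L, hit)
    data.frame(parent = vapply(hit, `[`, "", 2L),
               child = vapply(hit, `[`, "", 3L), stringsAsFactors = FALSE)
  }
}
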