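#' Structure-search constraints
#'
#' Bundles the prior constraints for DAG search: banned arcs (never present),
#' retained arcs (forced into every solution; not counted against the parent
#' limit), a tier assignment (arcs may run from a lower or equal tier to a
#' higher or equal one, never from a higher tier down), and the maximum
#' number of non-retained parents per child.
#'
#' @param nodes character vector of node names.
#' @param banned data.frame with columns `parent`, `child`, or `NULL`.
#' @param retained data.frame with columns `parent`, `child`, or `NULL`.
#' @param tiers named integer vector over `nodes`; defaults to all zero.
#' @param max_parents positive integer parent limit.
#' @return an object of class `constraint_set`.
#' @export
constraint_set <- function(nodes, banned = NULL, retained = NULL,
                           tiers = NULL, max_parents = 3L) {
  empty <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  banned <- banned %||% empty
  retained <- retained %||% empty
  if (is.null(tiers)) tiers <- stats::setNames(rep(0L, length(nodes)), nodes)
  if (!all(nodes %in% names(tiers))) stopf("tiers must cover every node")
  max_parents <- as.integer(max_parents)
  if (is.na(max_parents) || max_parents < 1L) stopf("max_parents must be >= 1")
  arc_key <- function(df) paste(df$parent, df$child, sep = "\r")
  if (length(intersect(arc_key(banned), arc_key(retained)))) {
    stopf("banned and retained arc sets must be disjoint")
  }
  for (i in seq_len(nrow(retained))) {
    p <- retained$parent[i]; ch <- retained$child[i]
    if (tiers[[p]] > tiers[[ch]]) {
      stopf("retained arc %s -> %s violates the tier ordering", p, ch)
    }
  }
  # retained arcs alone must be acyclic
  if (nrow(retained) && !arcs_acyclic(retained, nodes)) {
    stopf("retained arcs alone contain a cycle")
  }
  structure(list(nodes = nodes, banned = banned, retained = retained,
                 tiers = tiers[nodes], max_parents = max_parents),
            class = "constraint_set")
}

arc_in <- function(df, parent, child) {
  any(df$parent == parent & df$child == child)
}

# Deterministic (lexicographic Kahn) topological order over an arc frame.
topo_order_arcs <- function(arcs, nodes) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(arcs)) {
    tb <- table(arcs$child)
    indeg[names(tb)] <- as.integer(tb)
  }
  out <- character(0)
  avail <- nodes[indeg == 0L]
  while (length(avail)) {
    v <- sort(avail)[1L]
    avail <- setdiff(avail, v)
    out <- c(out, v)
    for (k in arcs$child[arcs$parent == v]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
  }
  if (length(out) != length(nodes)) stopf("arc set contains a cycle")
  out
}

# Kahn's algorithm over an arc data.frame; TRUE if acyclic.
arcs_acyclic <- function(arcs, nodes) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(arcs)) {
    tb <- table(arcs$child)
    indeg[names(tb)] <- as.integer(tb)
  }
  avail <- nodes[indeg == 0L]
  done <- 0L
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]; done <- done + 1L
    for (k in arcs$child[arcs$parent == v]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
  }
  done == length(nodes)
}

#' Default constraints for the mortality network
#'
#' The tier scheme used throughout: demographics (tier 0, never children),
#' biomarkers (tier 1, free arcs in either direction within the tier), and
#' the death indicator (tier 2, childless). Period dummies, when present, are
#' retained as parents of the death node only and banned everywhere else;
#' retained arcs do not count against `max_parents`.
#'
#' @param nodes node names to constrain (defaults to the full roster).
#' @param period_dummies character vector of period-dummy column names
#'   (e.g. `PER_2 .. PER_K`; the reference dummy should be excluded).
#' @param max_parents parent limit (default 3).
#' @return a [constraint_set].
#' @export
default_abn_constraints <- function(nodes = c(DEMOGRAPHIC_NODES,
                                              BIOMARKER_NODES, SURVIVAL_NODE),
                                    period_dummies = character(0),
                                    max_parents = 3L) {
  all_nodes <- c(nodes, period_dummies)
  tiers <- stats::setNames(rep(1L, length(all_nodes)), all_nodes)
  tiers[intersect(DEMOGRAPHIC_NODES, all_nodes)] <- 0L
  tiers[intersect(SURVIVAL_NODE, all_nodes)] <- 2L
  tiers[period_dummies] <- 0L
  banned <- expand.grid(parent = all_nodes,
                        child = intersect(c(DEMOGRAPHIC_NODES, period_dummies),
                                          all_nodes),
                        stringsAsFactors = FALSE)
  if (length(period_dummies)) {
    # period dummies may only point at the death node
    extra <- expand.grid(parent = period_dummies,
                         child = setdiff(all_nodes, SURVIVAL_NODE),
                         stringsAsFactors = FALSE)
    banned <- rbind(banned, extra)
    retained <- data.frame(parent = period_dummies, child = SURVIVAL_NODE,
                           stringsAsFactors = FALSE)
  } else {
    retained <- NULL
  }
  banned <- banned[banned$parent != banned$child, , drop = FALSE]
  banned <- unique(banned)
  constraint_set(all_nodes, banned = banned, retained = retained,
                 tiers = tiers, max_parents = max_parents)
}

#' Admissible parent sets for a child
#'
#' All subsets of the admissible candidates (tier-respecting, not banned,
#' not the child itself) of size at most `max_parents`, each unioned with the
#' child's retained parents. Order is deterministic: by subset size, then
#' lexicographic.
#'
#' @param child child node name.
#' @param candidates candidate parent names.
#' @param constraints a [constraint_set].
#' @return list of character vectors (possibly including `character(0)`).
#' @export
enumerate_parent_sets <- function(child, candidates, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  tiers <- constraints$tiers
  retained <- constraints$retained$parent[constraints$retained$child == child]
  cand <- setdiff(candidates, c(child, retained))
  cand <- cand[vapply(cand, function(p) {
    tiers[[p]] <= tiers[[child]] && !arc_in(constraints$banned, p, child)
  }, logical(1))]
  cand <- sort(cand)
  sets <- list(character(0))
  for (k in seq_len(min(constraints$max_parents, length(cand)))) {
    cmb <- utils::combn(cand, k, simplify = FALSE)
    sets <- c(sets, cmb)
  }
  lapply(sets, function(s) sort(c(retained, s)))
}
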