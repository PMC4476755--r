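new_assignment <- function(membership, samples, modularity, level) {
  names(membership) <- samples
  structure(list(membership = membership, modularity = modularity,
                 level = level),
            class = "community_assignment")
}

# Relabel community ids to consecutive integers 0, 1, ... ordered by the
# smallest vertex index each community contains.
relabel_membership <- function(mem) {
  first <- tapply(seq_along(mem), mem, min)
  ord <- names(sort(first))
  as.integer(match(as.character(mem), ord) - 1L)
}

#' @export
print.community_assignment <- function(x, ...) {
  k <- length(unique(x$membership))
  cat(sprintf("community_assignment (%s): %d groups over %d individuals, Q = %s\n",
              x$level, k, length(x$membership),
              format(x$modularity, digits = 4)))
  print(table(size = tabulate(x$membership + 1L)))
  invisible(x)
}

#' Unconnected components of the triad graph
#'
#' The coarsest substructure level: maximal connected subgraphs. With data
#' from discrete populations these already form a valid partition into
#' ancestry groups. Labels are consecutive integers from 0, ordered by the
#' smallest vertex index in each component.
#'
#' @param tg a [build_triad_graph()] result.
#' @return a `community_assignment` with `level = "components"` (its
#'   modularity is `NA` for an edgeless graph).
#' @export
connected_components <- function(tg) {
  comp <- igraph::components(tg$graph)
  mem <- relabel_membership(comp$membership)
  q <- if (igraph::ecount(tg$graph) > 0) modularity_q(tg, mem) else NA_real_
  new_assignment(mem, tg$samples, q, "components")
}

#' Modularity of a partition (own implementation)
#'
#' Quality of a division of the graph into communities: the fraction of
#' edges falling within communities minus the expectation of that fraction
#' under random wiring with the same community degree totals,
#' `Q = sum_i (e_ii - a_i^2)` over the community-by-community edge-fraction
#' matrix `e` with row sums `a`. Each edge is counted once; edge weights are
#' honored when the graph keeps multiplicities. This implementation is
#' deliberately independent of igraph's and is asserted against it inside
#' [louvain()].
#'
#' @param tg a [build_triad_graph()] result.
#' @param membership a `community_assignment` or an integer label vector
#'   covering all vertices.
#' @return modularity Q in `[-1, 1]`.
#' @export
modularity_q <- function(tg, membership) {
  if (inherits(membership, "community_assignment"))
    membership <- membership$membership
  g <- tg$graph
  if (length(membership) != igraph::vcount(g))
    stop("membership must cover every vertex", call. = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0)
    stop("modularity is undefined for a graph with no edges", call. = FALSE)
  w <- igraph::E(g)$weight %||% rep(1, nrow(el))
  m <- sum(w)
  ci <- membership[el[, 1]]
  cj <- membership[el[, 2]]
  labs <- sort(unique(as.vector(membership)))
  within <- vapply(labs, function(cc) sum(w[ci == cc & cj == cc]), numeric(1))
  ends <- vapply(labs, function(cc) sum(w[ci == cc]) + sum(w[cj == cc]),
                 numeric(1))
  sum(within / m - (ends / (2 * m))^2)
}

#' Louvain community detection on the triad graph
#'
#' Two-phase greedy modularity maximization (local moves to the neighboring
#' community with the largest positive gain, then community aggregation,
#' iterated until no further gain). Communities always refine the
#' unconnected components, so running on the whole graph detects structure
#' within each component automatically. The result is deterministic for a
#' given `seed`. The returned modularity is computed by this package's own
#' implementation ([modularity_q()]) and asserted against the backing
#' library's value on every call.
#'
#' @param tg a [build_triad_graph()] result with at least one edge.
#' @param seed integer seed controlling the sweep order.
#' @return a `community_assignment` with `level = "louvain"`, labels
#'   consecutive from 0 ordered by smallest vertex index.
#' @export
louvain <- function(tg, seed = 1L) {
  g <- tg$graph
  if (igraph::ecount(g) == 0)
    stop("modularity is undefined for a graph with no edges", call. = FALSE)
  cl <- with_seed(seed, igraph::cluster_louvain(g))
  mem <- relabel_membership(igraph::membership(cl))
  q_own <- modularity_q(tg, mem)
  q_lib <- igraph::modularity(g, mem + 1L, weights = igraph::E(g)$weight)
  if (!isTRUE(abs(q_own - q_lib) < 1e-8))
    stop(sprintf("modularity cross-check failed: own %.10f vs library %.10f",
                 q_own, q_lib), call. = FALSE)
  new_assignment(mem, tg$samples, q_own, "louvain")
}

#' Export a community assignment
#'
#' Two-column delimited file: sample identifier, community label. The same
#' format serves components and Louvain communities.
#'
#' @param a a `community_assignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(a, path) {
  write.table(data.frame(sample = names(a$membership),
                         community = a$membership),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
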