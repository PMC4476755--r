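#' Rank every other individual by similarity
#'
#' For each individual i, all other individuals are ranked by their
#' covariance with i in descending order: rank 1 is the most similar, ties
#' receive the average of the tied positions (computed on exact equality of
#' covariance values, no epsilon). The self-comparison is excluded (`NA` on
#' the diagonal).
#'
#' @param d symmetric `n x n` similarity matrix, `n >= 3`.
#' @return `n x n` matrix `R` of class `rank_table` with `R[i, j]` the rank
#'   of j from i's point of view; each row (diagonal excluded) is a tied
#'   ranking of `1..n-1`.
#' @export
rank_individuals <- function(d) {
  n <- nrow(d)
  if (is.null(n) || n < 3)
    stop("triads require at least 3 individuals", call. = FALSE)
  if (n != ncol(d)) stop("similarity matrix must be square", call. = FALSE)
  R <- matrix(NA_real_, n, n, dimnames = dimnames(d))
  for (i in seq_len(n))
    R[i, -i] <- rank(-d[i, -i], ties.method = "average")
  class(R) <- c("rank_table", class(R))
  R
}

# Symmetrized rank sums S[i, j] = rank_i[j] + rank_j[i], with +Inf on the
# diagonal so argmin never selects the self-pair.
rank_sums <- function(ranks) {
  S <- unclass(ranks) + t(unclass(ranks))
  diag(S) <- Inf
  S
}

#' Closest partner of an individual under two-sided rank minimization
#'
#' Returns the j minimizing `rank_i[j] + rank_j[i]`: j must be close to i
#' *and* i close to j, which makes the pairing robust against one-sided
#' neighbors. Ties break to the smallest index.
#'
#' @param i individual index.
#' @param ranks a [rank_individuals()] table.
#' @return index of the partner j.
#' @export
closest_partner <- function(i, ranks) {
  S <- rank_sums(ranks)
  which.min(S[i, ])
}

#' Third triad member for a dyad
#'
#' Returns the k (distinct from i and j) minimizing
#' `rank_i[k] + rank_k[i] + rank_j[k] + rank_k[j]`, i.e. the individual
#' closest to *both* members of the dyad. Ties break to the smallest index.
#' With only three individuals the single remaining one is returned.
#'
#' @param i,j the dyad, `i != j`.
#' @param ranks a [rank_individuals()] table.
#' @return index of the third member k.
#' @export
third_member <- function(i, j, ranks) {
  if (i == j) stop("i and j must differ", call. = FALSE)
  S <- rank_sums(ranks)
  v <- S[i, ] + S[j, ]
  v[c(i, j)] <- Inf
  which.min(v)
}

#' Build the triad graph of a sample
#'
#' One triad is built per individual i: its closest partner j (two-sided
#' rank minimization) and the third member k closest to both. The n triads
#' (3 edges each) are merged into one undirected graph on the n individuals
#' -- at most `3n` edges; duplicates collapse into a simple graph by
#' default, or are retained as integer edge weights (multiplicities) with
#' `keep_multiplicity = TRUE`. The graph's unconnected components and
#' communities are the substructure levels used downstream.
#'
#' @param d symmetric similarity matrix (larger = more similar), `n >= 3`.
#' @param keep_multiplicity keep duplicate-edge counts as edge weights.
#' @return object of class `triad_graph`: list with `graph` (an
#'   [igraph][igraph::graph] object), `triads` (`data.frame` of anchor,
#'   partner, third), `samples`.
#' @examples
#' d <- tcrossprod(matrix(rnorm(60), 6))
#' tg <- build_triad_graph(d)
#' tg$triads
#' @export
build_triad_graph <- function(d, keep_multiplicity = FALSE) {
  ranks <- rank_individuals(d)
  n <- nrow(ranks)
  S <- rank_sums(ranks)
  j <- max.col(-S, ties.method = "first")
  A <- S + S[j, , drop = FALSE]
  A[cbind(seq_len(n), seq_len(n))] <- Inf
  A[cbind(seq_len(n), j)] <- Inf
  k <- max.col(-A, ties.method = "first")
  triads <- data.frame(anchor = seq_len(n), partner = j, third = k)
  el <- rbind(cbind(triads$anchor, triads$partner),
              cbind(triads$partner, triads$third),
              cbind(triads$anchor, triads$third))
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  ig <- igraph::make_graph(as.vector(t(el)), n = n, directed = FALSE)
  if (keep_multiplicity) {
    igraph::E(ig)$weight <- 1
    ig <- igraph::simplify(ig, edge.attr.comb = list(weight = "sum"))
  } else {
    ig <- igraph::simplify(ig)
  }
  samples <- rownames(d) %||% as.character(seq_len(n))
  igraph::V(ig)$name <- samples
  structure(list(graph = ig, triads = triads, samples = samples,
                 keep_multiplicity = keep_multiplicity),
            class = "triad_graph")
}

#' @export
print.triad_graph <- function(x, ...) {
  cat(sprintf("triad_graph: %d individuals, %d unique edges from %d triads%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              nrow(x$triads),
              if (isTRUE(x$keep_multiplicity)) " (weighted by multiplicity)" else ""))
  invisible(x)
}

#' Export a triad graph for external viewers
#'
#' `write_edge_list()` writes a two-column delimited file of sample-id
#' pairs; `write_graphml()` writes GraphML via igraph.
#'
#' @param tg a [build_triad_graph()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(tg, path) {
  el <- igraph::as_edgelist(tg$graph, names = TRUE)
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = c("from", "to"))
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(tg, path) {
  igraph::write_graph(tg$graph, path, format = "graphml")
  invisible(path)
}
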