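# Small fixtures built in code.

# Genotype matrix with known coordinates for region/MAF tests.
toy_gm <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  genotype_matrix(dosages,
                  variants = data.frame(
                    chrom = chrom %||% rep("chr1", m),
                    pos = pos %||% (seq_len(m) * 10L),
                    id = paste0("v", seq_len(m)),
                    ref = "A", alt = "G", stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Block-structured similarity: within-block similarity >> between-block.
block_cov <- function(sizes, within = 0.9, between = 0.1, jitter = 0.001,
                      seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  d[outer(lab, lab, "==")] <- within
  set.seed(seed)
  noise <- matrix(rnorm(n * n, sd = jitter), n)
  d <- d + (noise + t(noise)) / 2
  diag(d) <- 1
  (d + t(d)) / 2
}

# Wrap an arbitrary igraph into the triad_graph container (for component /
# modularity tests on hand-built graphs).
fake_tg <- function(ig) {
  structure(list(graph = ig,
                 triads = NULL,
                 samples = as.character(seq_len(igraph::vcount(ig))),
                 keep_multiplicity = FALSE),
            class = "triad_graph")
}

two_triangle_tg <- function() {
  fake_tg(igraph::make_graph(c(1, 2, 2, 3, 1, 3, 4, 5, 5, 6, 4, 6),
                             directed = FALSE))
}

# Confounded case/control set: y correlated with a two-population split,
# differentiated null SNPs (no true effect).
stratified_nulls <- function(n_per = 150, m = 600, f = c(0.8, 0.2),
                             seed = 42) {
  set.seed(seed)
  pop <- rep(c(1, 2, 1, 2), c(0.8, 0.2, 0.2, 0.8) * n_per)
  y <- rep(c(1, 0), each = n_per)
  X <- matrix(rbinom(length(pop) * m, 2, f[pop]), length(pop), m)
  list(X = X, y = y, pop = pop)
}
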