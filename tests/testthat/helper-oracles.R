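# Independent brute-force oracles used to validate the fast implementations.
# Everything here is written with plain loops and first-principles formulas,
# deliberately avoiding the code paths under test.

# Average-tie ranks computed by counting, not by rank():
# rank of j from i = #(others strictly more similar) + (#(ties incl. j) + 1)/2.
oracle_rank_table <- function(d) {
  n <- nrow(d)
  R <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    for (j in others) {
      v <- d[i, others]
      R[i, j] <- sum(v > d[i, j]) + (sum(v == d[i, j]) + 1) / 2
    }
  }
  R
}

# Literal two-step triad construction: exhaustive minimization of the
# two-sided rank sums, ties to the smallest index (strict < while scanning
# ascending indices).
oracle_triads <- function(d) {
  R <- oracle_rank_table(d)
  n <- nrow(d)
  out <- matrix(NA_integer_, n, 3)
  for (i in seq_len(n)) {
    best <- Inf; bj <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      s <- R[i, j] + R[j, i]
      if (s < best) { best <- s; bj <- j }
    }
    bestk <- Inf; bk <- NA_integer_
    for (k in seq_len(n)) {
      if (k == i || k == bj) next
      s <- R[i, k] + R[k, i] + R[bj, k] + R[k, bj]
      if (s < bestk) { bestk <- s; bk <- k }
    }
    out[i, ] <- c(i, bj, bk)
  }
  out
}

oracle_edge_set <- function(triads) {
  el <- rbind(cbind(triads[, 1], triads[, 2]),
              cbind(triads[, 2], triads[, 3]),
              cbind(triads[, 1], triads[, 3]))
  el <- unique(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

edge_set_of <- function(tg) {
  el <- igraph::as_edgelist(tg$graph, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# Random symmetric similarity matrix (a covariance of random data, so ties
# are absent almost surely).
rand_cov <- function(n) {
  x <- matrix(rnorm(n * (n + 2)), n)
  d <- tcrossprod(x) / (n + 2)
  (d + t(d)) / 2
}

# Connected components by transitive closure of the boolean adjacency
# matrix (Warshall), labels by smallest contained vertex.
oracle_components <- function(el, n) {
  A <- diag(TRUE, n)
  for (r in seq_len(nrow(el))) {
    A[el[r, 1], el[r, 2]] <- TRUE
    A[el[r, 2], el[r, 1]] <- TRUE
  }
  for (k in seq_len(n)) A <- A | (A[, k] %o% A[k, ])
  lab <- apply(A, 1, function(row) min(which(row)))
  as.integer(match(lab, sort(unique(lab))) - 1L)
}

# Exhaustive single-window greedy LD pruning for small panels.
oracle_ld_prune <- function(dos, r2_max) {
  m <- ncol(dos)
  keep <- rep(TRUE, m)
  for (a in seq_len(m - 1)) {
    if (!keep[a]) next
    for (b in (a + 1):m) {
      if (!keep[b]) next
      r <- suppressWarnings(cor(dos[, a], dos[, b],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) keep[b] <- FALSE
    }
  }
  keep
}

# Direct maximum-likelihood logistic fit by numerical optimization, as an
# oracle independent of IRLS; returns the slope of x and the LRT p-value.
oracle_logistic <- function(x, y, E = NULL) {
  loglik <- function(beta, M) {
    eta <- drop(M %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  fit_ml <- function(M) {
    opt <- optim(rep(0, ncol(M)), fn = loglik, M = M,
                 method = "BFGS",
                 control = list(fnscale = -1, maxit = 500, reltol = 1e-14))
    opt
  }
  Mnull <- cbind(rep(1, length(y)), E)
  Mfull <- cbind(Mnull, x)
  f0 <- fit_ml(Mnull)
  f1 <- fit_ml(Mfull)
  stat <- max(0, 2 * (f1$value - f0$value))
  list(beta = f1$par[length(f1$par)],
       p = pchisq(stat, 1, lower.tail = FALSE))
}

# Hudson-style ratio-of-averages Fst estimator from two population samples
# of genotype dosages (rows = individuals).
oracle_fst <- function(g1, g2) {
  n1 <- 2 * nrow(g1); n2 <- 2 * nrow(g2)
  p1 <- colMeans(g1) / 2; p2 <- colMeans(g2) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
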