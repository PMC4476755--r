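#' Price-style genotype normalization
#'
#' Centers each variant column at its mean over non-missing calls and scales
#' it by `sqrt(p(1-p))`, where `p` is by default the posterior allele
#' frequency estimate `(1 + allele count) / (2 + 2 * calls)` (the smoothed
#' estimator used with the genetic covariance matrix; `freq = "sample"` uses
#' the plain sample frequency instead -- the downstream rank-based graph is
#' insensitive to the choice). Missing entries contribute 0 after centering.
#' Columns with zero variance carry no ancestry information and are dropped
#' with a notice.
#'
#' @param g a [genotype_matrix()]; every variant needs at least one
#'   non-missing call.
#' @param freq `"posterior"` (default) or `"sample"` allele-frequency
#'   estimator for the scaling denominator.
#' @return numeric `n x m'` matrix of normalized dosages (rows named by
#'   sample), `m' <= m` after dropping zero-variance columns.
#' @export
normalize_genotypes <- function(g, freq = c("posterior", "sample")) {
  freq <- match.arg(freq)
  M <- g$dosages
  calls <- colSums(!is.na(M))
  if (any(calls == 0))
    stop("every variant needs at least one non-missing call", call. = FALSE)
  s <- colSums(M, na.rm = TRUE)
  mu <- s / calls
  cx <- sweep(M, 2, mu)
  var0 <- colSums(cx^2, na.rm = TRUE) == 0
  if (all(var0))
    stop("all variants have zero variance; nothing to normalize", call. = FALSE)
  if (any(var0))
    message(sprintf("normalize_genotypes: dropping %d zero-variance variant(s)",
                    sum(var0)))
  p <- if (freq == "posterior") (1 + s) / (2 + 2 * calls) else s / (2 * calls)
  den <- sqrt(p * (1 - p))
  X <- sweep(cx, 2, den, "/")
  X[is.na(X)] <- 0
  X <- X[, !var0, drop = FALSE]
  rownames(X) <- g$samples
  X
}

#' Genetic covariance matrix between individuals
#'
#' `D = X X' / m` for the normalized genotype matrix `X`: the `n x n`
#' individual-by-individual covariance matrix whose entry `D[i, j]` measures
#' the genetic similarity of individuals i and j. The result is exactly
#' symmetrized. The `1/m` scaling makes values comparable across SNP panels;
#' every downstream consumer in this package is rank-based and therefore
#' scale-invariant. Any other similarity matrix (larger = more similar) can
#' be substituted downstream; negate distance-type measures first.
#'
#' @param x normalized `n x m` matrix from [normalize_genotypes()].
#' @return symmetric `n x n` matrix with sample ids as dimnames.
#' @seealso [genetic_covariance()] for the one-call convenience wrapper.
#' @export
covariance_matrix <- function(x) {
  if (ncol(x) < 1) stop("need at least one variant column", call. = FALSE)
  D <- tcrossprod(x) / ncol(x)
  D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}

#' @rdname covariance_matrix
#' @param g a [genotype_matrix()].
#' @param ... passed to [normalize_genotypes()].
#' @export
genetic_covariance <- function(g, ...) {
  covariance_matrix(normalize_genotypes(g, ...))
}

#' Write / read a similarity matrix as a square delimited file
#'
#' @param d symmetric matrix with sample-id dimnames.
#' @param path file path.
#' @return the matrix (read) or `path`, invisibly (write).
#' @export
write_similarity <- function(d, path) {
  write.table(data.frame(id = rownames(d), d, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(tab[, -1, drop = FALSE])
  rownames(d) <- as.character(tab[[1]])
  d <- (d + t(d)) / 2
  d
}

#' Principal components of the genetic covariance matrix
#'
#' Top-k eigenvectors of `D`, the continuous ancestry covariates of the
#' EIGENSTRAT-style comparator. Eigenvalues are returned in nonincreasing
#' order and each component's sign is fixed so that its largest-magnitude
#' loading is positive, making the covariates reproducible across runs.
#'
#' @param d symmetric similarity matrix.
#' @param k number of components, `1 <= k < n`.
#' @return object of class `principal_components`: list with `vectors`
#'   (`n x k`), `values` (length k, nonincreasing), `samples`.
#' @export
principal_components <- function(d, k) {
  n <- nrow(d)
  if (k < 1 || k >= n)
    stop("k must satisfy 1 <= k < n", call. = FALSE)
  e <- eigen(d, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(vec[, j]))
    if (vec[i0, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- rownames(d)
  colnames(vec) <- paste0("PC", seq_len(k))
  structure(list(vectors = vec, values = e$values[seq_len(k)],
                 samples = rownames(d)),
            class = "principal_components")
}

#' @export
print.principal_components <- function(x, ...) {
  cat(sprintf("principal_components: %d samples, %d components\n",
              nrow(x$vectors), ncol(x$vectors)))
  cat("eigenvalues:", format(x$values, digits = 4), "\n")
  invisible(x)
}
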