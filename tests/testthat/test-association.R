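fake_assignment <- function(mem) {
  structure(list(membership = setNames(as.integer(mem),
                                       paste0("s", seq_along(mem))),
                 modularity = NA_real_, level = "test"),
            class = "community_assignment")
}

test_that("dummy encoding drops the largest community as reference", {
  mem <- rep(0:2, c(30, 50, 20))
  cs <- dummy_encode(fake_assignment(mem))
  expect_equal(cs$kind, "dummies")
  expect_equal(colnames(cs$values), c("community_0", "community_2"))
  expect_true(all(rowSums(cs$values) %in% c(0, 1)))
  expect_equal(colSums(cs$values), c(community_0 = 30, community_2 = 20))
  # tie in sizes: lowest label wins the reference slot
  cs2 <- dummy_encode(fake_assignment(rep(0:1, c(25, 25))))
  expect_equal(colnames(cs2$values), "community_1")
  # single community: empty set, equivalent to "none"
  cs3 <- dummy_encode(fake_assignment(rep(0, 40)))
  expect_equal(cs3$kind, "none")
  expect_equal(ncol(cs3$values), 0)
})

test_that("covariate sets drop constant and collinear columns with a notice", {
  set.seed(40)
  M <- cbind(a = rnorm(30), b = rep(2, 30))
  expect_message(cs <- covariate_set(M, "pcs"), "constant")
  expect_equal(colnames(cs$values), "a")
  M2 <- cbind(a = rnorm(30), b = rnorm(30))
  M2 <- cbind(M2, c = M2[, 1] - 2 * M2[, 2])
  expect_message(cs2 <- covariate_set(M2, "pcs"), "collinear")
  expect_equal(ncol(cs2$values), 2)
})

test_that("LRT fits match a direct maximum-likelihood oracle to 6 decimals", {
  set.seed(41)
  n <- 20
  E <- matrix(rnorm(n), ncol = 1)
  x <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x + 0.5 * E[, 1]))
  g <- genotype_matrix(matrix(x, ncol = 1))
  res <- logistic_assoc(g, y, covariate_set(E, "pcs"), method = "lrt")
  want <- oracle_logistic(x, y, E)
  expect_equal(res$results$beta, want$beta, tolerance = 1e-6)
  expect_equal(res$results$p, want$p, tolerance = 1e-6)
  expect_true(res$results$converged)
  # also without covariates
  res0 <- logistic_assoc(g, y, NULL, method = "lrt")
  want0 <- oracle_logistic(x, y, NULL)
  expect_equal(res0$results$beta, want0$beta, tolerance = 1e-6)
  expect_equal(res0$results$p, want0$p, tolerance = 1e-6)
})

test_that("score and LRT p-values agree closely on a simulated panel", {
  set.seed(42)
  n <- 300; m <- 150
  X <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rbinom(n, 1, plogis(-0.2 + 0.25 * X[, 1] + 0.2 * X[, 2]))
  E <- covariate_set(matrix(rnorm(n), ncol = 1), "pcs")
  ps <- logistic_assoc(X, y, E, method = "score")$results$p
  pl <- logistic_assoc(X, y, E, method = "lrt")$results$p
  expect_lt(max(abs(ps - pl)), 0.01)
})

test_that("the type-I error rate under the null matches alpha", {
  set.seed(43)
  n <- 400; m <- 4000
  X <- matrix(rbinom(n * m, 2, 0.35), n, m)
  y <- rep(c(1, 0), each = n / 2)
  res <- logistic_assoc(X, y, NULL, alpha = 0.05, method = "score")
  expect_gt(res$prop_significant, 0.036)
  expect_lt(res$prop_significant, 0.064)
})

test_that("degenerate SNPs are flagged, never silently reported", {
  set.seed(44)
  n <- 60
  X <- cbind(rep(2, n), rbinom(n, 2, 0.4))
  y <- rep(c(1, 0), each = n / 2)
  expect_message(res <- logistic_assoc(X, y, NULL, method = "score"),
                 "flagged")
  expect_false(res$results$converged[1])
  expect_true(res$results$converged[2])
  expect_equal(res$n_flagged, 1)
  expect_message(resl <- logistic_assoc(X, y, NULL, method = "lrt"), "flagged")
  expect_false(resl$results$converged[1])
  # perfect separation is flagged on the LRT path
  xs <- c(rep(2, 30), rep(0, 30))
  expect_message(ressep <- logistic_assoc(cbind(xs), y, NULL, method = "lrt"),
                 "flagged")
  expect_false(ressep$results$converged[1])
})

test_that("stratification inflates the null and exact covariates restore it", {
  dat <- stratified_nulls(n_per = 150, m = 600)
  naive <- logistic_assoc(dat$X, dat$y, NULL, alpha = 0.05,
                          method = "score")
  expect_gt(naive$prop_significant, 0.3)       # heavy confounding
  pops <- covariate_set(matrix(as.numeric(dat$pop == 1), ncol = 1), "dummies")
  fixed <- logistic_assoc(dat$X, dat$y, pops, alpha = 0.05, method = "score")
  expect_gt(fixed$prop_significant, 0.02)
  expect_lt(fixed$prop_significant, 0.09)
})

test_that("a covariate orthogonal to genotype and phenotype leaves p unchanged", {
  set.seed(45)
  n <- 80
  X <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  y <- rbinom(n, 1, 0.5)
  base <- qr.Q(qr(cbind(1, y, X)))
  e <- rnorm(n)
  e <- e - base %*% crossprod(base, e)        # exactly orthogonal residual
  p0 <- logistic_assoc(X, y, NULL, method = "score")$results$p
  p1 <- logistic_assoc(X, y, covariate_set(cbind(e), "pcs"),
                       method = "score")$results$p
  expect_lt(max(abs(p0 - p1)), 1e-10)
})

test_that("the LRT statistic is twice the log-likelihood gain, nonnegative", {
  set.seed(46)
  n <- 100
  x <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(0.4 * x - 0.2))
  res <- logistic_assoc(cbind(x), y, NULL, method = "lrt")
  want <- oracle_logistic(x, y, NULL)
  stat_res <- qchisq(res$results$p, 1, lower.tail = FALSE)
  stat_want <- qchisq(want$p, 1, lower.tail = FALSE)
  expect_equal(stat_res, stat_want, tolerance = 1e-5)
  expect_gte(stat_res, 0)
})

test_that("association results export as delimited tables", {
  set.seed(47)
  X <- matrix(rbinom(200, 2, 0.4), 50, 4,
              dimnames = list(NULL, paste0("snp", 1:4)))
  y <- rbinom(50, 1, 0.5)
  res <- logistic_assoc(X, y, NULL, method = "lrt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assoc(res, path)
  tab <- read.delim(path)
  expect_equal(tab$id, paste0("snp", 1:4))
  expect_true(all(c("beta", "p", "converged") %in% names(tab)))
})
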