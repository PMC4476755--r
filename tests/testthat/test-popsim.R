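test_that("largest-remainder apportionment is exact and deterministic", {
  expect_equal(apportion(500, c(0.6, 0.4)), c(300L, 200L))
  expect_equal(apportion(500, c(0.45, 0.35, 0.20)), c(225L, 175L, 100L))
  expect_equal(apportion(500, c(0.35, 0.20, 0.45)), c(175L, 100L, 225L))
  expect_equal(apportion(500, c(0, 1)), c(0L, 500L))
  set.seed(50)
  for (trial in 1:20) {
    k <- sample(2:5, 1)
    pr <- runif(k); pr <- pr / sum(pr)
    n <- sample(10:999, 1)
    a <- apportion(n, pr)
    expect_equal(sum(a), n)
    expect_true(all(abs(a - n * pr) < 1))
  }
  expect_error(apportion(10, c(0.5, 0.4)), "sum to 1")
})

test_that("Balding-Nichols frequencies have the right limits and moments", {
  fr0 <- balding_nichols_freqs(50, 3, fst = 0, seed = 51)
  expect_equal(fr0$pop_freqs, matrix(fr0$ancestral, 50, 3))
  fr <- balding_nichols_freqs(1e5, 2, fst = 0.01, seed = 52)
  expect_true(all(fr$ancestral >= 0.1 & fr$ancestral <= 0.9))
  # Beta mean equals the ancestral frequency
  expect_lt(max(abs(colMeans(fr$pop_freqs - fr$ancestral))), 3e-3)
  # Beta variance is fst * p(1-p)
  v <- (fr$pop_freqs[, 1] - fr$ancestral)^2 / (fr$ancestral * (1 - fr$ancestral))
  expect_lt(abs(mean(v) - 0.01), 0.001)
})

test_that("realized genotype differentiation matches the nominal Fst", {
  spec <- scenario_spec("discrete", n_cases = 100, n_controls = 100,
                        n_pops = 2, fst = 0.01,
                        case_props = c(1, 0), control_props = c(0, 1),
                        seed = 53)
  st <- simulate_discrete(spec, 20000)
  g1 <- st$genotypes$dosages[st$truth == 1, ]
  g2 <- st$genotypes$dosages[st$truth == 2, ]
  expect_lt(abs(oracle_fst(g1, g2) - 0.01), 0.0015)
})

test_that("discrete scenarios apportion cases and controls as specified", {
  counts <- function(x) as.integer(table(x))
  s1 <- simulate_discrete(scenario_preset("moderate", seed = 54), 50)
  expect_equal(counts(s1$truth[s1$phenotype == 1]), c(300L, 200L))
  expect_equal(counts(s1$truth[s1$phenotype == 0]), c(200L, 300L))
  s2 <- simulate_discrete(scenario_preset("extreme", seed = 54), 50)
  expect_equal(counts(s2$truth[s2$phenotype == 1]), c(250L, 250L))
  expect_true(all(s2$truth[s2$phenotype == 0] == 2))
  s3 <- simulate_discrete(scenario_preset("three_pop", seed = 54), 50)
  expect_equal(counts(s3$truth[s3$phenotype == 1]), c(225L, 175L, 100L))
  expect_equal(counts(s3$truth[s3$phenotype == 0]), c(175L, 100L, 225L))
})

test_that("the admixed risk model evaluates and integrates as published", {
  expect_equal(disease_probability(0, 3), 0.5 * log(3) / 2, tolerance = 1e-12)
  expect_equal(disease_probability(0, 3), 0.27465, tolerance = 1e-4)
  expect_equal(disease_probability(1, 3), 3 * disease_probability(0, 3))
  expect_equal(disease_probability(1, 3), 0.82396, tolerance = 1e-4)
  for (r in c(1.5, 2, 3)) {
    val <- integrate(disease_probability, 0, 1, r = r)$value
    expect_equal(val, 0.5, tolerance = 1e-8)
  }
  # prevalence one-half: the expected case fraction of a random draw is 0.5
  set.seed(55)
  a <- runif(2e4)
  expect_equal(mean(disease_probability(a, 3)), 0.5, tolerance = 0.01)
  # risks that push the probability over 1 are rejected
  expect_error(scenario_spec("admixed", ancestral_risk = 10), "> 1")
  expect_error(scenario_spec("admixed", ancestral_risk = 0.5), "exceed 1")
})

test_that("admixed studies fill both pools and carry ancestry truth", {
  st <- simulate_admixed(scenario_preset("admixed", seed = 56), 500)
  expect_equal(sum(st$phenotype == 1), 500)
  expect_equal(sum(st$phenotype == 0), 500)
  expect_true(all(st$truth >= 0 & st$truth <= 1))
  # cases are enriched for high-risk ancestry
  expect_gt(mean(st$truth[st$phenotype == 1]),
            mean(st$truth[st$phenotype == 0]))
})

test_that("simulation is reproducible for a fixed seed", {
  a <- simulate_study(scenario_preset("moderate", seed = 57), 300)
  b <- simulate_study(scenario_preset("moderate", seed = 57), 300)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$truth, b$truth)
  cc <- simulate_study(scenario_preset("moderate", seed = 58), 300)
  expect_false(identical(a$genotypes$dosages, cc$genotypes$dosages))
  t1 <- simulate_test_snps(a, "random", 200, seed = 9)
  t2 <- simulate_test_snps(a, "random", 200, seed = 9)
  expect_identical(t1$dosages, t2$dosages)
})

test_that("differentiated test SNPs carry the specified population frequencies", {
  st <- simulate_discrete(scenario_preset("extreme", seed = 59), 50)
  xt <- simulate_test_snps(st, "differentiated", 2000, seed = 60)
  f1 <- mean(xt$dosages[st$truth == 1, ]) / 2
  f2 <- mean(xt$dosages[st$truth == 2, ]) / 2
  expect_equal(f1, 0.8, tolerance = 0.005)
  expect_equal(f2, 0.2, tolerance = 0.005)
  # three populations default to 0.8 / 0.2 / 0.2
  st3 <- simulate_discrete(scenario_preset("three_pop", seed = 59), 50)
  xt3 <- simulate_test_snps(st3, "differentiated", 1000, seed = 61)
  expect_equal(mean(xt3$dosages[st3$truth == 3, ]) / 2, 0.2,
               tolerance = 0.01)
  # admixed: frequency a * 0.8 + (1 - a) * 0.2 per individual
  sta <- simulate_admixed(scenario_preset("admixed", seed = 62), 50)
  xta <- simulate_test_snps(sta, "differentiated", 3000, seed = 63)
  want <- sta$truth * 0.8 + (1 - sta$truth) * 0.2
  got <- rowMeans(xta$dosages) / 2
  expect_lt(max(abs(got - want)), 0.05)
})

test_that("causal SNPs shift case allele frequency by the odds factor", {
  # r = 1 recovers the null generative process draw for draw
  st <- simulate_discrete(scenario_preset("moderate", seed = 64), 50)
  null_like <- simulate_test_snps(st, "causal", 500, rel_risk = 1,
                                  seed = 65)
  same <- simulate_test_snps(st, "random", 500, seed = 65)
  expect_identical(unname(null_like$dosages), unname(same$dosages))
  # p = 0.5, r = 1.5 gives case allele frequency 0.6
  spec1 <- scenario_spec("discrete", n_cases = 400, n_controls = 400,
                         n_pops = 2, fst = 0,
                         case_props = c(0.5, 0.5),
                         control_props = c(0.5, 0.5), seed = 66)
  st1 <- simulate_discrete(spec1, 10)
  xt <- simulate_test_snps(st1, "causal", 3000, rel_risk = 1.5, seed = 67)
  pc <- colMeans(xt$dosages[st1$phenotype == 1, ]) / 2
  p0 <- colMeans(xt$dosages[st1$phenotype == 0, ]) / 2
  want <- 1.5 * p0 / (1.5 * p0 + 1 - p0)
  expect_lt(abs(mean(pc - want)), 0.01)
  expect_gt(mean(pc), mean(p0))
})

test_that("random test SNPs are exchangeable with the training panel", {
  st <- simulate_discrete(scenario_preset("moderate", seed = 68), 10000)
  xt <- simulate_test_snps(st, "random", 10000, seed = 71)
  f_train <- colMeans(st$genotypes$dosages) / 2
  f_test <- colMeans(xt$dosages) / 2
  ks <- suppressWarnings(ks.test(f_train, f_test))
  expect_gt(ks$p.value, 0.01)
})

test_that("studies export as plain-text genotype and sample tables", {
  st <- simulate_discrete(scenario_preset("moderate", seed = 70), 30)
  stem <- file.path(withr::local_tempdir(), "study")
  paths <- write_study(st, stem)
  expect_true(all(file.exists(paths)))
  back <- read_genotype_matrix(paths[1])
  expect_identical(unname(back$dosages), unname(st$genotypes$dosages))
  smp <- read.delim(paths[2])
  expect_equal(smp$phenotype, unname(st$phenotype))
})
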