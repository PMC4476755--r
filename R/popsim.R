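#' Specify a simulation scenario
#'
#' Full parameterization of one stratified case/control study. Two kinds are
#' supported:
#' \describe{
#'   \item{`"discrete"`}{individuals belong to `n_pops` discrete
#'     subpopulations whose allele frequencies follow the Balding-Nichols
#'     model at differentiation `fst`; cases and controls are apportioned to
#'     populations by `case_props` / `control_props` (largest-remainder
#'     rounding, so subgroup counts are deterministic).}
#'   \item{`"admixed"`}{each individual has ancestry proportion `a ~
#'     Uniform(0, 1)` from population 1 (and `1 - a` from population 2) and
#'     disease probability `0.5 * log(r) * r^a / (r - 1)` with ancestral
#'     risk `r = ancestral_risk`; that probability integrates to 0.5 over
#'     `a`, so half the population is affected on average.}
#' }
#'
#' @param kind `"discrete"` or `"admixed"`.
#' @param n_cases,n_controls sample sizes (default 500 / 500).
#' @param n_pops number of discrete populations (2 or 3 in the standard
#'   scenarios).
#' @param fst differentiation between populations, in `(0, 1)` for discrete
#'   scenarios (default 0.01).
#' @param case_props,control_props per-population proportions summing to 1
#'   (discrete kind only).
#' @param ancestral_risk risk multiplier `r > 1` (admixed kind only;
#'   default 3). Values making the disease probability exceed 1 at `a = 1`
#'   are rejected.
#' @param seed integer seed stored with the scenario.
#' @return object of class `scenario_spec`.
#' @seealso [scenario_preset()] for the four standard scenarios.
#' @export
scenario_spec <- function(kind = c("discrete", "admixed"),
                          n_cases = 500, n_controls = 500,
                          n_pops = 2, fst = 0.01,
                          case_props = NULL, control_props = NULL,
                          ancestral_risk = 3, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_cases >= 1, n_controls >= 1)
  if (kind == "discrete") {
    if (!(fst >= 0 && fst < 1))
      stop("fst must lie in [0, 1) for discrete scenarios", call. = FALSE)
    if (is.null(case_props) || is.null(control_props))
      stop("discrete scenarios need case_props and control_props", call. = FALSE)
    if (length(case_props) != n_pops || length(control_props) != n_pops)
      stop("proportion vectors must have length n_pops", call. = FALSE)
    for (pr in list(case_props, control_props))
      if (abs(sum(pr) - 1) > 1e-8)
        stop("proportions must sum to 1", call. = FALSE)
  } else {
    if (ancestral_risk <= 1)
      stop("ancestral_risk must exceed 1", call. = FALSE)
    pmax_ <- 0.5 * log(ancestral_risk) * ancestral_risk / (ancestral_risk - 1)
    if (pmax_ > 1)
      stop(sprintf("disease probability reaches %.3f > 1 at a = 1 for r = %g",
                   pmax_, ancestral_risk), call. = FALSE)
  }
  structure(list(kind = kind, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_pops = as.integer(n_pops), fst = fst,
                 case_props = case_props, control_props = control_props,
                 ancestral_risk = ancestral_risk, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' The four standard simulation scenarios
#'
#' Presets for 1000 individuals (500 cases, 500 controls) at Fst = 0.01:
#' \describe{
#'   \item{`"moderate"`}{2 populations; 60% of cases from population 1, 40%
#'     from population 2; controls mirrored (40% / 60%). The control split
#'     is configurable via `control_props` -- only the case split is fixed
#'     by the design.}
#'   \item{`"extreme"`}{2 populations; cases 50% / 50%, controls 100% from
#'     population 2.}
#'   \item{`"three_pop"`}{3 populations; cases 45% / 35% / 20%, controls
#'     35% / 20% / 45%.}
#'   \item{`"admixed"`}{uniform individual ancestry with ancestral risk 3.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param control_props optional override of the control split for
#'   `"moderate"`.
#' @return a [scenario_spec()].
#' @examples
#' scenario_preset("extreme", seed = 7)
#' @export
scenario_preset <- function(name = c("moderate", "extreme", "three_pop",
                                     "admixed"),
                            seed = 1L, control_props = NULL) {
  name <- match.arg(name)
  switch(name,
    moderate = scenario_spec("discrete", n_pops = 2,
                             case_props = c(0.6, 0.4),
                             control_props = control_props %||% c(0.4, 0.6),
                             seed = seed),
    extreme = scenario_spec("discrete", n_pops = 2,
                            case_props = c(0.5, 0.5),
                            control_props = c(0, 1), seed = seed),
    three_pop = scenario_spec("discrete", n_pops = 3,
                              case_props = c(0.45, 0.35, 0.20),
                              control_props = c(0.35, 0.20, 0.45),
                              seed = seed),
    admixed = scenario_spec("admixed", ancestral_risk = 3, seed = seed))
}

#' @export
print.scenario_spec <- function(x, ...) {
  if (x$kind == "discrete")
    cat(sprintf(paste0("scenario_spec: discrete, %d+%d individuals, %d pops, ",
                       "Fst = %g\n  case props: %s\n  control props: %s\n"),
                x$n_cases, x$n_controls, x$n_pops, x$fst,
                paste(x$case_props, collapse = "/"),
                paste(x$control_props, collapse = "/")))
  else
    cat(sprintf("scenario_spec: admixed, %d+%d individuals, ancestral risk %g\n",
                x$n_cases, x$n_controls, x$ancestral_risk))
  invisible(x)
}

#' Balding-Nichols allele frequencies
#'
#' Draws an ancestral frequency `p ~ Uniform(p_range)` per SNP and, for each
#' population, a frequency from `Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) /
#' Fst)` -- mean `p`, spread governed by `Fst`. `fst = 0` degenerates to all
#' populations sharing the ancestral frequency.
#'
#' @param n_snps number of SNPs.
#' @param n_pops number of populations.
#' @param fst differentiation in `[0, 1)`.
#' @param p_range range of the uniform ancestral-frequency draw (default
#'   `c(0.1, 0.9)`).
#' @param seed optional seed; `NULL` uses the ambient RNG stream.
#' @return list with `ancestral` (length `n_snps`) and `pop_freqs`
#'   (`n_snps x n_pops`).
#' @export
balding_nichols_freqs <- function(n_snps, n_pops, fst,
                                  p_range = c(0.1, 0.9), seed = NULL) {
  stopifnot(fst >= 0, fst < 1, n_snps >= 1, n_pops >= 1)
  with_seed(seed, {
    p <- runif(n_snps, p_range[1], p_range[2])
    pop_freqs <- if (fst == 0) {
      matrix(p, n_snps, n_pops)
    } else {
      a <- p * (1 - fst) / fst
      b <- (1 - p) * (1 - fst) / fst
      vapply(seq_len(n_pops), function(k) rbeta(n_snps, a, b),
             numeric(n_snps))
    }
    list(ancestral = p, pop_freqs = matrix(pop_freqs, n_snps, n_pops))
  })
}

#' Disease probability under the admixed risk model
#'
#' `P(disease | a) = 0.5 * log(r) * r^a / (r - 1)` for ancestry proportion
#' `a` from the higher-risk population. Integrates to 0.5 over
#' `a ~ Uniform(0, 1)` for every `r > 1`.
#'
#' @param a ancestry proportion(s) in `[0, 1]`.
#' @param r ancestral risk, `> 1`.
#' @return disease probability vector.
#' @examples
#' disease_probability(c(0, 1), r = 3)
#' @export
disease_probability <- function(a, r) {
  stopifnot(r > 1)
  0.5 * log(r) * r^a / (r - 1)
}

new_study <- function(genotypes, phenotype, truth, spec) {
  names(phenotype) <- genotypes$samples
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 truth = truth, spec = spec),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study (%s): %d cases, %d controls, %d training SNPs\n",
              x$spec$kind, sum(x$phenotype == 1), sum(x$phenotype == 0),
              ncol(x$genotypes$dosages)))
  invisible(x)
}

sim_variant_table <- function(ids) {
  data.frame(chrom = "1", pos = seq_along(ids) - 1L, id = ids,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

sim_genotypes <- function(Pm, samples, prefix) {
  n <- nrow(Pm); m <- ncol(Pm)
  G <- matrix(as.double(rbinom(n * m, 2, Pm)), n, m)
  ids <- sprintf("%s_%06d", prefix, seq_len(m))
  genotype_matrix(G, variants = sim_variant_table(ids), samples = samples,
                  validate = FALSE)
}

sample_ids <- function(phenotype) {
  stat <- ifelse(phenotype == 1, "case", "control")
  idx <- ave(seq_along(phenotype), stat, FUN = seq_along)
  sprintf("%s_%04d", stat, idx)
}

#' Simulate a discrete-subpopulation case/control study
#'
#' Assigns cases and controls to populations by the scenario's proportions
#' (deterministic largest-remainder rounding), draws per-SNP population
#' frequencies from the Balding-Nichols model, and genotypes each
#' individual as `Binomial(2, f_pop)`. Training SNPs are null: they carry
#' no phenotype effect beyond the population mismatch itself.
#'
#' @param spec a discrete [scenario_spec()].
#' @param n_snps number of null training SNPs.
#' @return object of class `simulated_study`: list with `genotypes` (a
#'   [genotype_matrix()]), `phenotype` (0/1), `truth` (population label per
#'   individual), `spec`.
#' @export
simulate_discrete <- function(spec, n_snps) {
  stopifnot(inherits(spec, "scenario_spec"), spec$kind == "discrete")
  with_seed(spec$seed, {
    case_n <- apportion(spec$n_cases, spec$case_props)
    ctrl_n <- apportion(spec$n_controls, spec$control_props)
    pop <- c(rep(seq_along(case_n), case_n), rep(seq_along(ctrl_n), ctrl_n))
    y <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
    fr <- balding_nichols_freqs(n_snps, spec$n_pops, spec$fst)
    Pm <- t(fr$pop_freqs)[pop, , drop = FALSE]
    g <- sim_genotypes(Pm, sample_ids(y), "train")
    new_study(g, y, pop, spec)
  })
}

#' Simulate an admixed case/control study
#'
#' Individuals are drawn with ancestry `a ~ Uniform(0, 1)` and disease
#' status `Bernoulli(disease_probability(a, r))` until the case and control
#' pools are filled; genotypes are `Binomial(2, a f1 + (1 - a) f2)` with
#' population frequencies from the Balding-Nichols model.
#'
#' @param spec an admixed [scenario_spec()].
#' @param n_snps number of null training SNPs.
#' @return a `simulated_study`; `truth` is the ancestry proportion `a`.
#' @export
simulate_admixed <- function(spec, n_snps) {
  stopifnot(inherits(spec, "scenario_spec"), spec$kind == "admixed")
  with_seed(spec$seed, {
    r <- spec$ancestral_risk
    anc_case <- numeric(0); anc_ctrl <- numeric(0)
    while (length(anc_case) < spec$n_cases ||
           length(anc_ctrl) < spec$n_controls) {
      a <- runif(4 * (spec$n_cases + spec$n_controls))
      d <- rbinom(length(a), 1, disease_probability(a, r))
      anc_case <- c(anc_case,
                    a[d == 1])[seq_len(min(spec$n_cases,
                                           length(anc_case) + sum(d == 1)))]
      anc_ctrl <- c(anc_ctrl,
                    a[d == 0])[seq_len(min(spec$n_controls,
                                           length(anc_ctrl) + sum(d == 0)))]
    }
    anc <- c(anc_case, anc_ctrl)
    y <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
    fr <- balding_nichols_freqs(n_snps, 2, spec$fst)
    Pm <- outer(anc, fr$pop_freqs[, 1]) + outer(1 - anc, fr$pop_freqs[, 2])
    g <- sim_genotypes(Pm, sample_ids(y), "train")
    new_study(g, y, anc, spec)
  })
}

#' Simulate a study of either kind
#'
#' Dispatches to [simulate_discrete()] or [simulate_admixed()] by
#' `spec$kind`.
#'
#' @param spec a [scenario_spec()].
#' @param n_snps number of null training SNPs.
#' @return a `simulated_study`.
#' @export
simulate_study <- function(spec, n_snps) {
  if (spec$kind == "discrete") simulate_discrete(spec, n_snps)
  else simulate_admixed(spec, n_snps)
}

#' Simulate test SNPs for an existing study
#'
#' Generates additional SNPs for the *same* individuals (population labels
#' or ancestry proportions, and case/control status, are reused from the
#' study) in one of three categories:
#' \describe{
#'   \item{`"random"`}{null SNPs from the same generative process as the
#'     training panel (fresh Balding-Nichols frequencies, no phenotype
#'     effect).}
#'   \item{`"differentiated"`}{null SNPs with strongly different
#'     frequencies across populations: `diff_freqs[1]` (default 0.8) in
#'     population 1 and `diff_freqs[-1]` (default 0.2) elsewhere; in the
#'     admixed kind each individual's frequency is
#'     `a * 0.8 + (1 - a) * 0.2`.}
#'   \item{`"causal"`}{SNPs with a multiplicative per-allele relative risk:
#'     the base frequency follows the random-SNP process and in cases each
#'     allele is the risk allele with odds multiplied by `rel_risk`, i.e.
#'     `p_case = r p / (r p + 1 - p)`; `rel_risk = 1` recovers the null.}
#' }
#'
#' @param study a `simulated_study`.
#' @param category `"random"`, `"differentiated"` or `"causal"`.
#' @param n_snps number of SNPs to generate.
#' @param rel_risk per-allele relative risk for `"causal"` (default 1.5).
#' @param diff_freqs per-population frequencies for `"differentiated"`
#'   (default 0.8 for population 1, 0.2 for the rest).
#' @param seed optional seed; `NULL` continues the ambient stream.
#' @return a [genotype_matrix()] of test SNPs for the study's individuals.
#' @export
simulate_test_snps <- function(study,
                               category = c("random", "differentiated",
                                            "causal"),
                               n_snps, rel_risk = 1.5, diff_freqs = NULL,
                               seed = NULL) {
  category <- match.arg(category)
  spec <- study$spec
  n_pops <- if (spec$kind == "discrete") spec$n_pops else 2L
  diff_freqs <- diff_freqs %||% c(0.8, rep(0.2, n_pops - 1))
  stopifnot(length(diff_freqs) == n_pops)
  with_seed(seed, {
    Pm <- switch(category,
      random = ,
      causal = {
        fr <- balding_nichols_freqs(n_snps, n_pops, spec$fst)
        if (spec$kind == "discrete")
          t(fr$pop_freqs)[study$truth, , drop = FALSE]
        else
          outer(study$truth, fr$pop_freqs[, 1]) +
            outer(1 - study$truth, fr$pop_freqs[, 2])
      },
      differentiated = {
        pf <- if (spec$kind == "discrete") diff_freqs[study$truth]
              else study$truth * diff_freqs[1] +
                   (1 - study$truth) * diff_freqs[2]
        matrix(pf, length(pf), n_snps)
      })
    if (category == "causal") {
      stopifnot(rel_risk > 0)
      case_rows <- study$phenotype == 1
      Pc <- rel_risk * Pm / (rel_risk * Pm + 1 - Pm)
      Pm[case_rows, ] <- Pc[case_rows, ]
    }
    sim_genotypes(Pm, study$genotypes$samples, substr(category, 1, 4))
  })
}

#' Export a simulated study as plain text
#'
#' Writes the training genotypes in the plain-matrix format plus a
#' phenotype/truth table (`<stem>_genotypes.tsv`, `<stem>_samples.tsv`).
#'
#' @param study a `simulated_study`.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_study <- function(study, stem) {
  gpath <- paste0(stem, "_genotypes.tsv")
  spath <- paste0(stem, "_samples.tsv")
  write_genotype_matrix(study$genotypes, gpath)
  write.table(data.frame(sample = study$genotypes$samples,
                         phenotype = study$phenotype,
                         truth = study$truth),
              spath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gpath, spath))
}
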