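parse_methods <- function(methods, n_pops) {
  out <- list()
  for (m in methods) {
    if (m %in% c("naive", "components", "communities")) {
      out[[m]] <- list(kind = m)
    } else if (grepl("^pcs(:[0-9]+)?$", m)) {
      k <- if (grepl(":", m)) as.integer(sub("^pcs:", "", m))
           else if (n_pops <= 2) 1L else 2L
      out[[paste0("pcs", k)]] <- list(kind = "pcs", k = k)
    } else {
      stop("unknown correction method: ", m, call. = FALSE)
    }
  }
  out
}

#' Run the simulation-study experiment grid
#'
#' The full evaluation pipeline for one scenario: per replicate, a training
#' study is simulated, population substructure is inferred from it
#' (covariance -> triad graph -> unconnected components and Louvain
#' communities; principal components from the same covariance), the three
#' test-SNP categories are generated for the same individuals, and every
#' correction arm is association-tested at level `alpha` with the vectorized
#' score test. Significant fractions are averaged across replicates,
#' mirroring the layout of the published comparison table (arms in columns,
#' SNP categories in rows).
#'
#' An arm whose covariates come out empty (a single community) degrades to
#' the naive model with a notice -- the expected behaviour for, e.g., the
#' component level on an admixed sample whose triad graph is one connected
#' component.
#'
#' @param spec a [scenario_spec()].
#' @param methods correction arms: subset of `"naive"`, `"components"`,
#'   `"communities"`, `"pcs"` or `"pcs:K"` (for `"pcs"` the component count
#'   defaults to 1 for two populations and 2 otherwise).
#' @param n_train training SNPs used to infer structure per replicate
#'   (default 30000; see the methods vignette for the choice).
#' @param n_test test SNPs per category per replicate (default 200000).
#' @param reps number of independent replicates (default 2).
#' @param alpha significance level (default 1e-4).
#' @param rel_risk relative risk of causal test SNPs (default 1.5).
#' @param categories SNP categories to evaluate.
#' @param chunk_size SNPs simulated and tested per block, bounding memory.
#' @param seed base seed; replicate r uses `seed + 100003 * r`. Defaults to
#'   `spec$seed`.
#' @param verbose print per-replicate progress.
#' @return object of class `experiment_result`: list with `table`
#'   (data.frame: arm, category, prop_significant, n_flagged), `per_rep`
#'   (replicate x arm x category array of proportions), `structure`
#'   (per-replicate component/community counts, modularity and --- for
#'   discrete scenarios --- precision against the true populations), and the
#'   run parameters.
#' @export
run_experiment <- function(spec,
                           methods = c("naive", "components", "communities"),
                           n_train = 30000, n_test = 200000, reps = 2,
                           alpha = 1e-4, rel_risk = 1.5,
                           categories = c("random", "differentiated",
                                          "causal"),
                           chunk_size = 20000, seed = NULL,
                           verbose = FALSE) {
  stopifnot(reps >= 1, n_train >= 10, n_test >= 1)
  categories <- match.arg(categories, several.ok = TRUE)
  seed <- seed %||% spec$seed
  n_pops <- if (spec$kind == "discrete") spec$n_pops else 2L
  arms <- parse_methods(methods, n_pops)
  per_rep <- array(NA_real_,
                   dim = c(reps, length(arms), length(categories)),
                   dimnames = list(NULL, names(arms), categories))
  flagged <- array(0, dim = dim(per_rep), dimnames = dimnames(per_rep))
  structure_rows <- vector("list", reps)

  for (r in seq_len(reps)) {
    rep_seed <- as.integer(seed + 100003 * r)
    spec_r <- spec; spec_r$seed <- rep_seed
    if (verbose) message(sprintf("replicate %d (seed %d): simulating %d training SNPs",
                                 r, rep_seed, n_train))
    study <- simulate_study(spec_r, n_train)
    y <- as.numeric(study$phenotype)
    D <- genetic_covariance(study$genotypes)
    tg <- build_triad_graph(D)
    comp <- connected_components(tg)
    comm <- louvain(tg, seed = rep_seed)
    pcs_k <- vapply(arms, function(a) if (a$kind == "pcs") a$k else 0L,
                    integer(1))
    pcs <- if (any(pcs_k > 0)) principal_components(D, max(pcs_k)) else NULL

    covars <- lapply(arms, function(a) {
      cs <- switch(a$kind,
                   naive = NULL,
                   components = dummy_encode(comp),
                   communities = dummy_encode(comm),
                   pcs = pc_covariates(pcs, a$k))
      if (!is.null(cs) && ncol(cs$values) == 0) {
        message(sprintf("replicate %d: '%s' arm has no usable covariates; degrades to naive",
                        r, a$kind))
        cs <- NULL
      }
      cs
    })
    nulls <- lapply(covars, function(cs)
      score_null(y, if (is.null(cs)) NULL else cs$values))

    prec <- function(a) {
      if (spec$kind != "discrete") return(NA_real_)
      tab <- table(a$membership, study$truth)
      sum(apply(tab, 1, max)) / length(y)
    }
    structure_rows[[r]] <- data.frame(
      rep = r, n_components = length(unique(comp$membership)),
      n_communities = length(unique(comm$membership)),
      modularity = comm$modularity,
      precision_components = prec(comp),
      precision_communities = prec(comm))

    starts <- seq(1, n_test, by = chunk_size)
    for (ci in seq_along(categories)) {
      cat_name <- categories[ci]
      cat_id <- match(cat_name, c("random", "differentiated", "causal"))
      sig <- setNames(numeric(length(arms)), names(arms))
      nok <- setNames(numeric(length(arms)), names(arms))
      nbad <- setNames(numeric(length(arms)), names(arms))
      for (b in seq_along(starts)) {
        m_b <- min(chunk_size, n_test - starts[b] + 1)
        cseed <- rep_seed + 1009L * cat_id + b
        Xb <- simulate_test_snps(study, cat_name, m_b, rel_risk = rel_risk,
                                 seed = cseed)$dosages
        for (an in names(arms)) {
          sc <- score_pvalues(Xb, nulls[[an]])
          sig[an] <- sig[an] + sum(sc$p < alpha & sc$valid, na.rm = TRUE)
          nok[an] <- nok[an] + sum(sc$valid)
          nbad[an] <- nbad[an] + sum(!sc$valid)
        }
      }
      per_rep[r, , ci] <- sig / nok
      flagged[r, , ci] <- nbad
      if (verbose)
        message(sprintf("  %s: %s", cat_name,
                        paste(sprintf("%s=%.3g", names(arms), sig / nok),
                              collapse = ", ")))
    }
  }

  tab <- expand.grid(arm = names(arms), category = categories,
                     stringsAsFactors = FALSE)
  tab$prop_significant <- mapply(function(a, cc) mean(per_rep[, a, cc]),
                                 tab$arm, tab$category)
  tab$n_flagged <- mapply(function(a, cc) sum(flagged[, a, cc]),
                          tab$arm, tab$category)
  structure(list(table = tab, per_rep = per_rep,
                 structure = do.call(rbind, structure_rows),
                 spec = spec,
                 params = list(n_train = n_train, n_test = n_test,
                               reps = reps, alpha = alpha,
                               rel_risk = rel_risk, seed = seed)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %s scenario, %d replicate(s), alpha = %g\n",
              x$spec$kind, x$params$reps, x$params$alpha))
  wide <- tapply(x$table$prop_significant,
                 list(x$table$category, x$table$arm), identity)
  print(signif(wide[unique(x$table$category), unique(x$table$arm),
                    drop = FALSE], 4))
  invisible(x)
}

#' Cross-tabulate a detected partition against true labels
#'
#' Rows are detected communities (or components), columns the true
#' subpopulation labels. The derived precision is the fraction of
#' individuals whose community's majority label matches their own:
#' `sum over communities of the majority count, divided by n`.
#'
#' @param a a `community_assignment`.
#' @param truth label vector covering all individuals.
#' @return object of class `contingency_table`: list with `table` and
#'   `precision`.
#' @export
contingency <- function(a, truth) {
  if (length(truth) != length(a$membership))
    stop("truth labels must cover all individuals", call. = FALSE)
  tab <- table(community = a$membership, truth = truth)
  structure(list(table = tab,
                 precision = sum(apply(tab, 1, max)) / length(truth)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  print(x$table)
  cat(sprintf("precision: %.4f\n", x$precision))
  invisible(x)
}

#' Plot the triad network with community hulls
#'
#' Force-directed (Fruchterman-Reingold) layout of the triad graph with
#' edges hidden, one point per individual colored by its true label (a
#' single color when no labels are supplied) and a convex-hull polygon
#' drawn around each detected community -- the standard way of eyeballing
#' how communities line up with ancestry. The layout is deterministic for
#' a given `seed`.
#'
#' @param tg a [build_triad_graph()] result.
#' @param assignment optional `community_assignment` for the hulls.
#' @param truth optional true label vector for node colors.
#' @param path output PNG path.
#' @param seed layout seed.
#' @param width,height image size in pixels.
#' @return the `n x 2` layout coordinate matrix, invisibly.
#' @export
plot_network <- function(tg, assignment = NULL, truth = NULL, path,
                         seed = 1L, width = 1200, height = 1200) {
  lay <- with_seed(seed, igraph::layout_with_fr(tg$graph))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::plot.new()
  rngx <- range(lay[, 1]); rngy <- range(lay[, 2])
  pad <- 0.05 * c(diff(rngx), diff(rngy))
  graphics::plot.window(xlim = rngx + c(-1, 1) * pad[1],
                        ylim = rngy + c(-1, 1) * pad[2], asp = 1)
  if (!is.null(assignment)) {
    for (lab in sort(unique(assignment$membership))) {
      pts <- lay[assignment$membership == lab, , drop = FALSE]
      if (nrow(pts) >= 3) {
        h <- grDevices::chull(pts)
        graphics::polygon(pts[h, 1], pts[h, 2],
                          border = "grey40",
                          col = grDevices::adjustcolor("grey70", 0.25))
      }
    }
  }
  cols <- if (is.null(truth)) "steelblue" else {
    f <- factor(truth)
    grDevices::hcl.colors(max(3, nlevels(f)), "Dark 3")[as.integer(f)]
  }
  graphics::points(lay, pch = 19, col = cols, cex = 0.9)
  if (!is.null(truth)) {
    f <- factor(truth)
    graphics::legend("topleft", legend = levels(f), pch = 19,
                     col = grDevices::hcl.colors(max(3, nlevels(f)), "Dark 3")[seq_len(nlevels(f))],
                     bty = "n")
  }
  graphics::title(main = sprintf("triad network: %d individuals%s",
                                 igraph::vcount(tg$graph),
                                 if (is.null(assignment)) "" else
                                   sprintf(", %d communities",
                                           length(unique(assignment$membership)))))
  invisible(lay)
}
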