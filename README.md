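# trianet

Network-based inference of population substructure for case/control
association studies.

## The problem

Genome-wide association studies with a population-based design are
confounded by **population stratification**: when cases and controls are
sampled unevenly from ancestral subgroups, allele-frequency differences
between those subgroups masquerade as disease associations. trianet infers
the hidden subgroups directly from the genotypes with a social-network
construction and turns them into discrete covariates for per-SNP logistic
regression — an alternative to principal-component (EIGENSTRAT-style) and
model-based (ADMIXTURE-style) corrections that is particularly sharp when
the sample consists of discrete subpopulations.

## The method

Given an *n × m* dosage matrix *G* (*g<sub>ik</sub>* ∈ {0,1,2}), columns
are centered and scaled by √(p̂(1−p̂)) and the genetic covariance matrix
*D = XX′/m* between individuals is computed. For each individual *i*, all
others are ranked by covariance with *i* (rank 1 = most similar, ties
averaged), and a **triad** is built:

1. partner *j* minimizes rank⁽ⁱ⁾[j] + rank⁽ʲ⁾[i]   (mutual closeness),
2. third member *k* ∉ {i, j} minimizes
   rank⁽ⁱ⁾[k] + rank⁽ᵏ⁾[i] + rank⁽ʲ⁾[k] + rank⁽ᵏ⁾[j].

The *n* triads merge into one undirected graph (≤ 3n edges). Its
**unconnected components** give a coarse partition; **Louvain** modularity
maximization (Q = Σᵢ (eᵢᵢ − aᵢ²)) refines it into communities. Community
membership is dummy-encoded and used as covariates *E* in

&nbsp;&nbsp;&nbsp;&nbsp;logit P(Y=1) = βX + γE,

tested per SNP with a 1-df likelihood-ratio test (full IRLS fit) or a
vectorized score test for genome-scale panels. A Balding–Nichols simulator
(discrete subpopulations at a chosen F<sub>st</sub>, or an admixed
population with uniform ancestry and disease probability
½·log r·rᵃ/(r−1)) and an experiment grid reproduce the published
type-I-error/power comparison at desk scale.

## Worked example

```r
library(trianet)

spec <- scenario_preset("extreme", seed = 1)   # 2 pops, Fst 0.01,
                                               # cases 50/50, controls 0/100
ex <- run_experiment(spec,
                     methods = c("naive", "pcs:1", "components", "communities"),
                     n_train = 30000, n_test = 20000, reps = 1, alpha = 1e-4)
print(ex)
#> experiment_result: discrete scenario, 1 replicate(s), alpha = 0.0001
#>                  naive   pcs1 components communities
#> random         0.03515 0.0002    0.00020     0.00025
#> differentiated 1.00000 0.0001    0.00015     0.00015
#> causal         0.50840 0.2655    0.26420     0.26900
```

Reading the table: under extreme case/control mismatch the uncorrected
("naive") regression calls essentially **every** differentiated null SNP
significant (1.00) and inflates the random-SNP type-I rate 350-fold above
the 10⁻⁴ level (0.035). All corrected arms — one principal component, the
graph's unconnected components, or its Louvain communities — return both
null categories to the nominal level (≈ 1–2 × 10⁻⁴ at this Monte-Carlo
resolution) and agree on the honest causal-SNP power (≈ 0.26; the naive
0.51 is inflated by the same confounding). The replicate's structure
summary confirms why the discrete covariates work:

```r
ex$structure
#>   rep n_components n_communities modularity precision_components precision_communities
#> 1   1            6            24  0.7411992                    1                     1
```

Typical analysis of real data goes through the same pieces:

```r
g  <- read_vcf("cohort.vcf.gz")
g  <- maf_filter(g, 0.05)
g  <- exclude_regions(g, read_bed_regions("long_range_ld.bed"))
g  <- ld_prune(g)
D  <- genetic_covariance(g)
tg <- build_triad_graph(D)
comm <- louvain(tg, seed = 1)
plot_network(tg, comm, truth = pop_labels, path = "network.png")
res <- logistic_assoc(test_snps, phenotype, dummy_encode(comm))
```

A thin command-line wrapper with the same pipeline lives at
`inst/scripts/trianet` (subcommands `simulate`, `structure`, `assoc`,
`table7`, `plot`).

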