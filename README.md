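# immclust

Discovery and validation of immune molecular subtypes from bulk tumor
expression cohorts.

Solid tumors differ widely in how much, and what kind of, immune
infiltration they carry, and those differences track prognosis and
immunotherapy benefit. `immclust` is for computational oncologists who
want to stratify a tumor cohort by its immune microenvironment the way
multi-cohort subtyping studies do it — and to test every step of that
workflow on synthetic cohorts with known planted structure before
touching real data.

The pipeline:

1. **Score** each tumor against immune gene signatures by single-sample
   gene-set enrichment (ssGSEA). With genes ranked per sample
   ($r_g = N$ for the highest) and walked in decreasing order, the
   enrichment score of set $G$ is
   $\mathrm{ES} = \sum_i \big[ P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i) \big]$
   with $P_{\mathrm{in}}(i) = \sum_{g \in G,\, \mathrm{pos}(g)\le i}
   r_g^\alpha / \sum_{g\in G} r_g^\alpha$ and $P_{\mathrm{out}}$ the
   fraction of non-members seen so far ($\alpha = 0.25$ by default).
2. **Screen** signature scores for disease-free-survival association per
   cohort (univariate Cox, Breslow ties, Wald $p < 0.05$, 30-day
   follow-up exclusion) and keep signatures replicating in at least two
   cohorts.
3. **Cluster** the discovery cohort on the retained scores by consensus:
   500 subsamples of 80% of samples, PAM with Euclidean distance at each
   $k \in 2..10$; the consensus-CDF area $A(k)$ and its relative increase
   $\Delta(k)$ guide the choice of $k$. Final labels cut an
   average-linkage hierarchy of $1 - M_k$ and are named IS1..ISK from
   worst to best prognosis by restricted-mean survival time.
4. **Validate** in independent cohorts by nearest-centroid projection
   (Pearson), the in-group proportion (IGP), and centroid correlation
   matching.
5. **Characterize** subtypes: Kaplan–Meier/log-rank, tumor mutational
   burden, a per-gene mutation-frequency chi-square screen, cytolytic
   activity, stromal/immune scores, Kruskal–Wallis/Wilcoxon contrasts,
   and WGCNA-style co-expression modules
   ($a_{ij} = |\mathrm{cor}|^{\beta}$, $\beta = 10$, topological overlap,
   dynamic-cut-style module detection, eigengenes, survival-filtered hub
   genes).

A first-class synthetic-cohort generator (`simulate_cohort()`,
`simulate_pair()`) plants K subtypes with signature shifts, exponential
survival with subtype hazards, and subtype-dependent mutation burdens, so
the whole workflow runs end-to-end with no downloads.

## Worked example

Simulate a discovery/validation pair at the default study conditions
(2,000 genes, 150 samples, 3 planted subtypes, 17 signatures), then run
the discovery workflow:

```r
library(immclust)

cfg  <- simulation_config(seed = 42)
pair <- simulate_pair(cfg, seed_a = 1, seed_b = 2)
disc <- pair$a

x      <- log_transform(filter_expressed_genes(disc$expression))
scores <- ssgsea_scores(x, disc$signature_sets, alpha = 0.25)
screen <- screen_cohort(scores, disc$survival, cohort_id = "discovery")
screen
#> screen_report 'discovery': 17 signature(s), 10 selected

cons <- consensus_run(scores[screen$selected, ], k_range = 2:6,
                      n_resamples = 500, frac = 0.8, seed = 7)
cons
#> consensus_result over k = 2..6 (500 resamples, frac 0.80)
#>           2     3     4     5     6
#> A     0.438 0.663 0.737 0.784 0.827
#> delta 0.438 0.514 0.111 0.065 0.054
```

The sharp $\Delta$ peak at $k = 3$ recovers the planted subtype number.
Label the clusters by prognosis and test the survival separation:

```r
subtypes <- order_by_prognosis(final_labels(cons, 3), disc$survival)
table(subtypes)
#> IS1 IS2 IS3
#>  48  42  60
attr(subtypes, "ordering_basis")
#>   original label rmst_days
#> 1       C3   IS1  303.8519
#> 2       C1   IS2  455.3089
#> 3       C2   IS3  718.2196

km <- km_logrank(disc$survival, subtypes)
#> log-rank chi-square = 14.9 on 2 df, p = 0.00058
```

IS1 carries the shortest restricted-mean disease-free survival (~304
days) and IS3 the longest (~718 days). Project the independent cohort
onto the discovery centroids and check reproducibility:

```r
cen <- subtype_centroids(scores[screen$selected, ], subtypes)
val_scores <- ssgsea_scores(
  log_transform(filter_expressed_genes(pair$b$expression)),
  pair$b$signature_sets)[screen$selected, ]
proj <- project_nearest_centroid(val_scores, cen)
igp(val_scores, proj)
#>   label       igp  n flag
#> 1   IS1 0.9807692 52
#> 2   IS2 0.9811321 53
#> 3   IS3 0.9777778 45
```

An in-group proportion near 1 for every subtype means each projected
subtype forms a tight, reproducible group in the validation cohort.

`run_pipeline(default_config(seed = 1), out_dir = "run")` executes all of
the above plus mutation and co-expression characterization from one
configuration (or a YAML file via `read_config()`), writing every stage
table as TSV alongside a `manifest.json` with the configuration, seeds,
and md5 hashes of all outputs; identical configurations reproduce
byte-identical results.

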